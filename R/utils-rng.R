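# Named random substreams derived from one master seed.
#
# Every stochastic stage seeds its own substream with a seed derived from the
# master seed and a stage label, so adding or reordering stages never shifts
# the draws of another stage, and a whole run is reproducible from one integer.

.MERSENNE31 <- 2147483647

# Deterministic 31-bit hash of a label string (polynomial rolling hash).
.label_hash <- function(name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% .MERSENNE31
  h
}

#' Derive the seed of a named substream
#'
#' @param seed master seed (integer-like).
#' @param name substream label.
#' @return An integer in `[0, 2^31 - 2]`, deterministic in both arguments.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  s <- as.numeric(seed) %% .MERSENNE31
  as.integer((s * 48271 + .label_hash(name)) %% .MERSENNE31)
}

# Evaluate `expr` under the substream RNG state, restoring the caller's state.
with_substream <- function(seed, name, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Small validation helpers -----------------------------------------------------

.stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

.check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    .stop_config(field, "must be a probability in [0, 1]")
  invisible(x)
}

.check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < min || x != floor(x))
    .stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

.check_effect_map <- function(x, field, labels) {
  if (!is.numeric(x) || is.null(names(x)) || !setequal(names(x), labels))
    .stop_config(field, paste0("must be a named numeric vector covering ",
                               "exactly {", paste(labels, collapse = ", "), "}"))
  invisible(x[labels])
}

.check_category_probs <- function(x, field, labels) {
  .check_effect_map(x, field, labels)
  .check_prob(x, field)
  if (abs(sum(x) - 1) > 1e-8)
    .stop_config(field, "must sum to 1")
  invisible(x[labels])
}
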