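# Iterated one-observation-per-species subsampling.
#
# Species differ wildly in how many photographs they have, so raw
# per-observation percentages over-weight well-photographed species. Every
# summary here is computed over species: in each iteration one observation
# per species is drawn uniformly at random, class percentages are computed
# over species, and results are averaged over iterations. The per-iteration
# species-to-class assignment ("stream") is materialized so that downstream
# contingency and frequency analyses see the same resamples.

.class_codes <- function(cls) {
  match(cls, identification_classes())
}

# iterations x species integer matrix of class codes: one subsampled
# observation per species per iteration.
.subsample_stream <- function(observations, n_iter) {
  cls <- .class_codes(observations$class)
  by_sp <- split(seq_len(nrow(observations)), observations$verified_name)
  sp_names <- names(by_sp)
  stream <- matrix(0L, nrow = n_iter, ncol = length(by_sp),
                   dimnames = list(NULL, sp_names))
  for (s in seq_along(by_sp)) {
    idx <- by_sp[[s]]
    pick <- if (length(idx) == 1L) rep.int(idx, n_iter)
            else idx[1L + floor(runif(n_iter) * length(idx))]
    stream[, s] <- cls[pick]
  }
  stream
}

.stream_percentages <- function(stream) {
  n_sp <- ncol(stream)
  pct <- vapply(seq_along(identification_classes()),
                function(k) rowSums(stream == k) / n_sp * 100,
                numeric(nrow(stream)))
  if (nrow(stream) == 1L) pct <- matrix(pct, nrow = 1L)
  colnames(pct) <- identification_classes()
  pct
}

#' Iterated one-per-species subsampling of class percentages
#'
#' In each of `n_iter` iterations one observation per species is selected
#' uniformly at random, so each species counts once; the percentage of
#' species in each identification class is computed per iteration and
#' averaged across iterations.
#'
#' @param observations classified observation table (see
#'   [classify_observations()]); must contain `verified_name` and `class`.
#' @param n_iter number of iterations (default 1000).
#' @param seed master seed for the subsampling stream.
#' @return Object of class `iteration_summary` with elements
#'   `n_iterations`, `species` (names), `percent` (iterations x 4 matrix),
#'   `averaged` (named means), `mc_se` (Monte-Carlo standard errors of the
#'   averages), `cumulative` (percent identified at least to species /
#'   genus / family) and `stream` (iterations x species class codes).
#' @export
iterate_subsample <- function(observations, n_iter = 1000, seed = 1) {
  if (is.null(observations) || !nrow(observations))
    stop("observation table is empty", call. = FALSE)
  if (!"class" %in% names(observations))
    stop("observations must be classified first (missing 'class' column)",
         call. = FALSE)
  n_iter <- .check_count(n_iter, "n_iter")
  stream <- with_substream(seed, "subsample",
                           .subsample_stream(observations, n_iter))
  .summarize_stream(stream, n_iter)
}

.summarize_stream <- function(stream, n_iter) {
  pct <- .stream_percentages(stream)
  averaged <- colMeans(pct)
  mc_se <- apply(pct, 2, sd) / sqrt(n_iter)
  cumulative <- cumsum(averaged[c("species", "genus", "family")])
  names(cumulative) <- c("species", "genus_or_better", "family_or_better")
  structure(list(n_iterations = n_iter, species = colnames(stream),
                 percent = pct, averaged = averaged, mc_se = mc_se,
                 cumulative = cumulative, stream = stream),
            class = "iteration_summary")
}

#' @export
print.iteration_summary <- function(x, ...) {
  cat(sprintf("iteration_summary: %d species, %d iterations\n",
              length(x$species), x$n_iterations))
  cat("averaged class percentages:\n")
  print(round(x$averaged, 2))
  cat("cumulative:\n")
  print(round(x$cumulative, 2))
  invisible(x)
}

#' Paired comparison of two study settings
#'
#' Restricts both tables to species present in both settings, draws one
#' observation per species per setting independently in each iteration, and
#' reports per identification class the proportion of iterations in which the
#' field percentage strictly exceeds the database percentage. Proportions
#' below `alpha` or above `1 - alpha` flag a significant difference.
#'
#' @param obs_db,obs_field classified observation tables for the two
#'   settings.
#' @param n_iter iterations (default 1000).
#' @param seed master seed.
#' @param alpha two-tailed flag threshold on the exceedance proportion.
#' @return Object of class `paired_comparison`: `exceedance` (field > db),
#'   `tie_mass`, `significant` (logical per class), `n_common`, plus both
#'   settings' averaged percentages over the common species.
#' @export
compare_settings <- function(obs_db, obs_field, n_iter = 1000, seed = 1,
                             alpha = 0.05) {
  if (!nrow(obs_db) || !nrow(obs_field))
    stop("both observation tables must be nonempty", call. = FALSE)
  common <- intersect(unique(obs_db$verified_name),
                      unique(obs_field$verified_name))
  if (!length(common))
    stop("no species occur in both settings", call. = FALSE)
  n_iter <- .check_count(n_iter, "n_iter")
  db <- obs_db[obs_db$verified_name %in% common, , drop = FALSE]
  fi <- obs_field[obs_field$verified_name %in% common, , drop = FALSE]
  s_db <- with_substream(seed, "paired/database",
                         .subsample_stream(db, n_iter))
  s_fi <- with_substream(seed, "paired/field",
                         .subsample_stream(fi, n_iter))
  p_db <- .stream_percentages(s_db)
  p_fi <- .stream_percentages(s_fi)
  exceedance <- colMeans(p_fi > p_db)
  tie_mass <- colMeans(p_fi == p_db)
  structure(list(
    n_common = length(common), n_iterations = n_iter, alpha = alpha,
    exceedance = exceedance, tie_mass = tie_mass,
    significant = exceedance < alpha | exceedance > 1 - alpha,
    averaged_database = colMeans(p_db), averaged_field = colMeans(p_fi)),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired_comparison: %d common species, %d iterations\n",
              x$n_common, x$n_iterations))
  out <- data.frame(class = identification_classes(),
                    database = round(unname(x$averaged_database), 2),
                    field = round(unname(x$averaged_field), 2),
                    p_field_higher = round(unname(x$exceedance), 3),
                    significant = unname(x$significant))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Median-frequency null model per identification class
#'
#' Tests whether species in a given identification class are systematically
#' more or less frequent in the region than a random draw of as many species.
#' In each subsampling iteration the median regional frequency of the species
#' in each class is compared with the median of a random relabelling of
#' classes over species (same class sizes); the per-class P value is the
#' proportion of iterations in which the null median strictly exceeds the
#' empirical one.
#'
#' @param summary an [iterate_subsample()] result (its stream is reused so
#'   all analyses of a run see the same resamples).
#' @param species species table with `accepted_name` and `frequency`.
#' @param seed master seed for the null relabelling.
#' @return Object of class `frequency_null`: per class the empirical median
#'   frequency (across-iteration median of per-iteration medians) and the
#'   null P; classes empty in every iteration are reported as `NA`.
#' @export
frequency_null_test <- function(summary, species, seed = 1) {
  stopifnot(inherits(summary, "iteration_summary"))
  freq <- setNames(species$frequency, species$accepted_name)
  if (any(!(summary$species %in% names(freq))))
    stop("species table lacks frequencies for some sampled species",
         call. = FALSE)
  f <- as.numeric(freq[summary$species])
  stream <- summary$stream
  n_iter <- nrow(stream)
  n_cls <- length(identification_classes())
  emp <- matrix(NA_real_, n_iter, n_cls)
  nul <- matrix(NA_real_, n_iter, n_cls)
  with_substream(seed, "frequency_null", {
    for (t in seq_len(n_iter)) {
      cls <- stream[t, ]
      perm <- cls[sample.int(length(cls))]
      for (k in seq_len(n_cls)) {
        if (any(cls == k)) {
          emp[t, k] <- median(f[cls == k])
          nul[t, k] <- median(f[perm == k])
        }
      }
    }
  })
  p <- vapply(seq_len(n_cls), function(k) {
    ok <- !is.na(emp[, k])
    if (!any(ok)) return(NA_real_)
    mean(nul[ok, k] > emp[ok, k])
  }, 0)
  med <- vapply(seq_len(n_cls), function(k) {
    if (all(is.na(emp[, k]))) NA_real_ else median(emp[, k], na.rm = TRUE)
  }, 0)
  structure(list(median_frequency = setNames(med, identification_classes()),
                 p_value = setNames(p, identification_classes()),
                 n_iterations = n_iter),
            class = "frequency_null")
}

#' @export
print.frequency_null <- function(x, ...) {
  cat(sprintf("frequency_null: %d iterations\n", x$n_iterations))
  print(data.frame(class = identification_classes(),
                   median_frequency = unname(x$median_frequency),
                   p = round(unname(x$p_value), 3)), row.names = FALSE)
  invisible(x)
}
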