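# Binomial random-intercept model of species-level identification success on
# image characteristics (plant organs, number of species in focus,
# background), with species as a random factor so that well-photographed
# species do not dominate. Inference is Wald-based: type-III chi-square per
# factor block, estimated marginal means on the logit scale with
# delta-method standard errors, Holm-adjusted pairwise contrasts and
# compact-letter grouping.

#' Fit the binomial random-intercept model of identification success
#'
#' Outcome is 1 when the observation was identified to species level.
#' Fixed effects are the three image annotations (treatment coding,
#' reference level first alphabetically); species enters as a random
#' intercept. Species with fewer than `min_obs` observations are excluded
#' before fitting. The random-effect integral uses the Laplace
#' approximation by default (`nAGQ = 1`); adaptive Gauss-Hermite is
#' available via `nAGQ`.
#'
#' @param observations classified observation table.
#' @param min_obs minimum observations per species (default 3).
#' @param fixed character vector of fixed-effect annotation columns.
#' @param nAGQ integration points for [lme4::glmer()].
#' @return Object of class `glmm_fit`: the `lme4` model plus coefficient
#'   vector, covariance matrix, factor/level metadata, counts, convergence
#'   diagnostics.
#' @export
fit_binary_mixed <- function(observations, min_obs = 3,
                             fixed = c("organs", "focus", "background"),
                             nAGQ = 1L) {
  if (!"class" %in% names(observations))
    stop("observations must be classified first", call. = FALSE)
  min_obs <- .check_count(min_obs, "min_obs")
  dat <- observations
  n_per <- table(dat$verified_name)
  keep <- dat$verified_name %in% names(n_per)[n_per >= min_obs]
  dat <- dat[keep, , drop = FALSE]
  if (!nrow(dat))
    stop("no species with at least ", min_obs, " observations", call. = FALSE)
  dat$success <- as.integer(dat$class == "species")

  used <- character(0)
  for (f in fixed) {
    lv <- sort(unique(as.character(dat[[f]])))
    if (length(lv) < 2) {
      warning("factor '", f, "' has a single observed level and was dropped")
    } else {
      dat[[f]] <- factor(dat[[f]], levels = lv)
      used <- c(used, f)
    }
  }
  if (!length(used))
    stop("no fixed-effect factor has two or more observed levels",
         call. = FALSE)
  form <- as.formula(paste("success ~", paste(used, collapse = " + "),
                           "+ (1 | verified_name)"))
  model <- lme4::glmer(form, data = dat, family = stats::binomial(),
                       nAGQ = nAGQ)
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  beta <- lme4::fixef(model)
  V <- as.matrix(vcov(model))
  mm <- model.matrix(model)
  structure(list(
    model = model, coefficients = beta, vcov = V,
    assign = attr(mm, "assign"),
    factors = lapply(setNames(used, used),
                     function(f) levels(dat[[f]])),
    fixed_terms = used,
    sd_species = sqrt(unname(lme4::VarCorr(model)$verified_name[1, 1])),
    n_obs = nrow(dat), n_species = length(unique(dat$verified_name)),
    min_obs = min_obs,
    converged = is.null(msgs), messages = msgs),
    class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(paste0("glmm_fit: %d observations of %d species ",
                     "(min %d obs/species)\n"),
              x$n_obs, x$n_species, x$min_obs))
  cat(sprintf("random-intercept SD (species): %.3f\n", x$sd_species))
  print(round(x$coefficients, 3))
  if (!x$converged)
    cat("convergence messages:\n ", paste(x$messages, collapse = "\n  "),
        "\n")
  invisible(x)
}

#' Type-III Wald chi-square tests per factor
#'
#' For each fixed factor the full block of its (treatment-coded)
#' coefficients `b` with covariance block `V` is tested against zero with
#' `chi-square = b' V^{-1} b`, degrees of freedom equal to the block size.
#'
#' @param fit a [fit_binary_mixed()] result (or any list with
#'   `coefficients`, `vcov`, `assign` and `fixed_terms`).
#' @return data.frame with columns `factor`, `chisq`, `df`, `p`.
#' @export
type3_wald <- function(fit) {
  terms <- fit$fixed_terms
  out <- lapply(seq_along(terms), function(i) {
    idx <- which(fit$assign == i)
    b <- fit$coefficients[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e)
      stop("singular covariance block for factor '", terms[i], "'",
           call. = FALSE))
    chi <- drop(t(b) %*% Vi %*% b)
    data.frame(factor = terms[i], chisq = chi, df = length(b),
               p = pchisq(chi, df = length(b), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Model matrix of the full factorial reference grid under treatment coding.
.reference_grid <- function(fit) {
  grid <- expand.grid(fit$factors, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  for (f in names(fit$factors))
    grid[[f]] <- factor(grid[[f]], levels = fit$factors[[f]])
  form <- as.formula(paste("~", paste(fit$fixed_terms, collapse = " + ")))
  list(grid = grid, X = model.matrix(form, grid))
}

#' Estimated marginal means for one factor
#'
#' For each level of `factor` the linear predictor is averaged, with equal
#' weights, over the levels of the other fixed factors, at a random effect
#' of zero. Standard errors come from the coefficient covariance by the
#' delta method; pairwise level contrasts are z-tested on the logit scale
#' with Holm adjustment and summarized as compact letters.
#'
#' @param fit a [fit_binary_mixed()] result.
#' @param factor name of a fixed factor in the model.
#' @param alpha significance level for the letter grouping.
#' @param adjust multiplicity adjustment for pairwise P values
#'   (see [stats::p.adjust()]; default `"holm"`).
#' @return Object of class `emm_result`: `emm` (level, logit-scale mean,
#'   back-transformed probability, SE, letters) and `contrasts` (pairwise
#'   estimates, z, adjusted P).
#' @export
estimated_marginal_means <- function(fit, factor, alpha = 0.05,
                                     adjust = "holm") {
  if (!(factor %in% fit$fixed_terms))
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  rg <- .reference_grid(fit)
  levels <- fit$factors[[factor]]
  L <- t(vapply(levels, function(l) {
    colMeans(rg$X[rg$grid[[factor]] == l, , drop = FALSE])
  }, numeric(ncol(rg$X))))
  est <- drop(L %*% fit$coefficients)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))

  pairs <- utils::combn(seq_along(levels), 2)
  Ld <- L[pairs[1, ], , drop = FALSE] - L[pairs[2, ], , drop = FALSE]
  d <- drop(Ld %*% fit$coefficients)
  d_se <- sqrt(rowSums((Ld %*% fit$vcov) * Ld))
  z <- d / d_se
  p_adj <- p.adjust(2 * pnorm(-abs(z)), method = adjust)
  contrasts <- data.frame(
    level1 = levels[pairs[1, ]], level2 = levels[pairs[2, ]],
    estimate = d, se = d_se, z = z, p_adj = p_adj,
    stringsAsFactors = FALSE)

  pmat <- matrix(1, length(levels), length(levels),
                 dimnames = list(levels, levels))
  for (k in seq_len(ncol(pairs))) {
    pmat[pairs[1, k], pairs[2, k]] <- p_adj[k]
    pmat[pairs[2, k], pairs[1, k]] <- p_adj[k]
  }
  letters <- compact_letter_display(pmat, alpha = alpha)
  emm <- data.frame(level = levels, emm_logit = est, prob = plogis(est),
                    se = se, letters = letters, stringsAsFactors = FALSE)
  structure(list(factor = factor, emm = emm, contrasts = contrasts,
                 alpha = alpha, adjust = adjust), class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat(sprintf("estimated marginal means for '%s' (%s-adjusted contrasts)\n",
              x$factor, x$adjust))
  out <- x$emm
  out$emm_logit <- round(out$emm_logit, 3)
  out$prob <- round(out$prob, 3)
  out$se <- round(out$se, 3)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Compact letter display from a pairwise P matrix
#'
#' Insert-and-absorb algorithm: start from one group holding every level;
#' for each significant pair, every group containing both is split into two
#' groups each missing one member; groups that become subsets of others are
#' absorbed. Levels sharing a letter do not differ significantly; levels
#' differing significantly share no letter. Deterministic given level order.
#'
#' @param p_matrix symmetric matrix of (adjusted) pairwise P values with
#'   level names as dimnames.
#' @param alpha significance threshold.
#' @return Named character vector of letter strings, one per level.
#' @export
compact_letter_display <- function(p_matrix, alpha = 0.05) {
  lv <- rownames(p_matrix)
  n <- length(lv)
  if (n == 1L) return(setNames("a", lv))
  cols <- list(rep(TRUE, n))  # logical membership vectors
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (p_matrix[i, j] < alpha) {
        new_cols <- list()
        for (col in cols) {
          if (col[i] && col[j]) {
            a <- col; a[i] <- FALSE
            b <- col; b[j] <- FALSE
            new_cols <- c(new_cols, list(a, b))
          } else {
            new_cols <- c(new_cols, list(col))
          }
        }
        # absorb columns contained in another column
        keep <- rep(TRUE, length(new_cols))
        for (k in seq_along(new_cols)) {
          for (l in seq_along(new_cols)) {
            if (k != l && keep[l] &&
                all(new_cols[[k]] <= new_cols[[l]]) &&
                (any(new_cols[[k]] != new_cols[[l]]) || k > l)) {
              keep[k] <- FALSE
              break
            }
          }
        }
        cols <- new_cols[keep]
      }
    }
  }
  # order groups by their first member so letters read top-down
  ord <- order(vapply(cols, function(c) which(c)[1], 0L))
  cols <- cols[ord]
  out <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  setNames(out, lv)
}
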