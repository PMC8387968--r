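# Training-image and frequency association analyses: is a species identified
# more reliably when the classifier saw more training images of it, and does
# training effort differ among families, growth forms, life forms and
# habitats?

#' Per-species identification success
#'
#' @param observations classified observation table.
#' @return data.frame with `accepted_name`, `n_obs`, `n_success` and
#'   `success` (proportion of observations identified to species level).
#' @export
species_success <- function(observations) {
  if (!"class" %in% names(observations))
    stop("observations must be classified first", call. = FALSE)
  agg <- aggregate(cbind(n_obs = rep(1L, nrow(observations)),
                         n_success = observations$class == "species"),
                   by = list(accepted_name = observations$verified_name),
                   FUN = sum)
  agg$success <- agg$n_success / agg$n_obs
  agg[order(agg$accepted_name), , drop = FALSE]
}

#' Correlation of identification success with training-image count
#'
#' Pearson correlation between per-species success proportion and the
#' natural log of the species' training-image count, with a two-sided t-test
#' P value. Species with no training images are excluded (the transform is
#' undefined for them) with a message.
#'
#' @param success result of [species_success()].
#' @param species species table with `n_training_images`.
#' @return Object of class `correlation_result`: `r`, `n`, `p`, `transform`.
#' @export
training_correlation <- function(success, species) {
  dat <- merge(success, species[, c("accepted_name", "n_training_images")],
               by = "accepted_name")
  drop0 <- dat$n_training_images < 1
  if (any(drop0)) {
    message(sum(drop0), " species without training images excluded")
    dat <- dat[!drop0, , drop = FALSE]
  }
  if (nrow(dat) < 3)
    stop("need at least 3 species with both values", call. = FALSE)
  x <- log(dat$n_training_images)
  y <- dat$success
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = nrow(dat),
                 p = ct$p.value,
                 transform = "natural log applied to training-image counts"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, P = %.3g); %s\n",
              x$r, x$n, x$p, x$transform))
  invisible(x)
}

#' Training-image effort across species groups
#'
#' Linear model of `ln(n_training_images)` on a grouping trait with a
#' type-III F test (a single factor, so this is the classical one-way
#' analysis-of-variance F), per-group marginal means with delta-method
#' standard errors, Holm-adjusted pairwise t contrasts and compact letters.
#' Groups with a single species are dropped with a warning.
#'
#' @param species species table.
#' @param grouping one of `family`, `growth_form`, `life_form`, `habitat`.
#' @param alpha significance level for letters.
#' @param min_group_size smallest group retained (default 2).
#' @return Object of class `group_training`: `anova` (F, df, P), `means`
#'   (group, mean ln count, SE, letters), `contrasts`.
#' @export
group_training_comparison <- function(species, grouping, alpha = 0.05,
                                      min_group_size = 2) {
  grouping <- match.arg(grouping,
                        c("family", "growth_form", "life_form", "habitat"))
  dat <- species[species$n_training_images >= 1, , drop = FALSE]
  dat$group <- as.character(dat[[grouping]])
  sizes <- table(dat$group)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    warning("dropping group(s) with fewer than ", min_group_size,
            " species: ", paste(small, collapse = ", "))
    dat <- dat[!(dat$group %in% small), , drop = FALSE]
  }
  if (length(unique(dat$group)) < 2)
    stop("need at least 2 groups of size >= ", min_group_size, call. = FALSE)
  dat$group <- factor(dat$group)
  dat$ln_train <- log(dat$n_training_images)
  fit <- lm(ln_train ~ group, data = dat)
  an <- anova(fit)
  lv <- levels(dat$group)
  X <- model.matrix(~ group,
                    data.frame(group = factor(lv, levels = lv)))
  beta <- coef(fit)
  V <- vcov(fit)
  est <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  pairs <- utils::combn(seq_along(lv), 2)
  Xd <- X[pairs[1, ], , drop = FALSE] - X[pairs[2, ], , drop = FALSE]
  d <- drop(Xd %*% beta)
  d_se <- sqrt(rowSums((Xd %*% V) * Xd))
  tt <- d / d_se
  p_adj <- p.adjust(2 * pt(-abs(tt), df = fit$df.residual), method = "holm")
  pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  for (k in seq_len(ncol(pairs))) {
    pmat[pairs[1, k], pairs[2, k]] <- p_adj[k]
    pmat[pairs[2, k], pairs[1, k]] <- p_adj[k]
  }
  letters <- compact_letter_display(pmat, alpha = alpha)
  structure(list(
    grouping = grouping,
    anova = data.frame(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                       p = an$`Pr(>F)`[1]),
    means = data.frame(group = lv, mean_ln_train = est, se = se,
                       n = as.integer(table(dat$group)[lv]),
                       letters = letters, stringsAsFactors = FALSE),
    contrasts = data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
                           estimate = d, se = d_se, t = tt, p_adj = p_adj,
                           stringsAsFactors = FALSE)),
    class = "group_training")
}

#' @export
print.group_training <- function(x, ...) {
  cat(sprintf("training images by %s: F(%d, %d) = %.2f, P = %.3g\n",
              x$grouping, x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  out <- x$means
  out$mean_ln_train <- round(out$mean_ln_train, 2)
  out$se <- round(out$se, 3)
  print(out, row.names = FALSE)
  invisible(x)
}
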