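# Fixed-marginal randomization machinery for class-by-group cross tables.
#
# The null of "no association" conditional on both margins is the multiple
# hypergeometric law. Tables are sampled from it by sequential conditional
# hypergeometric draws (Patefield's construction): filling the table cell by
# cell, each count is hypergeometric given what remains of its row and of the
# column margins. The sampler is vectorized over the number of tables so
# Monte-Carlo tests stay cheap in plain R.

#' Sample contingency tables with fixed margins
#'
#' Draws `n` tables uniformly from the independence (multiple
#' hypergeometric) distribution conditional on the given row and column
#' sums, via sequential conditional hypergeometric draws.
#'
#' @param row_margins,col_margins nonnegative integer vectors with equal
#'   totals.
#' @param n number of tables.
#' @return An integer array of dimension `(rows, cols, n)`.
#' @export
sample_fixed_margin_tables <- function(row_margins, col_margins, n = 1) {
  r <- as.integer(round(row_margins))
  cl <- as.integer(round(col_margins))
  if (any(r < 0) || any(cl < 0))
    stop("margins must be nonnegative", call. = FALSE)
  if (sum(r) != sum(cl))
    stop("row and column margins must have equal totals", call. = FALSE)
  nr <- length(r); nc <- length(cl)
  out <- array(0L, dim = c(nr, nc, n))
  colrem <- matrix(rep(cl, each = n), nrow = n)  # remaining column margins
  suffix <- 1 * (row(diag(nc)) >= col(diag(nc)))  # ones on/below diagonal
  for (i in seq_len(nr)) {
    rowleft <- rep.int(r[i], n)
    # after[, j]: what remains of columns j..nc before filling cell (i, j)
    after <- colrem %*% suffix
    for (j in seq_len(nc - 1L)) {
      x <- rhyper(n, m = colrem[, j], n = after[, j + 1L], k = rowleft)
      out[i, j, ] <- x
      colrem[, j] <- colrem[, j] - x
      rowleft <- rowleft - x
    }
    out[i, nc, ] <- rowleft
    colrem[, nc] <- colrem[, nc] - rowleft
  }
  storage.mode(out) <- "integer"
  out
}

#' Sample one fixed-margin table
#'
#' @inheritParams sample_fixed_margin_tables
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return An integer matrix with exactly the requested margins.
#' @export
sample_fixed_margin_table <- function(row_margins, col_margins, seed = NULL) {
  draw <- function() sample_fixed_margin_tables(row_margins, col_margins,
                                                1)[, , 1, drop = TRUE]
  tab <- if (is.null(seed)) draw() else with_substream(seed, "table", draw())
  matrix(as.integer(tab), nrow = length(row_margins))
}

# log multiple-hypergeometric probability of table(s) given margins.
# `cells` is a (#cells x n) matrix of counts (column-major per table).
.log_table_prob <- function(cells, row_margins, col_margins) {
  konst <- sum(lfactorial(row_margins)) + sum(lfactorial(col_margins)) -
    lfactorial(sum(row_margins))
  konst - colSums(lfactorial(cells))
}

# Enumerate all nonnegative integer tables with the given margins, up to
# `cap` tables; returns a (#cells x #tables) matrix or NULL if cap exceeded.
.enumerate_margin_tables <- function(row_margins, col_margins, cap = 1e4) {
  nr <- length(row_margins); nc <- length(col_margins)
  acc <- new.env(parent = emptyenv())
  acc$tables <- vector("list", 256L)
  acc$n <- 0L
  recurse <- function(i, colrem, rows_done) {
    if (i > nr) {
      acc$n <- acc$n + 1L
      if (acc$n > cap) return(FALSE)
      if (acc$n > length(acc$tables))
        acc$tables <- c(acc$tables, vector("list", length(acc$tables)))
      acc$tables[[acc$n]] <- rows_done
      return(TRUE)
    }
    ri <- row_margins[i]
    fill_row <- function(j, left, row) {
      if (j == nc) {
        if (left > colrem[nc]) return(TRUE)
        row[nc] <- left
        return(recurse(i + 1L, colrem - row, c(rows_done, row)))
      }
      lo <- max(0L, left - sum(colrem[(j + 1L):nc]))
      hi <- min(left, colrem[j])
      if (lo > hi) return(TRUE)
      for (x in lo:hi) {
        row[j] <- x
        if (!fill_row(j + 1L, left - x, row)) return(FALSE)
      }
      TRUE
    }
    fill_row(1L, ri, integer(nc))
  }
  ok <- recurse(1L, col_margins, integer(0))
  if (!ok) return(NULL)
  if (acc$n == 0L) return(matrix(integer(0), nrow = nr * nc))
  # rows were accumulated row-major; transpose to column-major cell order
  m <- vapply(acc$tables[seq_len(acc$n)], function(v) {
    as.integer(t(matrix(v, nrow = nr, byrow = TRUE)))
  }, integer(nr * nc))
  matrix(m, nrow = nr * nc)
}

#' Fisher exact test by enumeration or Monte Carlo
#'
#' Two-sided Fisher exact test for an r x c integer table: the P value is the
#' total multiple-hypergeometric probability of tables (with the observed
#' margins) no more probable than the observed one. Small problems are
#' enumerated exactly; larger ones use the add-one Monte-Carlo estimator
#' `(1 + #{less or equally probable samples}) / (B + 1)` on fixed-margin
#' samples from [sample_fixed_margin_tables()].
#'
#' @param table integer matrix.
#' @param B Monte-Carlo sample size (default 2000).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param exact_cap enumerate exactly when the number of feasible tables does
#'   not exceed this cap.
#' @return List with `p.value`, `method` ("exact" or "monte-carlo") and `B`.
#' @export
fisher_exact_mc <- function(table, B = 2000, seed = NULL, exact_cap = 2000) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers", call. = FALSE)
  r <- rowSums(tab); cl <- colSums(tab)
  if (sum(tab) == 0)
    return(list(p.value = 1, method = "degenerate", B = 0L))
  lp_obs <- .log_table_prob(matrix(as.integer(tab)), r, cl)
  tol <- 1e-7
  # cheap upper bound on the number of feasible tables (row compositions,
  # ignoring column constraints): only attempt enumeration when it fits
  nc <- length(cl)
  log_bound <- sum(lchoose(r + nc - 1, nc - 1))
  enum <- if (log_bound <= log(max(exact_cap, 1)))
    .enumerate_margin_tables(r, cl, cap = exact_cap) else NULL
  if (!is.null(enum)) {
    lp <- .log_table_prob(enum, r, cl)
    p <- sum(exp(lp[lp <= lp_obs + tol]))
    return(list(p.value = min(1, p), method = "exact", B = 0L))
  }
  run <- function() {
    draws <- sample_fixed_margin_tables(r, cl, B)
    lp <- .log_table_prob(matrix(draws, nrow = length(tab)), r, cl)
    (1 + sum(lp <= lp_obs + tol)) / (B + 1)
  }
  p <- if (is.null(seed)) run() else with_substream(seed, "fisher", run())
  list(p.value = p, method = "monte-carlo", B = as.integer(B))
}

#' Cell-level randomization test on an averaged cross table
#'
#' Generates `n_rand` random tables with the observed table's margins (after
#' integerizing them by largest remainder, since the observed table is an
#' average over subsampling iterations and generally non-integer), and for
#' each cell computes `z = (observed - mean_random) / sd_random` and the
#' lower-tail standard-normal probability `pnorm(z)`. Cells with probability
#' above `upper` are flagged `higher`, below `lower` flagged `lower`.
#'
#' @param observed numeric matrix (cells may be non-integer averages).
#' @param n_rand number of random tables (default 1000).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param lower,upper flag thresholds on the normal probability.
#' @return Object of class `cell_randomization`: matrices `observed`,
#'   `mean_random`, `sd_random`, `z`, `prob` and character matrix `flag`
#'   (values `higher`, `lower`, `none`). Cells with zero randomization SD get
#'   `z = 0`, `prob = 0.5`, flag `none`.
#' @export
cell_randomization_test <- function(observed, n_rand = 1000, seed = NULL,
                                    lower = 0.05, upper = 0.95) {
  obs <- as.matrix(observed)
  n_rand <- .check_count(n_rand, "n_rand")
  m <- .integerize_margins(rowSums(obs), colSums(obs))
  run <- function() sample_fixed_margin_tables(m$rows, m$cols, n_rand)
  draws <- if (is.null(seed)) run() else with_substream(seed, "cells", run())
  flat <- matrix(draws, nrow = length(obs))
  mu <- matrix(rowMeans(flat), nrow = nrow(obs), dimnames = dimnames(obs))
  sdev <- matrix(apply(flat, 1, sd), nrow = nrow(obs),
                 dimnames = dimnames(obs))
  z <- matrix(0, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  pos <- sdev > 0
  z[pos] <- (obs[pos] - mu[pos]) / sdev[pos]
  prob <- pnorm(z)
  flag <- matrix("none", nrow(obs), ncol(obs), dimnames = dimnames(obs))
  flag[prob > upper] <- "higher"
  flag[prob < lower] <- "lower"
  structure(list(observed = obs, mean_random = mu, sd_random = sdev,
                 z = z, prob = prob, flag = flag, n_rand = n_rand),
            class = "cell_randomization")
}

#' @export
print.cell_randomization <- function(x, ...) {
  cat(sprintf("cell_randomization: %d random tables\n", x$n_rand))
  cat("z-scores (flags in brackets where significant):\n")
  disp <- matrix(sprintf("%.2f", x$z), nrow(x$z), dimnames = dimnames(x$z))
  mark <- x$flag != "none"
  disp[mark] <- sprintf("%s [%s]", disp[mark], x$flag[mark])
  print(disp, quote = FALSE)
  invisible(x)
}

# Largest-remainder integerization of real-valued margins such that row and
# column totals agree (both rounded to the same integer grand total).
.integerize_margins <- function(rows, cols) {
  total <- round(sum(rows))
  list(rows = .largest_remainder(rows, total),
       cols = .largest_remainder(cols, total))
}

.largest_remainder <- function(x, total) {
  base <- floor(x)
  short <- as.integer(total - sum(base))
  if (short > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  } else if (short < 0) {
    # can only happen when all remainders are 0 and rounding shrank the total
    cut <- order(base, decreasing = TRUE)[seq_len(-short)]
    base[cut] <- base[cut] - 1
  }
  as.integer(base)
}

#' Grouped identification-class analysis
#'
#' The tabular equivalent of the family / growth-form / life-form / habitat
#' accuracy figures: per subsampling iteration, a group x class integer table
#' is built from that iteration's species-to-class assignment and Fisher
#' exact tested (Monte Carlo); across iterations the median and maximum
#' Fisher P are kept. The table averaged over iterations is then screened
#' cell by cell with [cell_randomization_test()], and per-group class
#' percentages are reported.
#'
#' @param summary an [iterate_subsample()] result for the observations being
#'   grouped.
#' @param species species table holding the grouping trait.
#' @param grouping one of `family`, `growth_form`, `life_form`, `habitat`.
#' @param min_group_size drop groups with fewer species (default 10 for
#'   family — only larger families are informative — and 2 otherwise).
#' @param fisher_B Monte-Carlo sample size per iteration's Fisher test.
#' @param n_rand random tables for the cell screen.
#' @param seed master seed.
#' @param lower,upper cell flag thresholds.
#' @return Object of class `grouped_analysis`: `fisher` (median, max and the
#'   per-iteration P values), `cells` (a [cell_randomization_test()] result
#'   on the averaged table), `percent` (per-group class percentages),
#'   `group_sizes`.
#' @export
grouped_class_analysis <- function(summary, species, grouping,
                                   min_group_size = NULL,
                                   fisher_B = 2000, n_rand = 1000, seed = 1,
                                   lower = 0.05, upper = 0.95) {
  stopifnot(inherits(summary, "iteration_summary"))
  grouping <- match.arg(grouping,
                        c("family", "growth_form", "life_form", "habitat"))
  if (is.null(min_group_size))
    min_group_size <- if (grouping == "family") 10L else 2L
  grp_all <- setNames(as.character(species[[grouping]]),
                      species$accepted_name)
  if (any(!(summary$species %in% names(grp_all))))
    stop("species table lacks '", grouping, "' for some sampled species",
         call. = FALSE)
  grp <- grp_all[summary$species]
  sizes <- table(grp)
  keep_groups <- names(sizes)[sizes >= min_group_size]
  if (length(keep_groups) < 2)
    stop("fewer than 2 groups of size >= ", min_group_size,
         " for grouping '", grouping, "'", call. = FALSE)
  keep <- grp %in% keep_groups
  stream <- summary$stream[, keep, drop = FALSE]
  grp <- factor(grp[keep], levels = sort(keep_groups))
  n_iter <- nrow(stream)
  n_cls <- length(identification_classes())
  g_idx <- split(seq_along(grp), grp)

  # per-iteration group x class counts, accumulated into the average
  counts_sum <- matrix(0, length(g_idx), n_cls,
                       dimnames = list(names(g_idx),
                                       identification_classes()))
  p_values <- numeric(n_iter)
  with_substream(seed, paste0("grouped/", grouping), {
    for (t in seq_len(n_iter)) {
      tab <- vapply(g_idx, function(ix)
        tabulate(stream[t, ix], nbins = n_cls), integer(n_cls))
      tab <- t(tab)
      counts_sum <- counts_sum + tab
      p_values[t] <- fisher_exact_mc(tab, B = fisher_B)$p.value
    }
  })
  averaged <- counts_sum / n_iter
  cells <- with_substream(seed, paste0("grouped_cells/", grouping),
                          cell_randomization_test(averaged, n_rand = n_rand,
                                                  lower = lower,
                                                  upper = upper))
  pct <- averaged / rowSums(averaged) * 100
  structure(list(grouping = grouping,
                 fisher = list(median_p = median(p_values),
                               max_p = max(p_values), p_values = p_values),
                 cells = cells, percent = pct,
                 group_sizes = sizes[names(g_idx)],
                 n_iterations = n_iter),
            class = "grouped_analysis")
}

#' @export
print.grouped_analysis <- function(x, ...) {
  cat(sprintf("grouped_analysis by %s: %d groups, %d iterations\n",
              x$grouping, nrow(x$percent), x$n_iterations))
  cat(sprintf("Fisher exact: median P = %.4g, max P = %.4g\n",
              x$fisher$median_p, x$fisher$max_p))
  disp <- matrix(sprintf("%.1f", x$percent), nrow(x$percent),
                 dimnames = dimnames(x$percent))
  mark <- x$cells$flag != "none"
  arrow <- ifelse(x$cells$flag == "higher", "↑", "↓")
  disp[mark] <- paste0(disp[mark], " ", arrow[mark])
  print(disp, quote = FALSE)
  invisible(x)
}
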