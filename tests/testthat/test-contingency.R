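# Fixed-marginal sampling, Fisher testing and the cell randomization screen.

test_that("forced margins admit exactly one table", {
  expect_equal(sample_fixed_margin_table(5, 5, seed = 1),
               matrix(5L, 1, 1))
  for (i in 1:10) {
    t2 <- sample_fixed_margin_table(c(2, 0), c(1, 1))
    expect_equal(t2, matrix(c(1L, 0L, 1L, 0L), 2, 2))
  }
  expect_error(sample_fixed_margin_table(c(2, 1), c(1, 1)), "equal totals")
  expect_error(sample_fixed_margin_table(c(-1, 2), c(1, 0)), "nonnegative")
})

test_that("every draw satisfies its margins exactly", {
  set.seed(10)
  for (i in 1:20) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    tab0 <- matrix(rpois(nr * nc, 3), nr, nc)
    r <- rowSums(tab0); cl <- colSums(tab0)
    draws <- sample_fixed_margin_tables(r, cl, 200)
    expect_true(all(apply(draws, 3, rowSums) == r))
    expect_true(all(apply(draws, 3, colSums) == cl))
  }
})

test_that("sampled tables follow the multiple hypergeometric law", {
  set.seed(11)
  draws <- sample_fixed_margin_tables(c(3, 2), c(2, 3), 2e4)
  emp <- tabulate(draws[1, 1, ] + 1, 3) / 2e4
  pmf <- choose(3, 0:2) * choose(2, 2 - (0:2)) / choose(5, 2)
  expect_true(all(abs(emp - pmf) < 0.02))
  # independent oracle: base R's Patefield implementation
  ref <- vapply(r2dtable(2e4, c(3, 2), c(2, 3)), function(x) x[1, 1], 0)
  emp_ref <- tabulate(ref + 1, 3) / 2e4
  expect_true(all(abs(emp - emp_ref) < 0.02))
})

test_that("cell means approach the independence expectation", {
  set.seed(12)
  r <- c(10, 20, 5); cl <- c(12, 8, 15)
  n <- 4000
  draws <- sample_fixed_margin_tables(r, cl, n)
  m <- apply(draws, c(1, 2), mean)
  s <- apply(draws, c(1, 2), sd)
  expected <- outer(r, cl) / sum(r)
  expect_true(all(abs(m - expected) <= 3 * s / sqrt(n) + 1e-9))
})

test_that("Fisher P values match closed forms on canonical tables", {
  p1 <- fisher_exact_mc(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(p1$method, "exact")
  expect_equal(p1$p.value, 1.0)
  p2 <- fisher_exact_mc(diag(c(10, 10)))
  expect_equal(p2$p.value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_mc(matrix(0, 2, 2))$p.value, 1)
})

test_that("exact enumeration agrees with the reference Fisher test on 2x2", {
  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact_mc(tab)$p.value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-7)
  }
})

test_that("Monte-Carlo estimates track enumeration on small tables", {
  set.seed(14)
  for (i in 1:15) {
    tab <- matrix(rpois(6, 2), 2, 3)
    if (sum(tab) == 0) next
    exact <- fisher_exact_mc(tab)$p.value
    mc <- fisher_exact_mc(tab, B = 1e4, exact_cap = 0)
    expect_equal(mc$method, "monte-carlo")
    expect_lt(abs(mc$p.value - exact), 0.02)
  }
})

test_that("cell randomization honours its z / probability / flag contract", {
  set.seed(15)
  tab <- matrix(rpois(12, 8), 3, 4)
  cr <- cell_randomization_test(tab, n_rand = 500, seed = 3)
  pos <- cr$sd_random > 0
  expect_equal(cr$z[pos],
               (cr$observed[pos] - cr$mean_random[pos]) / cr$sd_random[pos])
  expect_equal(cr$prob, pnorm(cr$z))
  expect_true(all(cr$flag[cr$prob > 0.95] == "higher"))
  expect_true(all(cr$flag[cr$prob < 0.05] == "lower"))
  expect_true(all(cr$flag[cr$prob >= 0.05 & cr$prob <= 0.95] == "none"))
  # degenerate margins: single row leaves no randomization freedom
  cr1 <- cell_randomization_test(matrix(c(4, 6), 1, 2), n_rand = 100,
                                 seed = 1)
  expect_equal(unname(cr1$z), matrix(0, 1, 2))
  expect_true(all(cr1$prob == 0.5) && all(cr1$flag == "none"))
})

test_that("non-integer averaged tables are integerized by largest remainder", {
  tab <- matrix(c(3.4, 2.6, 1.2, 4.8, 2.2, 0.8), 2, 3)
  cr <- cell_randomization_test(tab, n_rand = 50, seed = 2)
  # observed values stay real; the sampler must have run (margins feasible)
  expect_equal(cr$observed, tab)
  expect_true(all(cr$sd_random >= 0))
})

test_that("row relabelling permutes the randomization distribution", {
  set.seed(16)
  tab <- matrix(rpois(8, 20), 2, 4)
  cr1 <- cell_randomization_test(tab, n_rand = 6000, seed = 4)
  cr2 <- cell_randomization_test(tab[2:1, ], n_rand = 6000, seed = 5)
  expect_lt(max(abs(cr1$mean_random - cr2$mean_random[2:1, ])), 0.35)
  expect_lt(max(abs(cr1$z - cr2$z[2:1, ])), 0.35)
})

test_that("a planted enrichment is flagged higher", {
  set.seed(17)
  base <- c(0.3, 0.3, 0.25, 0.15)
  planted <- c(0.6, 0.4 * base[2:4] / 0.7)
  hits <- replicate(60, {
    counts <- rbind(t(stats::rmultinom(7, 50, base)),
                    t(stats::rmultinom(1, 50, planted)))
    cell_randomization_test(counts, n_rand = 600)$flag[8, 1] == "higher"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("grouped analysis separates extreme groups and filters small ones", {
  obs <- make_obs(sprintf("G s%03d", 1:100),
                  c(rep("species", 50), rep("none", 50)))
  sp <- make_species(unique(obs$verified_name),
                     family = c(rep("Fabaceae", 50), rep("Poaceae", 50)))
  s <- iterate_subsample(obs, n_iter = 60, seed = 5)
  ga <- grouped_class_analysis(s, sp, "family", fisher_B = 1500,
                               n_rand = 400, seed = 6)
  expect_lt(ga$fisher$median_p, 0.001)  # needs B > 1000: P floor is 1/(B+1)
  expect_equal(ga$cells$flag["Fabaceae", "species"], "higher")
  expect_equal(ga$cells$flag["Poaceae", "none"], "higher")
  expect_equal(ga$cells$flag["Fabaceae", "none"], "lower")

  # a 9-species family is dropped at the default threshold of 10
  sp2 <- sp
  sp2$family[1:9] <- "Tiny"
  ga2 <- grouped_class_analysis(s, sp2, "family", fisher_B = 100,
                                n_rand = 100, seed = 7)
  expect_false("Tiny" %in% rownames(ga2$percent))
  expect_error(grouped_class_analysis(s, make_species(
    unique(obs$verified_name), family = "OnlyOne"), "family"),
    "fewer than 2 groups")
})

test_that("grouped Fisher P is well behaved under homogeneity", {
  set.seed(18)
  frac <- replicate(200, {
    n <- 60
    obs <- make_obs(sprintf("G s%03d", 1:n),
                    sample(identification_classes(), n, TRUE,
                           prob = c(.5, .25, .15, .1)))
    sp <- make_species(unique(obs$verified_name),
                       growth_form = sample(c("herb", "tree", "shrub"),
                                            n, TRUE))
    s <- iterate_subsample(obs, n_iter = 25, seed = sample.int(1e6, 1))
    ga <- grouped_class_analysis(s, sp, "growth_form", fisher_B = 400,
                                 n_rand = 100, seed = sample.int(1e6, 1))
    ga$fisher$median_p < 0.05
  })
  expect_lte(mean(frac), 0.08)
})
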