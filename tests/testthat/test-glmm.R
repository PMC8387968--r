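# The image-characteristics mixed model: filtering, Wald blocks, marginal
# means and compact letters.

sim_glmm_data <- function(seed, n_species = 60, reps = c(2L, 3L),
                          organ = c(reproductive = 0, both = 0,
                                    vegetative = 0),
                          sd_species = 0.5, baseline = 0.5,
                          balanced = FALSE) {
  cfg <- simulation_config(
    n_species = n_species, n_families = 6,
    replicate_range = list(database = reps, field = reps),
    baseline_logit = baseline, beta_ln_train = 0,
    organ_effects = organ, focus_effect = 0,
    sd_species = sd_species, seed = seed,
    covariate_probabilities = if (balanced) list(
      organs = c(reproductive = 1, both = 1, vegetative = 1) / 3,
      focus = c(single = 0.5, multiple = 0.5),
      background = c(no_vegetation = 1, non_natural = 1,
                     vegetation = 1) / 3)
    else eval(formals(simulation_config)$covariate_probabilities))
  sim <- simulate_dataset(cfg)
  classify_observations(sim$observations, sim$taxonomy)
}

test_that("species below the observation threshold are excluded", {
  obs <- rbind(
    make_obs(rep("Genus abundans", 8), rep(c("species", "none"), 4),
             organs = rep(c("reproductive", "both", "vegetative"), 3),
             focus = rep(c("single", "multiple"), 4),
             background = rep(c("vegetation", "no_vegetation",
                                "non_natural"), 3)),
    make_obs(rep("Genus alter", 6), rep(c("none", "species"), 3),
             setting = "field",
             organs = rep(c("vegetative", "both"), 3),
             focus = rep(c("multiple", "single"), 3),
             background = rep(c("no_vegetation", "vegetation"), 3)),
    make_obs(rep("Genus rarus", 2), c("species", "none"),
             setting = "field", organs = "reproductive"))
  fit <- quiet_fit(obs, min_obs = 3)
  expect_equal(fit$n_species, 2)
  expect_equal(fit$n_obs, 14)
  expect_error(quiet_fit(obs, min_obs = 10), "no species")
})

test_that("Wald blocks reduce to their closed forms", {
  fit <- fake_fit(
    coefficients = c(`(Intercept)` = 0.3, organsb = 2, focusb = 0),
    vcov = diag(c(1, 1, 1)),
    factors = list(organs = c("a", "b"), focus = c("a", "b")),
    assign = c(0, 1, 2))
  w <- type3_wald(fit)
  expect_equal(w$chisq, c(4, 0))
  expect_equal(w$df, c(1, 1))
  expect_equal(w$p[1], pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(w$p[1], 4), 0.0455)
  expect_equal(w$p[2], 1)
})

test_that("type-III Wald agrees with the car reference implementation", {
  skip_if_not_installed("car")
  obs <- sim_glmm_data(seed = 201)
  fit <- quiet_fit(obs)
  mine <- type3_wald(fit)
  ref <- car::Anova(fit$model, type = "III")
  ref <- ref[rownames(ref) != "(Intercept)", ]
  expect_equal(mine$chisq, unname(ref$Chisq[match(mine$factor,
                                                  rownames(ref))]),
               tolerance = 1e-8)
  expect_equal(mine$df, unname(ref$Df[match(mine$factor, rownames(ref))]))
})

test_that("marginal means reduce to hand-computed averages", {
  # known coefficients, treatment coding, two factors of 2 and 3 levels
  beta <- c(`(Intercept)` = 0.2, organsb = 1.0, bgy = 0.4, bgz = -0.2)
  fit <- fake_fit(beta, diag(0.01, 4),
                  factors = list(organs = c("a", "b"),
                                 bg = c("x", "y", "z")),
                  assign = c(0, 1, 2))
  em <- estimated_marginal_means(fit, "organs")
  # level a: intercept + mean of bg effects; level b adds its own effect
  expect_equal(em$emm$emm_logit,
               c(0.2 + (0 + 0.4 - 0.2) / 3, 1.2 + (0 + 0.4 - 0.2) / 3),
               tolerance = 1e-12)
  expect_equal(em$emm$prob, plogis(em$emm$emm_logit))
  # all-zero coefficients give probability one half for every level
  fit0 <- fake_fit(setNames(rep(0, 4), names(beta)), diag(1e-4, 4),
                   factors = fit$factors, assign = fit$assign)
  em0 <- estimated_marginal_means(fit0, "bg")
  expect_equal(em0$emm$prob, rep(0.5, 3))
  expect_true(all(em0$emm$letters == "a"))
  expect_error(estimated_marginal_means(fit, "habitat"), "not in the model")
})

test_that("marginal means match the emmeans reference on a real fit", {
  skip_if_not_installed("emmeans")
  obs <- sim_glmm_data(seed = 202)
  fit <- quiet_fit(obs)
  mine <- estimated_marginal_means(fit, "organs")
  ref <- as.data.frame(emmeans::emmeans(fit$model, "organs"))
  ord <- match(mine$emm$level, as.character(ref$organs))
  expect_equal(mine$emm$emm_logit, ref$emmean[ord], tolerance = 1e-6)
  expect_equal(mine$emm$se, ref$SE[ord], tolerance = 1e-6)
})

test_that("estimates are invariant to row order", {
  obs <- sim_glmm_data(seed = 203)
  fit1 <- quiet_fit(obs)
  set.seed(1)
  fit2 <- quiet_fit(obs[sample.int(nrow(obs)), ])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
  expect_equal(fit1$sd_species, fit2$sd_species, tolerance = 1e-6)
})

test_that("a null generating process is recovered as null", {
  fits <- lapply(1:10, function(r) {
    obs <- sim_glmm_data(seed = 300 + r, n_species = 120, reps = c(3L, 4L),
                         sd_species = 0, baseline = 0, balanced = TRUE)
    quiet_fit(obs)
  })
  expect_lt(mean(vapply(fits, `[[`, 0, "sd_species")), 0.15)
  mean_coef <- rowMeans(vapply(fits, `[[`, numeric(6), "coefficients"))
  expect_lt(max(abs(mean_coef[-1])), 0.15)
})

test_that("a planted organ effect drives its Wald test, not others", {
  hits <- vapply(1:12, function(r) {
    obs <- sim_glmm_data(seed = 400 + r, n_species = 100, reps = c(3L, 4L),
                         organ = c(reproductive = 1.2, both = 0.6,
                                   vegetative = 0))
    w <- type3_wald(quiet_fit(obs))
    c(organ = w$p[w$factor == "organs"] < 0.05,
      background = w$p[w$factor == "background"] < 0.05)
  }, logical(2))
  expect_gte(mean(hits["organ", ]), 0.9)
  expect_lte(mean(hits["background", ]), 0.25)
})

test_that("compact letters encode exactly the significant separations", {
  p_all_ns <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(compact_letter_display(p_all_ns)), c("a", "a", "a"))

  chain <- matrix(1, 3, 3, dimnames = list(c("lo", "mid", "hi"),
                                           c("lo", "mid", "hi")))
  chain["lo", "hi"] <- chain["hi", "lo"] <- 0.001
  expect_equal(unname(compact_letter_display(chain)), c("a", "ab", "b"))

  set.seed(42)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    p <- matrix(1, k, k, dimnames = list(letters[1:k], letters[1:k]))
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      p[a, b] <- p[b, a] <- runif(1)
    }
    cl <- compact_letter_display(p, alpha = 0.3)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      shared <- length(intersect(strsplit(cl[a], "")[[1]],
                                 strsplit(cl[b], "")[[1]])) > 0
      if (p[a, b] < 0.3) expect_false(shared) else expect_true(shared)
    }
  }
})
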