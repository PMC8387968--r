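# The generator must honour its configuration exactly: deterministic under a
# seed, correct marginals, and classes that the classifier reproduces.

test_that("invalid configurations are rejected with the offending field", {
  expect_error(simulation_config(n_species = -1), "n_species")
  expect_error(simulation_config(n_families = 0), "n_families")
  expect_error(simulation_config(p_genus_given_fail = 1.5),
               "p_genus_given_fail")
  expect_error(simulation_config(organ_effects = c(reproductive = 1)),
               "organ_effects")
  expect_error(simulation_config(freq_train_correlation = 2),
               "freq_train_correlation")
  expect_error(
    simulation_config(replicate_range = list(database = c(3, 2),
                                             field = c(1, 5))),
    "replicate_range")
  expect_error(
    simulation_config(covariate_probabilities = list(
      organs = c(reproductive = 0.5, both = 0.4, vegetative = 0.4),
      focus = c(single = 0.8, multiple = 0.2),
      background = c(no_vegetation = 0.5, non_natural = 0.1,
                     vegetation = 0.4))),
    "sum to 1")
})

test_that("degenerate pool size yields an empty, well-formed table", {
  sp <- generate_species_table(simulation_config(n_species = 0))
  expect_equal(nrow(sp), 0)
  expect_true(all(c("accepted_name", "family", "frequency",
                    "n_training_images") %in% names(sp)))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_species = 40, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(s1$observations, f1, row.names = FALSE)
  write.csv(s2$observations, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$species, s2$species)
})

test_that("species tables satisfy their schema and trait ranges", {
  cfg <- simulation_config(n_species = 250, n_families = 12, seed = 5)
  sp <- generate_species_table(cfg)
  expect_equal(nrow(sp), 250)
  expect_false(anyDuplicated(sp$accepted_name) > 0)
  expect_true(all(sp$frequency >= 1 & sp$frequency <= 540))
  expect_true(all(sp$n_training_images >= 1))
  expect_lte(length(unique(sp$family)), 12)
  # genus nests in exactly one family
  g2f <- unique(sp[, c("genus", "family")])
  expect_false(anyDuplicated(g2f$genus) > 0)
  expect_silent(validate_species(sp))
})

test_that("copula construction recovers the configured correlation", {
  cfg <- simulation_config(n_species = 2000, freq_train_correlation = 0.9,
                           seed = 42)
  sp <- generate_species_table(cfg)
  r <- cor(log(sp$n_training_images), sp$frequency)
  expect_lt(abs(r - 0.9), 0.05)
  r_rank <- cor(log(sp$n_training_images), rank(sp$frequency))
  expect_lt(abs(r_rank - 0.9), 0.05)
})

test_that("a saturated logit gives species-level success everywhere", {
  cfg <- simulation_config(n_species = 30, baseline_logit = 50,
                           beta_ln_train = 0, sd_species = 0,
                           organ_effects = c(reproductive = 0, both = 0,
                                             vegetative = 0),
                           focus_effect = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$observations$true_class == "species"))
})

test_that("the neutral model yields a 50% success rate at large n", {
  cfg <- simulation_config(
    n_species = 4000, n_families = 20,
    replicate_range = list(database = c(13L, 13L), field = c(12L, 12L)),
    baseline_logit = 0, beta_ln_train = 0, sd_species = 0,
    organ_effects = c(reproductive = 0, both = 0, vegetative = 0),
    focus_effect = 0, seed = 77)
  sim <- simulate_dataset(cfg)
  frac <- mean(sim$observations$true_class == "species")
  expect_gte(nrow(sim$observations), 1e5)
  expect_lt(abs(frac - 0.5), 0.01)
})

test_that("class frequencies match the analytic mixture of the logit model", {
  cfg <- simulation_config(
    n_species = 4000, n_families = 20,
    replicate_range = list(database = c(13L, 13L), field = c(12L, 12L)),
    baseline_logit = 0.4, beta_ln_train = 0, sd_species = 0,
    organ_effects = c(reproductive = 0.5, both = 0, vegetative = -0.5),
    focus_effect = -0.3, seed = 101)
  sim <- simulate_dataset(cfg)
  cp <- cfg$covariate_probabilities
  p_succ <- sum(vapply(names(cp$organs), function(o)
    sum(vapply(names(cp$focus), function(fc)
      cp$organs[[o]] * cp$focus[[fc]] *
        plogis(0.4 + cfg$organ_effects[[o]] - 0.3 * (fc == "multiple")),
      0)), 0))
  expected <- c(
    species = p_succ,
    genus = (1 - p_succ) * cfg$p_genus_given_fail,
    family = (1 - p_succ) * (1 - cfg$p_genus_given_fail) *
      cfg$p_family_given_genus_fail)
  expected["none"] <- 1 - sum(expected)
  n <- nrow(sim$observations)
  obs_frac <- table(factor(sim$observations$true_class,
                           identification_classes())) / n
  for (k in identification_classes()) {
    se <- sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(obs_frac[[k]] - expected[[k]]), 3 * se + 1e-12)
  }
})

test_that("annotation marginals follow the configured distributions", {
  cfg <- simulation_config(n_species = 1500, seed = 55)
  sim <- simulate_dataset(cfg)
  obs <- sim$observations
  n <- nrow(obs)
  cp <- cfg$covariate_probabilities
  for (col in c("organs", "focus", "background")) {
    probs <- cp[[col]]
    emp <- table(factor(obs[[col]], names(probs))) / n
    for (lv in names(probs)) {
      se <- sqrt(probs[[lv]] * (1 - probs[[lv]]) / n)
      expect_lt(abs(emp[[lv]] - probs[[lv]]), 4 * se)
    }
  }
})

test_that("the classifier reproduces the generator's classes exactly", {
  cfg <- simulation_config(n_species = 120, seed = 31)
  sim <- simulate_dataset(cfg)
  obs <- classify_observations(sim$observations, sim$taxonomy)
  expect_identical(obs$class, obs$true_class)
  counts <- table(factor(obs$class, identification_classes()))
  expect_equal(unname(sim$truth$class_counts),
               as.integer(counts))
})

test_that("species random intercepts are centred as configured", {
  cfg <- simulation_config(n_species = 400, sd_species = 1.5, seed = 13)
  sim <- simulate_dataset(cfg)
  u <- sim$truth$species_intercepts
  expect_equal(length(u), 400)
  expect_lt(abs(mean(u)), 5 * 1.5 / sqrt(400))
  expect_lt(abs(sd(u) - 1.5), 0.25)
})
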