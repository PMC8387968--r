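# Synthetic observation-study generator.
#
# Emulates the structure of a two-setting identification study: a species
# pool with taxonomic and ecological traits, hierarchical replicates per
# species (many photos of some species, one of others), categorical image
# annotations, and a sequential (continuation-ratio) outcome model on the
# four identification classes: species-level success is Bernoulli on a logit
# scale with covariate effects and a species random intercept; conditional on
# failure the suggestion falls to genus, then family, then nothing.

# Fixed trait vocabularies for simulated species pools.
.growth_forms <- c(herb = 0.60, graminoid = 0.15, shrub = 0.12,
                   tree = 0.08, fern = 0.05)
.life_forms <- c(hemicryptophyte = 0.50, therophyte = 0.20, geophyte = 0.10,
                 phanerophyte = 0.10, chamaephyte = 0.05, hydrophyte = 0.05)
.habitats <- c(grassland = 0.30, forest = 0.30, wetland = 0.20,
               ruderal = 0.15, coastal = 0.05)

#' Configuration of the synthetic study generator
#'
#' Defaults describe a realistic two-setting identification study: about 80 %
#' species-level success overall, genus recovered for about half of the
#' failures and family for about half of the rest (so roughly 90 % correct to
#' genus and 95 % to family), replicate counts of 1–16 per species in the
#' database setting and 1–5 in the field, annotation frequencies matching a
#' typical mix of reproductive/vegetative photographs, and a species random
#' intercept of 1 logit.
#'
#' @param n_species number of species in the pool.
#' @param n_families number of plant families the pool is spread over.
#' @param replicate_range named list of integer pairs `(min, max)` giving the
#'   uniform range of replicates per species, for `database` and `field`.
#' @param baseline_logit intercept of species-level success (logit scale) at
#'   reference annotation levels and 1 training image.
#' @param beta_ln_train effect of `ln(n_training_images)` on the logit.
#' @param organ_effects,background_effects named numeric vectors of logit
#'   offsets for the three organ / background categories.
#' @param focus_effect logit penalty applied when several species are in
#'   focus.
#' @param sd_species standard deviation of the species random intercept.
#' @param p_genus_given_fail probability the suggestion still has the right
#'   genus when species-level identification fails.
#' @param p_family_given_genus_fail probability the right family is suggested
#'   when the genus is also wrong.
#' @param covariate_probabilities named list of categorical distributions for
#'   `organs`, `focus` and `background` annotations.
#' @param freq_train_correlation latent Gaussian-copula correlation between
#'   regional frequency and ln(training images), in `[-1, 1]`.
#' @param freq_mean,freq_sd mean and SD of the (truncated-normal) regional
#'   frequency marginal, on the atlas grid-cell scale (1–540).
#' @param train_meanlog,train_sdlog log-normal parameters of the
#'   training-image marginal.
#' @param seed master seed of the generator.
#' @return An object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(n_species = 300,
                              n_families = 16,
                              replicate_range = list(database = c(1L, 16L),
                                                     field = c(1L, 5L)),
                              baseline_logit = -0.4,
                              beta_ln_train = 0.35,
                              organ_effects = c(reproductive = 0.4,
                                                both = 0.4,
                                                vegetative = 0),
                              focus_effect = -0.6,
                              background_effects = c(no_vegetation = 0,
                                                     non_natural = 0,
                                                     vegetation = 0),
                              sd_species = 1,
                              p_genus_given_fail = 0.5,
                              p_family_given_genus_fail = 0.55,
                              covariate_probabilities = list(
                                organs = c(reproductive = 0.33, both = 0.47,
                                           vegetative = 0.20),
                                focus = c(single = 0.78, multiple = 0.22),
                                background = c(no_vegetation = 0.56,
                                               non_natural = 0.03,
                                               vegetation = 0.41)),
                              freq_train_correlation = 0.35,
                              freq_mean = 270, freq_sd = 120,
                              train_meanlog = 5, train_sdlog = 1,
                              seed = 1L) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 0 ||
      n_species != floor(n_species))
    .stop_config("n_species", "must be a nonnegative integer")
  n_species <- as.integer(n_species)
  n_families <- .check_count(n_families, "n_families")
  if (!is.list(replicate_range) ||
      !setequal(names(replicate_range), .settings))
    .stop_config("replicate_range", "must name both settings")
  for (s in .settings) {
    rr <- replicate_range[[s]]
    if (!is.numeric(rr) || length(rr) != 2 || any(rr != floor(rr)) ||
        rr[1] < 1 || rr[1] > rr[2])
      .stop_config(paste0("replicate_range$", s),
                   "must be an integer pair with 1 <= min <= max")
    replicate_range[[s]] <- as.integer(rr)
  }
  for (f in c("baseline_logit", "beta_ln_train", "focus_effect",
              "freq_mean", "freq_sd", "train_meanlog", "train_sdlog")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      .stop_config(f, "must be a finite number")
  }
  organ_effects <- .check_effect_map(organ_effects, "organ_effects",
                                     .organ_levels)
  background_effects <- .check_effect_map(background_effects,
                                          "background_effects",
                                          .background_levels)
  if (!is.numeric(sd_species) || sd_species < 0)
    .stop_config("sd_species", "must be nonnegative")
  .check_prob(p_genus_given_fail, "p_genus_given_fail")
  .check_prob(p_family_given_genus_fail, "p_family_given_genus_fail")
  if (!is.list(covariate_probabilities) ||
      !setequal(names(covariate_probabilities),
                c("organs", "focus", "background")))
    .stop_config("covariate_probabilities",
                 "must list organs, focus and background distributions")
  covariate_probabilities$organs <-
    .check_category_probs(covariate_probabilities$organs,
                          "covariate_probabilities$organs", .organ_levels)
  covariate_probabilities$focus <-
    .check_category_probs(covariate_probabilities$focus,
                          "covariate_probabilities$focus", .focus_levels)
  covariate_probabilities$background <-
    .check_category_probs(covariate_probabilities$background,
                          "covariate_probabilities$background",
                          .background_levels)
  if (!is.numeric(freq_train_correlation) ||
      abs(freq_train_correlation) > 1)
    .stop_config("freq_train_correlation", "must lie in [-1, 1]")
  seed <- .check_count(seed, "seed", min = 0)
  structure(list(
    n_species = n_species, n_families = n_families,
    replicate_range = replicate_range, baseline_logit = baseline_logit,
    beta_ln_train = beta_ln_train, organ_effects = organ_effects,
    focus_effect = focus_effect, background_effects = background_effects,
    sd_species = sd_species, p_genus_given_fail = p_genus_given_fail,
    p_family_given_genus_fail = p_family_given_genus_fail,
    covariate_probabilities = covariate_probabilities,
    freq_train_correlation = freq_train_correlation,
    freq_mean = freq_mean, freq_sd = freq_sd,
    train_meanlog = train_meanlog, train_sdlog = train_sdlog,
    seed = seed), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d species / %d families, ",
                     "baseline %.2f logit, sd_species %.2f, seed %d\n"),
              x$n_species, x$n_families, x$baseline_logit, x$sd_species,
              x$seed))
  invisible(x)
}

.sample_cat <- function(n, probs) {
  names(probs)[1L + findInterval(runif(n), cumsum(probs)[-length(probs)])]
}

#' Generate a synthetic species-trait table
#'
#' Species are spread over families (each family holding at least two genera
#' where its size allows), given categorical growth-form / life-form /
#' habitat traits, and a regional frequency and training-image count coupled
#' through a latent Gaussian copula so that `ln(n_training_images)` and
#' `frequency` correlate at roughly `freq_train_correlation`.
#'
#' @param config a [simulation_config()].
#' @return Species-trait data.frame (see [validate_species()] for columns).
#' @export
generate_species_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_species
  if (n == 0)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.species_columns))),
      .species_columns))
  with_substream(config$seed, "species", {
    fam_id <- sort(sample.int(config$n_families, n, replace = TRUE))
    # genera nest in families; aim for ~3 species per genus, min 2 genera
    genus_id <- integer(n)
    genus_fam <- integer(0)
    next_genus <- 0L
    for (f in unique(fam_id)) {
      idx <- which(fam_id == f)
      k <- max(min(2L, length(idx)), ceiling(length(idx) / 3))
      g <- next_genus + sample.int(k, length(idx), replace = TRUE)
      genus_id[idx] <- g
      genus_fam <- c(genus_fam, rep(f, k))
      next_genus <- next_genus + k
    }
    z1 <- rnorm(n)
    rho <- config$freq_train_correlation
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    frequency <- pmin(.max_grid_cells,
                      pmax(1, round(config$freq_mean + config$freq_sd * z1)))
    n_train <- pmax(1, round(exp(config$train_meanlog +
                                   config$train_sdlog * z2)))
    data.frame(
      accepted_name = sprintf("Genus_%03d species_%03d", genus_id,
                              seq_len(n)),
      genus = sprintf("Genus_%03d", genus_id),
      family = sprintf("Family_%02d", fam_id),
      growth_form = .sample_cat(n, .growth_forms),
      life_form = .sample_cat(n, .life_forms),
      habitat = .sample_cat(n, .habitats),
      frequency = as.integer(frequency),
      n_training_images = as.integer(n_train),
      stringsAsFactors = FALSE)
  })
}

# Taxonomy backbone for a simulated pool, including decoy accepted names so
# genus- and family-level suggestions resolve: one same-genus decoy species
# per genus and one extra-genus decoy per family.
.simulated_taxonomy <- function(species) {
  gen <- unique(species[, c("genus", "family")])
  fam <- unique(species$family)
  accepted <- rbind(
    species[, c("accepted_name", "genus", "family")],
    data.frame(accepted_name = paste(gen$genus, "decoyspecies"),
               genus = gen$genus, family = gen$family,
               stringsAsFactors = FALSE),
    data.frame(accepted_name = paste0("Genusdecoy_", fam, " nulla"),
               genus = paste0("Genusdecoy_", fam), family = fam,
               stringsAsFactors = FALSE))
  taxonomy_map(accepted)
}

#' Generate synthetic observations with known ground truth
#'
#' For each species a uniform number of replicate observations per setting is
#' drawn, image annotations come from the configured categorical
#' distributions, and the identification class follows the sequential
#' outcome model. The suggested name is written so that
#' [classify_observation()] reproduces the drawn class exactly: the verified
#' name on success, a same-genus decoy for a genus-level outcome, a
#' same-family decoy for a family-level outcome, and an empty suggestion for
#' `none`.
#'
#' @param species species table from [generate_species_table()].
#' @param config the same [simulation_config()].
#' @return A list with `observations` (table), `truth` (class
#'   `simulation_truth`: config echo, species random intercepts, realized
#'   class counts) and `taxonomy` (the backbone incl. decoy names).
#' @export
generate_observations <- function(species, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(species))
    stop("species table is empty; nothing to observe", call. = FALSE)
  species <- validate_species(species)
  taxonomy <- .simulated_taxonomy(species)
  with_substream(config$seed, "observations", {
    n_sp <- nrow(species)
    u <- rnorm(n_sp, 0, config$sd_species)
    names(u) <- species$accepted_name

    one_setting <- function(setting) {
      rr <- config$replicate_range[[setting]]
      reps <- rr[1] + floor(runif(n_sp) * (rr[2] - rr[1] + 1L))
      sp_idx <- rep.int(seq_len(n_sp), reps)
      m <- length(sp_idx)
      cp <- config$covariate_probabilities
      organs <- .sample_cat(m, cp$organs)
      focus <- .sample_cat(m, cp$focus)
      background <- .sample_cat(m, cp$background)
      lin <- config$baseline_logit +
        config$beta_ln_train * log(species$n_training_images[sp_idx]) +
        config$organ_effects[organs] +
        config$focus_effect * (focus == "multiple") +
        config$background_effects[background] +
        u[sp_idx]
      success <- runif(m) < plogis(lin)
      to_genus <- runif(m) < config$p_genus_given_fail
      to_family <- runif(m) < config$p_family_given_genus_fail
      cls <- ifelse(success, "species",
                    ifelse(to_genus, "genus",
                           ifelse(to_family, "family", "none")))
      suggested <- character(m)
      suggested[cls == "species"] <-
        species$accepted_name[sp_idx[cls == "species"]]
      suggested[cls == "genus"] <-
        paste(species$genus[sp_idx[cls == "genus"]], "decoyspecies")
      suggested[cls == "family"] <-
        paste0("Genusdecoy_", species$family[sp_idx[cls == "family"]],
               " nulla")
      suggested[cls == "none"] <- ""
      data.frame(
        obs_id = sprintf("%s_%05d", substr(setting, 1, 2), seq_len(m)),
        setting = setting,
        verified_name = species$accepted_name[sp_idx],
        suggested_name = suggested,
        organs = organs, focus = focus, background = background,
        true_class = cls,
        stringsAsFactors = FALSE)
    }
    obs <- rbind(one_setting("database"), one_setting("field"))
    counts <- table(factor(obs$true_class, levels = identification_classes()))
    truth <- structure(list(config = config,
                            species_intercepts = u,
                            class_counts = as.integer(counts)),
                       class = "simulation_truth")
    names(truth$class_counts) <- identification_classes()
    list(observations = obs, truth = truth, taxonomy = taxonomy)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth: realized class counts\n")
  print(x$class_counts)
  invisible(x)
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper: species pool, observations and taxonomy in one call.
#'
#' @param config a [simulation_config()].
#' @return Object of class `florastat_simulation`: list with `species`,
#'   `observations`, `taxonomy`, `truth` and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  species <- generate_species_table(config)
  out <- generate_observations(species, config)
  structure(list(species = species, observations = out$observations,
                 taxonomy = out$taxonomy, truth = out$truth,
                 config = config),
            class = "florastat_simulation")
}

#' @export
print.florastat_simulation <- function(x, ...) {
  cat(sprintf("florastat_simulation: %d species, %d observations (%s)\n",
              nrow(x$species), nrow(x$observations),
              paste(sprintf("%s: %d", names(table(x$observations$setting)),
                            table(x$observations$setting)), collapse = ", ")))
  invisible(x)
}
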