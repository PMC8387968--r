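# Shared in-code fixtures: a tiny hand-written taxonomy and observation
# builders. All larger inputs are generated by the package's own simulator.

tiny_taxonomy <- function() {
  taxonomy_map(
    accepted = data.frame(
      accepted_name = c("Trifolium pratense", "Trifolium repens",
                        "Medicago sativa", "Dactylorhiza majalis",
                        "Poa annua"),
      genus = c("Trifolium", "Trifolium", "Medicago", "Dactylorhiza", "Poa"),
      family = c("Fabaceae", "Fabaceae", "Fabaceae", "Orchidaceae",
                 "Poaceae"),
      stringsAsFactors = FALSE),
    synonyms = data.frame(
      synonym = "Dactylorhiza baltica",
      accepted_name = "Dactylorhiza majalis",
      stringsAsFactors = FALSE))
}

# Minimal classified observation table; classes given directly.
make_obs <- function(species, classes, setting = "database",
                     organs = "both", focus = "single",
                     background = "vegetation") {
  n <- max(length(species), length(classes))
  data.frame(
    obs_id = sprintf("%s_%04d", substr(setting[1], 1, 2), seq_len(n)),
    setting = rep_len(setting, n),
    verified_name = rep_len(species, n),
    suggested_name = "",
    organs = rep_len(organs, n),
    focus = rep_len(focus, n),
    background = rep_len(background, n),
    class = rep_len(classes, n),
    stringsAsFactors = FALSE)
}

# Species table with controllable traits for resampling/association tests.
make_species <- function(names, frequency = 100, n_train = 50,
                         family = "Family_01", growth_form = "herb",
                         life_form = "hemicryptophyte",
                         habitat = "grassland") {
  n <- length(names)
  data.frame(
    accepted_name = names,
    genus = vapply(strsplit(names, " "), `[`, "", 1),
    family = rep_len(family, n),
    growth_form = rep_len(growth_form, n),
    life_form = rep_len(life_form, n),
    habitat = rep_len(habitat, n),
    frequency = rep_len(frequency, n),
    n_training_images = rep_len(n_train, n),
    stringsAsFactors = FALSE)
}

# A hand-buildable stand-in for a fitted model, for closed-form checks of the
# Wald and marginal-means arithmetic.
fake_fit <- function(coefficients, vcov, factors, assign) {
  structure(list(coefficients = coefficients, vcov = vcov,
                 factors = factors, fixed_terms = names(factors),
                 assign = assign),
            class = "glmm_fit")
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(
  fit_binary_mixed(...)))
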