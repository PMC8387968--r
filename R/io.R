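# Reading, validating and writing the flat observation / species tables.
# CSV (UTF-8, header row) is the interchange format throughout.

#' Validate an observation table
#'
#' Checks the closed vocabularies (setting, organs, focus, background),
#' non-empty verified names and unique observation ids. Errors name the
#' offending row and value.
#'
#' @param observations data.frame with columns `obs_id`, `setting`,
#'   `verified_name`, `suggested_name`, `organs`, `focus`, `background`.
#' @return The table, with character columns coerced, invisibly usable.
#' @export
validate_observations <- function(observations) {
  missing_cols <- setdiff(.obs_columns, names(observations))
  if (length(missing_cols))
    stop("observation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  obs <- observations
  for (col in .obs_columns) obs[[col]] <- as.character(obs[[col]])
  obs$suggested_name[is.na(obs$suggested_name)] <- ""

  .check_vocab <- function(col, vocab) {
    bad <- which(!(obs[[col]] %in% vocab))
    if (length(bad))
      stop(sprintf("row %d: invalid %s value '%s' (allowed: %s)",
                   bad[1], col, obs[[col]][bad[1]],
                   paste(vocab, collapse = ", ")), call. = FALSE)
  }
  .check_vocab("setting", .settings)
  .check_vocab("organs", .organ_levels)
  .check_vocab("focus", .focus_levels)
  .check_vocab("background", .background_levels)

  empty <- which(is.na(obs$verified_name) | trimws(obs$verified_name) == "")
  if (length(empty))
    stop(sprintf("row %d: empty verified_name", empty[1]), call. = FALSE)
  dup <- which(duplicated(obs$obs_id))
  if (length(dup))
    stop(sprintf("duplicate obs_id '%s' (row %d)", obs$obs_id[dup[1]],
                 dup[1]), call. = FALSE)
  obs
}

#' Validate a species-trait table
#'
#' @param species data.frame with columns `accepted_name`, `genus`, `family`,
#'   `growth_form`, `life_form`, `habitat`, `frequency` (occupied atlas grid
#'   cells, at most 540) and `n_training_images`.
#' @return The validated table.
#' @export
validate_species <- function(species) {
  missing_cols <- setdiff(.species_columns, names(species))
  if (length(missing_cols))
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sp <- species
  if (anyDuplicated(sp$accepted_name))
    stop("duplicate accepted_name in species table", call. = FALSE)
  freq <- sp$frequency
  if (any(!is.finite(freq)) || any(freq < 1 | freq > .max_grid_cells) ||
      any(freq != floor(freq)))
    stop(sprintf("frequency must be an integer count of grid cells in [1, %d]",
                 .max_grid_cells), call. = FALSE)
  tr <- sp$n_training_images
  if (any(!is.finite(tr)) || any(tr < 1) || any(tr != floor(tr)))
    stop("n_training_images must be a positive integer", call. = FALSE)
  sp
}

#' Load observation (and species) tables from CSV
#'
#' Reads the flat observation table and, if given, the species-trait table,
#' validating vocabularies, duplicate ids and trait ranges.
#'
#' @param obs_path path to the observations CSV.
#' @param species_path optional path to the species CSV.
#' @param quiet suppress the row-count message.
#' @return A list with elements `observations` and `species` (the latter
#'   `NULL` when no species table is given).
#' @export
load_observations <- function(obs_path, species_path = NULL, quiet = FALSE) {
  if (!file.exists(obs_path))
    stop("observations file not found: ", obs_path, call. = FALSE)
  obs <- read.csv(obs_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  obs <- validate_observations(obs)
  if (!quiet) {
    counts <- table(obs$setting)
    message(sprintf("loaded %d observations (%s)", nrow(obs),
                    paste(sprintf("%s: %d", names(counts), counts),
                          collapse = ", ")))
  }
  species <- NULL
  if (!is.null(species_path)) {
    if (!file.exists(species_path))
      stop("species file not found: ", species_path, call. = FALSE)
    species <- read.csv(species_path, stringsAsFactors = FALSE)
    species$frequency <- as.numeric(species$frequency)
    species$n_training_images <- as.numeric(species$n_training_images)
    species <- validate_species(species)
  }
  list(observations = obs, species = species)
}

#' Load a taxonomy map from CSV files
#'
#' @param accepted_path three-column CSV (`accepted_name`, `genus`, `family`).
#' @param synonyms_path optional two-column CSV (`synonym`, `accepted_name`).
#' @return A [taxonomy_map()].
#' @export
load_taxonomy <- function(accepted_path, synonyms_path = NULL) {
  accepted <- read.csv(accepted_path, stringsAsFactors = FALSE)
  synonyms <- if (!is.null(synonyms_path) && file.exists(synonyms_path))
    read.csv(synonyms_path, stringsAsFactors = FALSE) else NULL
  taxonomy_map(accepted, synonyms)
}

#' Write a simulated dataset to a directory
#'
#' Writes `observations.csv`, `species.csv`, `taxonomy_accepted.csv`,
#' `taxonomy_synonyms.csv` and `truth.json` so a simulated study can be
#' re-loaded with [load_observations()] / [load_taxonomy()].
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "florastat_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  write.csv(sim$species, file.path(dir, "species.csv"), row.names = FALSE)
  write.csv(sim$taxonomy$accepted, file.path(dir, "taxonomy_accepted.csv"),
            row.names = FALSE)
  syn <- data.frame(synonym = names(sim$taxonomy$synonym_lookup),
                    accepted_name = unname(sim$taxonomy$synonym_lookup),
                    stringsAsFactors = FALSE)
  write.csv(syn, file.path(dir, "taxonomy_synonyms.csv"), row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(config = truth$config[setdiff(names(truth$config), "class")],
         species_intercepts = as.list(truth$species_intercepts),
         class_counts = as.list(truth$class_counts)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
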