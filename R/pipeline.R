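# Run configuration and end-to-end orchestration: one master seed, named
# substreams per stage, CSV outputs plus a JSON manifest, so a whole
# analysis is reproducible from a single small config file.

.config_defaults <- function() {
  list(input = NULL, simulate = NULL,
       n_iterations = 1000L, alpha = 0.05,
       flag_lower = 0.05, flag_upper = 0.95,
       min_group_size = 10L, min_obs_glmm = 3L,
       fisher_B = 2000L, cell_n_rand = 1000L,
       use_alternatives = FALSE,
       seed = 1L, output_dir = "florastat_run")
}

# yaml turns vectors into lists; coerce a simulate block back into the
# shapes simulation_config() expects.
.as_sim_config <- function(block) {
  block <- as.list(block)
  for (f in c("organ_effects", "background_effects"))
    if (!is.null(block[[f]])) block[[f]] <- unlist(block[[f]])
  if (!is.null(block$covariate_probabilities))
    block$covariate_probabilities <-
      lapply(block$covariate_probabilities, unlist)
  if (!is.null(block$replicate_range))
    block$replicate_range <- lapply(block$replicate_range,
                                    function(x) as.integer(unlist(x)))
  do.call(simulation_config, block)
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML/JSON file path or a named list; fills documented defaults
#' (1000 iterations, alpha 0.05, flag thresholds 0.05/0.95, minimum family
#' size 10, minimum 3 observations per species in the mixed model), rejects
#' unknown keys and out-of-range values, and normalizes the `simulate` block
#' into a [simulation_config()]. Normalization is idempotent.
#'
#' @param config file path or named list; an empty file yields all defaults.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "run_config")) config <- unclass(config)
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config))
    stop("config must be a file path or a named list", call. = FALSE)
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  for (nm in names(defaults))        # modifyList drops NULL-valued keys
    if (!nm %in% names(cfg)) cfg[nm] <- list(NULL)
  cfg <- cfg[names(defaults)]

  for (f in c("n_iterations", "min_group_size", "min_obs_glmm", "fisher_B",
              "cell_n_rand"))
    cfg[[f]] <- .check_count(cfg[[f]], f)
  cfg$seed <- .check_count(cfg$seed, "seed", min = 0)
  for (f in c("alpha", "flag_lower", "flag_upper"))
    .check_prob(cfg[[f]], f)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    .stop_config("alpha", "must lie strictly in (0, 1)")
  if (abs(cfg$flag_lower - (1 - cfg$flag_upper)) > 1e-9)
    .stop_config("flag_lower", "must equal 1 - flag_upper")
  if (!is.logical(cfg$use_alternatives) || length(cfg$use_alternatives) != 1)
    .stop_config("use_alternatives", "must be TRUE or FALSE")
  if (!is.null(cfg$input)) {
    need <- c("observations", "species", "taxonomy_accepted")
    missing_keys <- setdiff(need, names(cfg$input))
    if (length(missing_keys))
      .stop_config("input", paste("must name files:",
                                  paste(missing_keys, collapse = ", ")))
  }
  if (!is.null(cfg$simulate) && !inherits(cfg$simulate, "simulation_config"))
    cfg$simulate <- .as_sim_config(cfg$simulate)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  src <- if (!is.null(x$simulate)) "simulated data" else "loaded data"
  cat(sprintf("run_config: %s, %d iterations, seed %d, out '%s'\n",
              src, x$n_iterations, x$seed, x$output_dir))
  invisible(x)
}

.write_stage_csv <- function(df, dir, name, files) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  c(files, name)
}

#' Run the full evaluation pipeline
#'
#' Executes load/simulate, classification, per-setting subsampling, the
#' paired setting comparison, grouped class analyses (family, growth form,
#' life form, habitat), the median-frequency null model, the
#' image-characteristics mixed model and the training-image association
#' analyses, writing each stage's CSV plus a JSON run manifest and a
#' human-readable summary to the output directory. Identical config and
#' seed give a byte-identical bundle.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @param output_dir overrides the config's output directory.
#' @return Object of class `florastat_run` (invisibly): all stage results
#'   plus the output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- validate_config(config)
  if (is.null(cfg$input) && is.null(cfg$simulate))
    .stop_config("input", "or 'simulate' block must be present to run")
  dir <- if (is.null(output_dir)) cfg$output_dir else output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- "configuration"
  seed <- cfg$seed
  res <- list(config = cfg)

  write_manifest <- function(complete) {
    manifest <- list(
      package = "florastat",
      version = as.character(utils::packageVersion("florastat")),
      seed = seed,
      n_iterations = cfg$n_iterations,
      data_source = if (!is.null(cfg$simulate)) "simulated" else "loaded",
      n_observations = if (!is.null(res$observations))
        nrow(res$observations) else 0L,
      n_species = if (!is.null(res$species)) nrow(res$species) else 0L,
      files = as.list(files),
      complete = complete,
      failed_stage = if (complete) NULL else stage)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      write_manifest(FALSE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- data -----------------------------------------------------------------
  run_stage("data", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_dataset(cfg$simulate)
      res$simulation <- sim
      res$species <- sim$species
      res$taxonomy <- sim$taxonomy
      obs <- sim$observations
      write_dataset(sim, file.path(dir, "data"))
      files <- c(files, file.path("data", c("observations.csv",
                                             "species.csv",
                                             "taxonomy_accepted.csv",
                                             "taxonomy_synonyms.csv",
                                             "truth.json")))
    } else {
      loaded <- load_observations(cfg$input$observations,
                                  cfg$input$species, quiet = TRUE)
      res$species <- loaded$species
      res$taxonomy <- load_taxonomy(cfg$input$taxonomy_accepted,
                                     cfg$input$taxonomy_synonyms)
      obs <- loaded$observations
    }
    res$observations <- classify_observations(
      obs, res$taxonomy, use_alternatives = cfg$use_alternatives)
  })
  obs <- res$observations

  # --- per-setting subsampling ---------------------------------------------
  run_stage("subsampling", {
    summaries <- lapply(setNames(.settings, .settings), function(s) {
      sub <- obs[obs$setting == s, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      iterate_subsample(sub, n_iter = cfg$n_iterations,
                        seed = substream_seed(seed, paste0("stage/", s)))
    })
    res$settings <- summaries
    rows <- do.call(rbind, lapply(names(summaries), function(s) {
      x <- summaries[[s]]
      if (is.null(x)) return(NULL)
      data.frame(setting = s, class = identification_classes(),
                 mean_percent = unname(x$averaged),
                 mc_se = unname(x$mc_se), stringsAsFactors = FALSE)
    }))
    files <- .write_stage_csv(rows, dir, "class_percentages.csv", files)
  })

  # --- paired comparison ----------------------------------------------------
  run_stage("paired_comparison", {
    db <- obs[obs$setting == "database", , drop = FALSE]
    fi <- obs[obs$setting == "field", , drop = FALSE]
    if (nrow(db) && nrow(fi)) {
      cmp <- compare_settings(db, fi, n_iter = cfg$n_iterations,
                              seed = substream_seed(seed, "stage/paired"),
                              alpha = cfg$alpha)
      res$paired <- cmp
      files <- .write_stage_csv(
        data.frame(class = identification_classes(),
                   database_percent = unname(cmp$averaged_database),
                   field_percent = unname(cmp$averaged_field),
                   p_field_higher = unname(cmp$exceedance),
                   tie_mass = unname(cmp$tie_mass),
                   significant = unname(cmp$significant)),
        dir, "paired_comparison.csv", files)
    }
  })

  # --- merged stream for grouped + frequency analyses -----------------------
  run_stage("merged_subsampling", {
    res$merged <- iterate_subsample(
      obs, n_iter = cfg$n_iterations,
      seed = substream_seed(seed, "stage/merged"))
  })

  run_stage("grouped_analysis", {
    fisher_rows <- NULL
    for (g in c("family", "growth_form", "life_form", "habitat")) {
      ga <- grouped_class_analysis(
        res$merged, res$species, grouping = g,
        min_group_size = if (g == "family") cfg$min_group_size else 2L,
        fisher_B = cfg$fisher_B, n_rand = cfg$cell_n_rand,
        seed = substream_seed(seed, paste0("stage/grouped/", g)),
        lower = cfg$flag_lower, upper = cfg$flag_upper)
      res$grouped[[g]] <- ga
      long <- expand.grid(group = rownames(ga$percent),
                          class = colnames(ga$percent),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      long$n_species <- as.integer(ga$group_sizes[long$group])
      long$mean_percent <- ga$percent[cbind(long$group, long$class)]
      long$z <- ga$cells$z[cbind(long$group, long$class)]
      long$prob <- ga$cells$prob[cbind(long$group, long$class)]
      long$flag <- ga$cells$flag[cbind(long$group, long$class)]
      files <- .write_stage_csv(long, dir, paste0("grouped_", g, ".csv"),
                                 files)
      fisher_rows <- rbind(fisher_rows, data.frame(
        grouping = g, median_p = ga$fisher$median_p,
        max_p = ga$fisher$max_p, stringsAsFactors = FALSE))
    }
    files <- .write_stage_csv(fisher_rows, dir, "fisher_summary.csv", files)
  })

  run_stage("frequency_null", {
    fn <- frequency_null_test(res$merged, res$species,
                              seed = substream_seed(seed, "stage/freqnull"))
    res$frequency_null <- fn
    files <- .write_stage_csv(
      data.frame(class = identification_classes(),
                 median_frequency = unname(fn$median_frequency),
                 p = unname(fn$p_value)),
      dir, "frequency_null.csv", files)
  })

  # --- image-characteristics mixed model ------------------------------------
  run_stage("glmm", {
    fit <- fit_binary_mixed(obs, min_obs = cfg$min_obs_glmm)
    res$glmm <- fit
    wald <- type3_wald(fit)
    res$wald <- wald
    files <- .write_stage_csv(wald, dir, "glmm_wald.csv", files)
    emm_rows <- do.call(rbind, lapply(fit$fixed_terms, function(f) {
      em <- estimated_marginal_means(fit, f, alpha = cfg$alpha)
      res$emmeans[[f]] <- em
      cbind(data.frame(factor = f, stringsAsFactors = FALSE), em$emm)
    }))
    files <- .write_stage_csv(emm_rows, dir, "glmm_emmeans.csv", files)
  })

  # --- training-image association -------------------------------------------
  run_stage("association", {
    succ <- species_success(obs)
    res$success <- succ
    tc <- suppressMessages(training_correlation(succ, res$species))
    res$training_correlation <- tc
    files <- .write_stage_csv(
      data.frame(r = tc$r, n = tc$n, p = tc$p, transform = tc$transform),
      dir, "training_correlation.csv", files)
    gt_rows <- NULL
    for (g in c("family", "growth_form", "life_form", "habitat")) {
      gt <- suppressWarnings(
        group_training_comparison(res$species, g, alpha = cfg$alpha))
      res$group_training[[g]] <- gt
      gt_rows <- rbind(gt_rows, cbind(
        data.frame(grouping = g, F = gt$anova$F, df1 = gt$anova$df1,
                   df2 = gt$anova$df2, p = gt$anova$p,
                   stringsAsFactors = FALSE)[rep(1, nrow(gt$means)), ],
        gt$means))
    }
    rownames(gt_rows) <- NULL
    files <- .write_stage_csv(gt_rows, dir, "group_training.csv", files)
  })

  # --- summary + manifest ---------------------------------------------------
  run_stage("report", {
    lines <- c("florastat run summary", "=====================", "")
    for (s in .settings) {
      x <- res$settings[[s]]
      if (is.null(x)) next
      lines <- c(lines, sprintf(
        "%s: %.1f%% species, %.1f%% at least genus, %.1f%% at least family (%d species)",
        s, x$cumulative[1], x$cumulative[2], x$cumulative[3],
        length(x$species)))
    }
    if (!is.null(res$paired))
      lines <- c(lines, sprintf(
        "paired comparison over %d common species: exceedance %s",
        res$paired$n_common,
        paste(sprintf("%s %.3f", identification_classes(),
                      res$paired$exceedance), collapse = ", ")))
    lines <- c(lines, sprintf(
      "family analysis: Fisher median P = %.4g, max P = %.4g",
      res$grouped$family$fisher$median_p, res$grouped$family$fisher$max_p))
    lines <- c(lines, sprintf(
      "training-image correlation: r = %.3f (n = %d, P = %.3g)",
      res$training_correlation$r, res$training_correlation$n,
      res$training_correlation$p))
    writeLines(lines, file.path(dir, "summary.txt"))
    files <- c(files, "summary.txt")
    write_manifest(TRUE)
    files <- c(files, "manifest.json")
  })

  res$output_dir <- dir
  res$files <- files
  class(res) <- "florastat_run"
  invisible(res)
}

#' @export
print.florastat_run <- function(x, ...) {
  cat(sprintf("florastat_run: %d files in '%s'\n", length(x$files),
              x$output_dir))
  cat(readLines(file.path(x$output_dir, "summary.txt")), sep = "\n")
  invisible(x)
}
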