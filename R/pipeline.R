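# End-to-end orchestration: simulate/ingest -> preprocess -> train (lab) and
# quantify -> predict -> report (field), with config, logging and
# provenance.  A thin command-line wrapper over these functions ships in
# inst/scripts/phospec-cli.R.

#' Default run configuration
#'
#' Nested configuration for the pipeline stages.  A single top-level seed is
#' fanned out to per-stage seeds (`(seed mod 1e6) * 1000 + stage offset`) so
#' each stage is independently reproducible.
#'
#' @param seed Top-level seed.
#' @return A list of class `run_config` with `simulate`, `preprocess`,
#'   `model` and `stats` sub-configurations.
#' @export
default_run_config <- function(seed = 1) {
  structure(
    list(
      seed = as.integer(seed),
      simulate = list(
        scenario = "lab",
        n_replicates = 9, dead_low_p = 3, tech_reps = 3,
        n_plants = 30, site_effect = 1,
        noise_sd = 0.003, plant_sdlog_lab = 0.05, plant_sdlog_field = 0.12
      ),
      input = list(spectra = NULL, metadata = NULL, format = "wide-csv",
                   targets = NULL),
      # the regression is trained on baseline-corrected absorbance, so the
      # model path leaves spectra unnormalized (band ratios such as C/L are
      # scale-invariant either way); figure-style normalization remains
      # available through preprocess_config()
      preprocess = list(
        baseline_method = "rubber-band",
        normalization = "none",
        norm_region = c(800, 1800),
        replicate_policy = "average",
        region = c(800, 1800)
      ),
      model = list(
        n_resamples = 6000, folds = 10, max_components = 41,
        target = "p_conc", target_transform = "log10", unit = "plant"
      ),
      stats = list(variant = "welch", adjust = "holm",
                   signatures = c("Pi", "Po", "cl_ratio"))
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default value.  The merged configuration is validated before any stage
#' runs.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    ps_error(sprintf("config file not found: %s", path), "phospec_io_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1)
  for (section in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      cfg[[section]] <- utils::modifyList(cfg[[section]], user[[section]])
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # sub-configs must validate before any stage runs
  build_preprocess_config(config)
  with(config$model, stopifnot(
    n_resamples >= 1, folds >= 2, max_components >= 1,
    target_transform %in% c("log10", "identity")
  ))
  invisible(config)
}

build_preprocess_config <- function(config) {
  pp <- config$preprocess
  preprocess_config(
    baseline_method = pp$baseline_method %||% "rubber-band",
    normalization = pp$normalization %||% "per-spectrum-region-max",
    norm_region = as.numeric(pp$norm_region %||% c(800, 1800)),
    replicate_policy = pp$replicate_policy %||% "average",
    region = as.numeric(pp$region %||% c(800, 1800))
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

run_log <- function(path, lines, config) {
  writeLines(c(
    sprintf("# phospec run log | config_hash=%s | %s",
            config_hash(config), format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    lines
  ), path)
}

stage_line <- function(stage, t0, detail) {
  sprintf("%s | %.2fs | %s", stage,
          as.numeric(difftime(Sys.time(), t0, units = "secs")), detail)
}

ingest_spectra <- function(config, scenario, outdir) {
  t0 <- Sys.time()
  sim <- config$simulate
  if (!is.null(config$input$spectra)) {
    set <- tryCatch(
      read_spectra(config$input$spectra, format = config$input$format,
                   metadata_path = config$input$metadata),
      error = function(e) {
        ps_error(sprintf("stage ingest failed on '%s': %s",
                         config$input$spectra, conditionMessage(e)),
                 "phospec_stage_error")
      }
    )
    truth <- NULL
  } else if (scenario == "lab") {
    dat <- simulate_lab_dataset(
      seed = stage_seed(config$seed, "simulate"),
      n_replicates = sim$n_replicates, dead_low_p = sim$dead_low_p,
      tech_reps = sim$tech_reps, noise_sd = sim$noise_sd,
      plant_sdlog = sim$plant_sdlog_lab
    )
    set <- dat$spectra
    truth <- dat$truth
  } else {
    dat <- simulate_field_dataset(
      seed = stage_seed(config$seed, "simulate"),
      n_plants = sim$n_plants, site_effect = sim$site_effect,
      noise_sd = sim$noise_sd, plant_sdlog = sim$plant_sdlog_field
    )
    set <- dat$spectra
    truth <- dat$plants
  }
  list(set = set, truth = truth,
       log = stage_line("ingest", t0, sprintf("%d spectra", n_spectra(set))))
}

#' Run the lab training pipeline
#'
#' simulate (or ingest) -> preprocess -> bootstrap_train; writes the model
#' JSON, the learning-curve table, the ground-truth/targets table and a run
#' log to `outdir`.  Re-running with the same config yields byte-identical
#' artifacts.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with `model`, `cv` and the artifact `paths`.
#' @export
run_lab_training <- function(config = default_run_config(), outdir) {
  validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)

  ing <- ingest_spectra(config, "lab", outdir)
  logs <- c(logs, ing$log)

  t0 <- Sys.time()
  pp <- preprocess_set(ing$set, build_preprocess_config(config))
  logs <- c(logs, stage_line("preprocess", t0,
                             sprintf("%d spectra", n_spectra(pp$set))))

  t0 <- Sys.time()
  if (!is.null(ing$truth)) {
    targets <- stats::setNames(
      ing$truth[[config$model$target]], ing$truth$plant_id
    )
  } else if (!is.null(config$input$targets)) {
    tt <- utils::read.csv(config$input$targets)
    targets <- stats::setNames(tt[[config$model$target]], tt[[1]])
  } else {
    ps_error("no targets available: simulated truth or input$targets needed",
             "phospec_stage_error")
  }
  trained <- bootstrap_train(
    pp$set, targets,
    n_resamples = config$model$n_resamples, unit = config$model$unit,
    folds = config$model$folds, max_components = config$model$max_components,
    seed = stage_seed(config$seed, "train"),
    target_transform = config$model$target_transform
  )
  logs <- c(logs, stage_line("train", t0, sprintf(
    "%d components selected, MSEP %.5g",
    trained$cv$selected_components,
    trained$cv$msep_by_components[trained$cv$selected_components]
  )))

  paths <- list(
    model = file.path(outdir, "pcr_model.json"),
    learning_curve = file.path(outdir, "learning_curve.csv"),
    targets = file.path(outdir, "training_targets.csv"),
    log = file.path(outdir, "run_lab.log")
  )
  write_pcr_model(trained$model, paths$model)
  utils::write.csv(
    data.frame(
      n_components = seq_along(trained$cv$msep_by_components),
      msep = unname(trained$cv$msep_by_components)
    ),
    paths$learning_curve, row.names = FALSE
  )
  utils::write.csv(
    data.frame(unit = names(targets), target = unname(targets)),
    paths$targets, row.names = FALSE
  )
  run_log(paths$log, logs, config)
  invisible(list(model = trained$model, cv = trained$cv, paths = paths))
}

#' Run the field analysis pipeline
#'
#' simulate (or ingest) -> preprocess -> quantify -> predict -> report:
#' writes the per-sample profile table, predictions, the site-by-timepoint
#' season summary, pairwise consecutive-timepoint comparisons per site and
#' signature, the senescence Pi/Po vs second-year biomass association, and a
#' run log.
#'
#' @param config A `run_config`; field spectra are simulated unless
#'   `config$input$spectra` is set.
#' @param model_file Path to a model JSON written by [run_lab_training()].
#' @param outdir Output directory.
#' @return Invisibly, a list with `profiles`, `predictions`, `season`,
#'   `pairwise`, `association` and the artifact `paths`.
#' @export
run_field_analysis <- function(config = default_run_config(), model_file,
                               outdir) {
  validate_run_config(config)
  if (!file.exists(model_file)) {
    ps_error(sprintf("model file not found: %s", model_file),
             "phospec_io_error")
  }
  model <- read_pcr_model(model_file)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)

  ing <- ingest_spectra(config, "field", outdir)
  logs <- c(logs, ing$log)

  t0 <- Sys.time()
  ppc <- build_preprocess_config(config)
  ppc$replicate_policy <- "keep-all"  # one spectrum per plant-timepoint
  pp <- preprocess_set(ing$set, ppc)
  logs <- c(logs, stage_line("preprocess", t0,
                             sprintf("%d spectra", n_spectra(pp$set))))

  t0 <- Sys.time()
  profiles <- quantify_set(pp$set)
  logs <- c(logs, stage_line("quantify", t0,
                             sprintf("%d profiles", nrow(profiles))))

  t0 <- Sys.time()
  predictions <- predict_available(model, pp$set)
  logs <- c(logs, stage_line("predict", t0,
                             sprintf("%d predictions", nrow(predictions))))

  t0 <- Sys.time()
  season <- season_table(profiles, predictions,
                         signatures = c("Pi", "Po", "cellulose", "lignin",
                                        "amide", "lipid", "cl_ratio"))
  pairwise <- do.call(rbind, lapply(unique(profiles$site), function(s) {
    do.call(rbind, lapply(config$stats$signatures, function(sig) {
      pairwise_timepoints(profiles, sig, s,
                          variant = config$stats$variant,
                          adjust = config$stats$adjust)
    }))
  }))
  t5 <- profiles[profiles$timepoint == "T5", ]
  t5$pi_po <- pi_po_ratio(t5)
  association <- if (!is.null(ing$truth)) {
    t5$second_year_biomass <- ing$truth$second_year_biomass[
      match(t5$sample_id, ing$truth$sample_id)
    ]
    do.call(rbind, lapply(unique(t5$site), function(s) {
      res <- ratio_biomass_association(t5[t5$site == s, ])
      res$site <- s
      res
    }))
  } else {
    NULL
  }
  logs <- c(logs, stage_line("report", t0, sprintf(
    "%d season rows, %d pairwise comparisons", nrow(season), nrow(pairwise)
  )))

  paths <- list(
    profiles = file.path(outdir, "profiles.csv"),
    predictions = file.path(outdir, "predictions.csv"),
    season = file.path(outdir, "season_summary.csv"),
    pairwise = file.path(outdir, "pairwise_timepoints.csv"),
    association = file.path(outdir, "biomass_association.csv"),
    log = file.path(outdir, "run_field.log")
  )
  utils::write.csv(profiles, paths$profiles, row.names = FALSE)
  utils::write.csv(predictions, paths$predictions, row.names = FALSE)
  utils::write.csv(season, paths$season, row.names = FALSE)
  utils::write.csv(pairwise, paths$pairwise, row.names = FALSE)
  if (!is.null(association)) {
    utils::write.csv(association, paths$association, row.names = FALSE)
  }
  run_log(paths$log, logs, config)
  invisible(list(
    profiles = profiles, predictions = predictions, season = season,
    pairwise = pairwise, association = association, paths = paths
  ))
}
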