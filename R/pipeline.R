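## Pipeline orchestration: staged runs over CSV artifacts with a structured
## YAML config, provenance headers (config hash + seed) on every output, and
## a human-readable report. The exported functions are the primary
## interface; inst/cli/availbias.R is a thin command-line wrapper.

PIPELINE_STAGES <- c("sim-tags", "sim-survey", "prep-tags",
                     "fit-availability", "fit-detection", "fit-dsm",
                     "predict")

default_pipeline_config <- function() {
  list(
    output_dir = "availbias_output",
    seed = 1,
    paths = list(tags = NULL, effort = NULL, sightings = NULL, grid = NULL),
    burn_in_days = 2,
    shelf_threshold = 175,
    mcmc = list(n_iter = 5000, n_burn = 1000, n_chains = 3),
    detection = list(w = 500, key = "hazard_rate",
                     candidate_covariates = list(character(0), "cloud")),
    segment_length_km = 10,
    dsm_covariates = "dist_200m_km",
    average_availability = NULL,   # NULL: use the tag-data pooled mean
    scenarios = c("uncorrected", "average", "modelled")
  )
}

#' Read a pipeline configuration
#'
#' YAML file with any subset of the keys of the default configuration
#' (`output_dir`, `seed`, `paths.tags/effort/sightings/grid`,
#' `burn_in_days`, `shelf_threshold`, `mcmc.*`, `detection.*`,
#' `segment_length_km`, `average_availability`, `scenarios`); unspecified
#' keys keep their defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    merge_in <- function(base, upd) {
      for (k in names(upd)) {
        base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
          merge_in(base[[k]], upd[[k]])
        } else upd[[k]]
      }
      base
    }
    cfg <- merge_in(cfg, user)
  }
  cfg
}

stage_log <- function(...) message("[availbias] ", sprintf(...))

stage_file <- function(cfg, name) file.path(cfg$output_dir, name)

require_artifact <- function(cfg, name, producer) {
  p <- stage_file(cfg, name)
  if (!file.exists(p)) {
    stop("pipeline: missing artifact '", name, "'; run stage '", producer,
         "' first", call. = FALSE)
  }
  p
}

pipeline_provenance <- function(cfg) {
  list(seed = cfg$seed, config_hash = config_hash(cfg),
       package = as.character(utils::packageVersion("availbias")))
}

#' Run one pipeline stage
#'
#' Stages: `sim-tags`, `sim-survey` (synthetic data generation), `prep-tags`
#' (burn-in filter, dive-rule shelf classification, availability table),
#' `fit-availability` (Bayesian ZOIB model + DIC comparison + stratum
#' prediction), `fit-detection` (candidate detection functions + selection),
#' `fit-dsm` (segmentise effort and fit the density surface model per
#' scenario), `predict` (grid abundance per scenario). Each stage writes CSV
#' artifacts with provenance headers into `config$output_dir` and fails with
#' an actionable message naming the producing stage when a prerequisite is
#' missing.
#'
#' @param name stage name (see above).
#' @param config configuration list from [read_pipeline_config()].
#' @return invisibly, a list of paths written.
#' @export
run_stage <- function(name, config = read_pipeline_config()) {
  name <- match.arg(name, PIPELINE_STAGES)
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- pipeline_provenance(cfg)
  out <- list()

  if (name == "sim-tags") {
    sim <- simulate_tags(tag_sim_config(seed = cfg$seed))
    out$tags <- stage_file(cfg, "tags.csv")
    write_depth_records(sim$records, out$tags, provenance = prov)
    writeLines(jsonlite::toJSON(sim$truth$config, auto_unbox = TRUE,
                                digits = NA),
               stage_file(cfg, "tag_truth.json"))
    cfg$paths$tags <- out$tags
    stage_log("sim-tags: wrote %s (%d bins)", out$tags,
              nrow(bins_of(sim$records)))

  } else if (name == "sim-survey") {
    sim <- simulate_survey(survey_sim_config(seed = cfg$seed))
    out$effort <- stage_file(cfg, "effort.csv")
    out$sightings <- stage_file(cfg, "sightings.csv")
    out$grid <- stage_file(cfg, "grid.csv")
    write_csv_provenance(sim$effort[c("transect", "lon", "lat",
                                      "on_effort", "cloud")],
                         out$effort, prov)
    write_csv_provenance(sim$sightings, out$sightings, prov)
    write_csv_provenance(sim$grid[setdiff(names(sim$grid), c("x", "y"))],
                         out$grid, prov)
    writeLines(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, digits = NA),
               stage_file(cfg, "survey_truth.json"))
    stage_log("sim-survey: %d sightings on %.0f km of trackline",
              nrow(sim$sightings), sim$truth$effort_km)

  } else if (name == "prep-tags") {
    tags_path <- cfg$paths$tags %||% stage_file(cfg, "tags.csv")
    if (!file.exists(tags_path)) {
      stop("pipeline: tag file '", tags_path, "' not found; point ",
           "paths.tags at it or run stage 'sim-tags' first", call. = FALSE)
    }
    rec <- read_depth_records(tags_path)
    rec <- filter_burn_in(rec, cfg$burn_in_days)
    shelf <- classify_shelf(rec, mode = "dive-rule",
                            depth_threshold = cfg$shelf_threshold)
    obs <- as_availability(rec, shelf)
    out$availability <- stage_file(cfg, "availability.csv")
    obs_out <- obs
    obs_out$bin_start <- format(obs_out$bin_start, "%Y-%m-%d %H:%M:%S")
    write_csv_provenance(obs_out, out$availability, prov)
    stage_log("prep-tags: %d availability observations (pooled mean %.2f)",
              nrow(obs), average_availability(obs))

  } else if (name == "fit-availability") {
    av_path <- require_artifact(cfg, "availability.csv", "prep-tags")
    obs <- read_csv_provenance(av_path)
    obs$bin_start <- as.POSIXct(obs$bin_start, tz = "UTC")
    mc <- cfg$mcmc
    fit_full <- fit_zoib(obs, terms = c("shelf", "time_bin"),
                         n_iter = mc$n_iter, n_burn = mc$n_burn,
                         n_chains = mc$n_chains, seed = cfg$seed)
    fit_shelf <- fit_zoib(obs, terms = "shelf",
                          n_iter = mc$n_iter, n_burn = mc$n_burn,
                          n_chains = mc$n_chains, seed = cfg$seed)
    cmp <- compare_zoib(list(`shelf+time_bin` = fit_full,
                             shelf_only = fit_shelf))
    best <- if (zoib_dic(fit_full) <= zoib_dic(fit_shelf)) fit_full else fit_shelf
    pred <- predict_availability(best, seed = cfg$seed)
    ## long-format posterior draws
    dr <- zoib_draws(fit_full)
    nkeep <- nrow(fit_full$chains[[1]])
    long <- data.frame(
      chain = rep(seq_len(fit_full$n_chains), each = nkeep * ncol(dr)),
      iter = rep(rep(seq_len(nkeep), each = ncol(dr)), fit_full$n_chains),
      parameter = rep(colnames(dr), nkeep * fit_full$n_chains),
      value = as.vector(t(dr)))
    out$draws <- stage_file(cfg, "posterior_draws.csv")
    out$prediction <- stage_file(cfg, "availability_prediction.csv")
    out$dic <- stage_file(cfg, "dic_comparison.csv")
    write_csv_provenance(long, out$draws, prov)
    write_csv_provenance(pred, out$prediction, prov)
    write_csv_provenance(cmp, out$dic, prov)
    saveRDS(best, stage_file(cfg, "zoib_fit.rds"))
    stage_log("fit-availability: on %.3f / off %.3f (DIC delta %.2f)",
              pred$mean[pred$stratum == "on"],
              pred$mean[pred$stratum == "off"], cmp$delta_dic[2])

  } else if (name == "fit-detection") {
    sg_path <- cfg$paths$sightings %||% stage_file(cfg, "sightings.csv")
    if (!file.exists(sg_path)) {
      stop("pipeline: sightings file '", sg_path, "' not found; point ",
           "paths.sightings at it or run stage 'sim-survey' first",
           call. = FALSE)
    }
    sg <- read_csv_provenance(sg_path)
    pooled <- detection_pool(sg)
    cands <- list()
    for (cv in cfg$detection$candidate_covariates) {
      cv <- unlist(cv)
      nm <- if (!length(cv)) "null" else paste(cv, collapse = "+")
      fm <- if (!length(cv)) ~1 else stats::reformulate(cv)
      fit <- try(fit_detection(pooled, key = cfg$detection$key,
                               formula = fm, w = cfg$detection$w),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) cands[[nm]] <- fit
    }
    if (!length(cands)) stop("pipeline: no detection candidate converged")
    sel <- select_detection_model(cands)
    out$comparison <- stage_file(cfg, "detection_comparison.csv")
    write_csv_provenance(sel$table, out$comparison, prov)
    p_per <- data.frame(sighting_id = pooled$sighting_id %||%
                          seq_len(nrow(pooled)),
                        p = average_p(sel$fit, pooled))
    out$p <- stage_file(cfg, "sighting_p.csv")
    write_csv_provenance(p_per, out$p, prov)
    saveRDS(sel$fit, stage_file(cfg, "detection_fit.rds"))
    stage_log("fit-detection: selected '%s' (mean p %.3f)", sel$selected,
              mean(p_per$p))

  } else if (name == "fit-dsm") {
    eff_path <- cfg$paths$effort %||% stage_file(cfg, "effort.csv")
    grid_path <- cfg$paths$grid %||% stage_file(cfg, "grid.csv")
    sg_path <- cfg$paths$sightings %||% stage_file(cfg, "sightings.csv")
    for (p in c(eff_path, grid_path, sg_path)) {
      if (!file.exists(p)) {
        stop("pipeline: '", p, "' not found; run stage 'sim-survey' or set ",
             "paths.*", call. = FALSE)
      }
    }
    det_path <- require_artifact(cfg, "detection_fit.rds", "fit-detection")
    effort <- read_csv_provenance(eff_path)
    grid <- read_csv_provenance(grid_path)
    sg <- detection_pool(read_csv_provenance(sg_path))
    det <- readRDS(det_path)
    segs <- segmentize(effort, cfg$segment_length_km, grid = grid)
    segs <- segment_counts(segs, sg)
    p_seg <- mean(average_p(det, segs))
    pred <- NULL
    if ("modelled" %in% cfg$scenarios) {
      zp <- require_artifact(cfg, "availability_prediction.csv",
                             "fit-availability")
      pred <- read_csv_provenance(zp)
    }
    avg_const <- cfg$average_availability
    if (is.null(avg_const) && "average" %in% cfg$scenarios) {
      ap <- require_artifact(cfg, "availability.csv", "prep-tags")
      avg_const <- round(average_availability(read_csv_provenance(ap)), 2)
    }
    fits <- list()
    for (sc in cfg$scenarios) {
      a <- scenario_availability(segs, sc, zoib_prediction = pred,
                                 constant = avg_const %||% 0.41)
      fits[[sc]] <- fit_dsm(segs, covariates = cfg$dsm_covariates,
                            availability = a, p_hat = p_seg,
                            w = cfg$detection$w)
      stage_log("fit-dsm[%s]: deviance explained %.1f%%", sc,
                100 * (fits[[sc]]$deviance_explained %||% NA))
    }
    saveRDS(list(fits = fits, p_seg = p_seg, segments = segs,
                 centre = attr(segs, "centre")),
            stage_file(cfg, "dsm_fits.rds"))
    out$segments <- stage_file(cfg, "segments.csv")
    write_csv_provenance(segs, out$segments, prov)

  } else if (name == "predict") {
    dsm_path <- require_artifact(cfg, "dsm_fits.rds", "fit-dsm")
    grid_path <- cfg$paths$grid %||% stage_file(cfg, "grid.csv")
    dsm <- readRDS(dsm_path)
    grid <- read_csv_provenance(grid_path)
    gxy <- project_aeqd(grid$lon, grid$lat, dsm$centre)
    grid$x <- gxy$x; grid$y <- gxy$y
    est <- list(); cells <- list()
    for (sc in names(dsm$fits)) {
      pr <- predict_abundance(dsm$fits[[sc]], grid, seed = cfg$seed)
      est[[sc]] <- cbind(scenario = sc, pr$estimate)
      cells[[sc]] <- cbind(scenario = sc,
                           pr$cells[c("lon", "lat", "density", "abundance")])
    }
    out$abundance <- stage_file(cfg, "abundance.csv")
    out$cells <- stage_file(cfg, "cell_density.csv")
    write_csv_provenance(do.call(rbind, est), out$abundance, prov)
    write_csv_provenance(do.call(rbind, cells), out$cells, prov)
    stage_log("predict: %d scenario estimate(s) written", length(est))
  }
  invisible(out)
}

#' Summarise a completed pipeline run
#'
#' Prints (and returns) the scenario-by-scenario abundance table with CVs and
#' lognormal confidence intervals, the ratio of each corrected estimate to
#' the uncorrected one, and the detection-function comparison. If no
#' sightings were available the report states that estimation was skipped.
#'
#' @param output_dir the pipeline output directory.
#' @return invisibly, a list with `abundance` and `detection` tables.
#' @export
pipeline_report <- function(output_dir) {
  ab_path <- file.path(output_dir, "abundance.csv")
  if (!file.exists(ab_path)) {
    stop("pipeline_report: no abundance table in '", output_dir,
         "'; run stage 'predict' first", call. = FALSE)
  }
  ab <- read_csv_provenance(ab_path)
  if (!nrow(ab) || all(ab$N_hat == 0)) {
    cat("No sightings available: abundance estimation skipped.\n")
    return(invisible(list(abundance = ab, detection = NULL)))
  }
  if ("uncorrected" %in% ab$scenario) {
    ab$ratio_to_uncorrected <-
      ab$N_hat / ab$N_hat[ab$scenario == "uncorrected"]
  }
  cat("Abundance estimates by availability scenario\n")
  shown <- ab
  shown$N_hat <- round(shown$N_hat)
  shown$cv <- round(shown$cv, 2)
  shown$ci_low <- round(shown$ci_low); shown$ci_high <- round(shown$ci_high)
  if ("ratio_to_uncorrected" %in% names(shown)) {
    shown$ratio_to_uncorrected <- round(shown$ratio_to_uncorrected, 2)
  }
  print(shown, row.names = FALSE)
  det <- NULL
  det_path <- file.path(output_dir, "detection_comparison.csv")
  if (file.exists(det_path)) {
    det <- read_csv_provenance(det_path)
    cat("\nDetection function comparison\n")
    det_shown <- det
    det_shown$aic <- round(det_shown$aic, 3)
    det_shown$cvm_p <- round(det_shown$cvm_p, 3)
    print(det_shown, row.names = FALSE)
  }
  invisible(list(abundance = ab, detection = det))
}
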