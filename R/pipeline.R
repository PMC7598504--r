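#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end run, with defaults matching the
#' assay conventions: significance level 0.05, cell volume 4 um^3, detection
#' limit 0.2 mM, free fractions 0.40 (putrescine) / 0.05 (spermidine), q
#' threshold 0.05, band-detection prominence 5% with a background window of
#' about 3x the band spacing.
#'
#' @param seed Master seed for the synthetic scenario.
#' @param scenario A [scenario_config()] (set to `NULL` to quantify
#'   externally supplied profiles in `profile_paths` instead).
#' @param profile_paths Optional named character vector of lane-profile CSV
#'   paths (used when `scenario` is `NULL`).
#' @param ref0,ref1 Lane ids of the RSU reference lanes.
#' @param background_window_px,background_fit,min_prominence_frac,min_separation_px,smooth_px
#'   Densitometry parameters (see [quantify_lane()]).
#' @param alpha Significance level for group comparisons.
#' @param stat_method Group-comparison method.
#' @param cell_volume_um3,lod_mM,free_fractions Polyamine constants.
#' @param q_threshold Differential-expression q threshold.
#' @param expression_table Optional path to an expression TSV; default is the
#'   packaged table.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L,
                               scenario = scenario_config(),
                               profile_paths = NULL,
                               ref0 = "ref0", ref1 = "ref1",
                               background_window_px = 91L,
                               background_fit = "linear",
                               min_prominence_frac = 0.05,
                               min_separation_px = 10,
                               smooth_px = 5L,
                               alpha = 0.05,
                               stat_method = "tukey",
                               cell_volume_um3 = 4,
                               lod_mM = 0.2,
                               free_fractions = default_free_fractions,
                               q_threshold = 0.05,
                               expression_table = system.file(
                                 "extdata", "table1_expression.tsv",
                                 package = "topoquant")) {
  structure(list(seed = as.integer(seed), scenario = scenario,
                 profile_paths = profile_paths, ref0 = ref0, ref1 = ref1,
                 background_window_px = background_window_px,
                 background_fit = background_fit,
                 min_prominence_frac = min_prominence_frac,
                 min_separation_px = min_separation_px,
                 smooth_px = smooth_px,
                 alpha = alpha, stat_method = stat_method,
                 cell_volume_um3 = cell_volume_um3, lod_mM = lod_mM,
                 free_fractions = free_fractions, q_threshold = q_threshold,
                 expression_table = expression_table),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any key present in the file overrides the corresponding
#' [default_run_config()] entry; the nested `scenario` and `geometry`
#' mappings are rebuilt through their constructors so invariants are checked.
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (!is.null(y$scenario)) {
    sc_args <- y$scenario
    if (!is.null(sc_args$geometry)) {
      sc_args$geometry <- do.call(gel_geometry, sc_args$geometry)
    }
    if (!is.null(sc_args$sample_offsets_lk)) {
      sc_args$sample_offsets_lk <- unlist(sc_args$sample_offsets_lk)
    }
    cfg$scenario <- do.call(scenario_config, sc_args)
    y$scenario <- NULL
  }
  for (k in names(y)) {
    if (!k %in% names(cfg)) {
      stop_tq("topoquant_config_error", sprintf("unknown config key '%s'", k))
    }
    cfg[[k]] <- y[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Deterministic hash of a config: md5 of its canonical deparse.
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config, control = c("all", "hexNumeric")), tf)
  unname(tools::md5sum(tf))
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[topoquant] ", fmt), ...))
}

#' Run the full supercoiling pipeline
#'
#' Generates (or loads) the lane profiles, quantifies every lane with a
#' shared Lk index origin anchored on the `ref0` lane (all lanes of one run
#' are treated as one gel, so weighted means are directly comparable),
#' computes RSU against the two reference lanes, analyzes the expression
#' table if configured, and writes all outputs to a run directory:
#' `lanes/*.csv`, `bands.tsv`, `supercoiling.tsv`, `expression_flagged.tsv`,
#' `pathway_summary.tsv`, and a machine-readable `summary.json` carrying the
#' package version, the config hash and per-stage provenance. Progress is
#' logged to stderr; result files never contain log lines. Runs are
#' deterministic given the seed.
#'
#' @param config A [default_run_config()] / [read_run_config()] list.
#' @param out_dir Run directory (created if missing).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with `supercoiling` (lane table with RSU),
#'   `bands`, `expression`, `pathways`, `summary` (the summary written to
#'   JSON), and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("topoquant_run_"),
                         quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  # --- validate before any computation
  for (k in c("ref0", "ref1")) {
    if (is.null(config[[k]]) || !nzchar(config[[k]])) {
      stop_tq("topoquant_config_error", sprintf("config is missing the '%s' lane label", k))
    }
  }
  if (is.null(config$scenario) && is.null(config$profile_paths)) {
    stop_tq("topoquant_config_error", "config needs a scenario or profile_paths")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "lanes"), showWarnings = FALSE)
  stages <- character()

  # --- stage: inputs
  if (!is.null(config$scenario)) {
    log_stage(quiet, "simulate: generating synthetic scenario (seed %d)", config$seed)
    scen <- generate_scenario(config$scenario, seed = config$seed)
    profiles <- scen$profiles
    manifest <- scen$manifest
    utils::write.table(manifest, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stages <- c(stages, "simulate")
  } else {
    log_stage(quiet, "load: reading %d lane profiles", length(config$profile_paths))
    profiles <- lapply(names(config$profile_paths), function(id) {
      read_lane_profile(config$profile_paths[[id]], lane_id = id)
    })
    names(profiles) <- names(config$profile_paths)
    manifest <- NULL
    stages <- c(stages, "load")
  }
  ids <- names(profiles)
  for (k in c("ref0", "ref1")) {
    if (!(config[[k]] %in% ids)) {
      stop_tq("topoquant_config_error",
              sprintf("reference lane '%s' is not among the lanes (%s)",
                      config[[k]], paste(ids, collapse = ", ")))
    }
  }
  for (id in ids) write_lane_profile(profiles[[id]], file.path(out_dir, "lanes", paste0(id, ".csv")))

  # --- stage: densitometry (shared index origin anchored on ref0)
  log_stage(quiet, "densitometry: quantifying %d lanes", length(ids))
  ref_fit <- quantify_lane(profiles[[config$ref0]],
                           background_window_px = config$background_window_px,
                           background_fit = config$background_fit,
                           min_prominence_frac = config$min_prominence_frac,
                           min_separation_px = config$min_separation_px,
                           smooth_px = config$smooth_px)
  origin <- min(ref_fit$bands$center_px)
  spacing <- ref_fit$spacing_px
  fits <- lapply(profiles, function(p) {
    quantify_lane(p,
                  background_window_px = config$background_window_px,
                  background_fit = config$background_fit,
                  min_prominence_frac = config$min_prominence_frac,
                  min_separation_px = config$min_separation_px,
                  smooth_px = config$smooth_px,
                  expected_spacing_px = if (is.na(spacing)) "auto" else spacing,
                  reference_center = origin)
  })
  bands <- do.call(rbind, lapply(fits, `[[`, "bands"))
  rownames(bands) <- NULL
  write_band_table(bands, file.path(out_dir, "bands.tsv"))
  stages <- c(stages, "densitometry")

  # --- stage: supercoiling statistics
  log_stage(quiet, "scstats: RSU against %s/%s", config$ref0, config$ref1)
  wlk <- vapply(fits, `[[`, numeric(1), "weighted_lk")
  sc <- rsu_table(wlk, ref0 = config$ref0, ref1 = config$ref1)
  if (!is.null(manifest)) {
    sc$true_mean_lk <- manifest$true_mean_lk[match(sc$lane_id, manifest$lane_id)]
  }
  utils::write.table(format(sc, digits = 4), file.path(out_dir, "supercoiling.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stages <- c(stages, "scstats")

  # --- stage: expression
  expr <- NULL; paths <- NULL
  if (!is.null(config$expression_table) && nzchar(config$expression_table)) {
    log_stage(quiet, "expression: flagging at q < %g", config$q_threshold)
    expr <- flag_differential(read_expression_table(config$expression_table),
                              q_threshold = config$q_threshold)
    paths <- summarize_pathways(expr)
    utils::write.table(expr, file.path(out_dir, "expression_flagged.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(paths, file.path(out_dir, "pathway_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stages <- c(stages, "expression")
  }

  # --- summary (deterministic: no timestamps)
  summary <- list(
    package = "topoquant",
    version = as.character(utils::packageVersion("topoquant")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    lanes = lapply(seq_len(nrow(sc)), function(i) {
      list(lane_id = sc$lane_id[i],
           weighted_lk = round(sc$weighted_lk[i], 4),
           rsu = round(sc$rsu[i], 4))
    }),
    n_differential = if (is.null(expr)) NULL else sum(expr$differential)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage(quiet, "done in %.2f s: %s", proc.time()[["elapsed"]] - t0, out_dir)
  invisible(list(supercoiling = sc, bands = bands, expression = expr,
                 pathways = paths, summary = summary, out_dir = out_dir))
}
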