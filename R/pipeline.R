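# End-to-end orchestration: simulate (or read) -> normalize -> filter ->
# score -> select, with every artifact written to disk and a JSON run
# manifest recording parameters and seed. Each stage failure is reported
# with the stage name; artifacts from completed stages are retained.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(type = "storage", n_null_features = 100L),
    normalize = list(mode = "anchored", threshold = 0.5),
    filter = list(),
    score = list(mode = "literal", threshold = 85, markers = NULL,
                 variant = "as_printed"),
    select = list(pcorr = 0.7, n_orthogonal = 1L, scaling = "pareto",
                  control_pattern = "_T0$", test_pattern = "_25C_(24|48)h$")
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      merge_config(defaults[[nm]], user[[nm]])
    } else user[[nm]]
  }
  defaults
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full processing pipeline
#'
#' Orchestrates the protocol end to end. The input is either a simulated
#' storage series / QC run (the default) or a feature table + manifest read
#' from disk; the stages are drift normalization against the RQCs, QC
#' feature filtering, quality scoring of every study sample against the
#' marker panel, and OPLS-DA / S-plot candidate selection between a control
#' and a test group of samples. All randomness flows from the single
#' config seed.
#'
#' @param config a nested list, or the path to a YAML file with the same
#'   structure. Recognized sections (all optional): `seed`; `input`
#'   (`table`, `manifest` paths) or `simulate` (`type` = "storage" or
#'   "qc_run" plus any [sim_config()] field); `normalize` (`mode`,
#'   `threshold`); `filter` (any [filter_config()] field); `score`
#'   (`mode`, `threshold`, `markers` path, `variant`); `select` (`pcorr`,
#'   `n_orthogonal`, `scaling`, `control_pattern`, `test_pattern`, or
#'   `skip = TRUE`).
#' @param out_dir directory for the artifacts (created if needed):
#'   `normalized.csv` (+ manifest), `normalization_report.json`,
#'   `filtered.csv`, `filter_report.json`, `scores.csv`,
#'   `candidates.csv`, `run_manifest.json`.
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  artifacts <- character(0)

  markers <- NULL
  table <- run_stage("input", {
    if (!is.null(cfg$input)) {
      read_feature_table(cfg$input$table, cfg$input$manifest)
    } else {
      sim_args <- cfg$simulate
      type <- sim_args$type %||% "storage"
      n_null <- sim_args$n_null_features %||% 100L
      sim_args$type <- NULL
      sim_args$n_null_features <- NULL
      sim_args$seed <- sim_args$seed %||% cfg$seed
      scfg <- do.call(sim_config, sim_args)
      if (type == "storage") {
        markers <- run_stage("quality_scoring", {
          load_marker_table(cfg$score$markers,
                            variant = cfg$score$variant %||% "as_printed")
        })
        simulate_storage_series(scfg, markers, n_null_features = n_null)$table
      } else {
        simulate_intensities(scfg)$table
      }
    }
  })

  norm <- run_stage("drift_normalization", {
    normalize_table(table, threshold = cfg$normalize$threshold,
                    mode = cfg$normalize$mode)
  })
  write_feature_table(norm$table, path("normalized.csv"))
  jsonlite::write_json(unclass(norm$report), path("normalization_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  artifacts <- c(artifacts, path("normalized.csv"),
                 path("normalization_report.json"))

  filt <- run_stage("qc_filtering", {
    fargs <- cfg$filter
    apply_all_filters(norm$table, do.call(filter_config, fargs))
  })
  write_feature_table(filt$table, path("filtered.csv"))
  jsonlite::write_json(unclass(filt$report), path("filter_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  artifacts <- c(artifacts, path("filtered.csv"), path("filter_report.json"))

  scores <- run_stage("quality_scoring", {
    if (is.null(markers)) {
      markers <- load_marker_table(cfg$score$markers,
                                   variant = cfg$score$variant %||%
                                     "as_printed")
    }
    score_samples(filt$table, markers, mode = cfg$score$mode,
                  threshold = cfg$score$threshold)
  })
  utils::write.csv(scores, path("scores.csv"), row.names = FALSE)
  artifacts <- c(artifacts, path("scores.csv"))

  candidates <- NULL
  if (!isTRUE(cfg$select$skip)) {
    candidates <- run_stage("marker_discovery", {
      inj <- filt$table$injections
      study <- inj[inj$role == "study" & !is.na(inj$sample_id), ,
                   drop = FALSE]
      ctrl <- grepl(cfg$select$control_pattern, study$sample_id)
      test <- grepl(cfg$select$test_pattern, study$sample_id)
      if (!any(ctrl) || !any(test)) {
        stop("control/test patterns match no study sample")
      }
      keep <- study$injection_id[ctrl | test]
      labels <- factor(ifelse(ctrl[ctrl | test], "control", "test"),
                       levels = c("control", "test"))
      m <- t(filt$table$intensities[, match(keep, inj$injection_id),
                                    drop = FALSE])
      m <- impute_halfmin(m)
      model <- opls_da(m, labels, n_orthogonal = cfg$select$n_orthogonal,
                       scaling = cfg$select$scaling)
      pts <- s_plot(model, m)
      selected <- select_by_pcorr(pts, threshold = cfg$select$pcorr)
      ranked <- rank_candidates(m, labels, top_n = cfg$select$top_n %||% 40L,
                                points = pts)
      ranked$pcorr_selected <- ranked$feature_id %in% selected
      ranked
    })
    utils::write.csv(candidates, path("candidates.csv"), row.names = FALSE)
    artifacts <- c(artifacts, path("candidates.csv"))
  }

  manifest <- list(
    package = "gmetkit",
    version = as.character(utils::packageVersion("gmetkit")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "input")],
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  artifacts <- c(artifacts, path("run_manifest.json"))

  invisible(list(table = table, normalized = norm, filtered = filt,
                 scores = scores, candidates = candidates,
                 artifacts = artifacts))
}
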