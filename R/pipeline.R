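#' Pipeline configuration
#'
#' Bundles every stage's tunables: the cohort source (a
#' [cohort_config()] for synthetic data, or a directory in the raw CSV
#' schema for user data), the fuzzy rule base, the preprocessing
#' constants (15/100 Hz filter corners, 10 N stance threshold,
#' 101-point grid, 10 steps), the SVM selection settings and the
#' effect-size threshold.
#'
#' @param cohort A [cohort_config()] or a path to a cohort directory.
#' @param rule_base_path Path to a fuzzy rule-base YAML (`NULL` for the
#'   packaged default).
#' @param kin_cutoff_hz,grf_cutoff_hz Filter corners (15 / 100 Hz).
#' @param threshold_N Stance threshold (10 N).
#' @param n_points Stance grid (101).
#' @param n_steps Stances averaged per subject (10).
#' @param selection A [selection_config()].
#' @param effect_threshold Medium-effect threshold (0.5).
#' @param out_dir Output directory for all artifacts.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            rule_base_path = NULL,
                            kin_cutoff_hz = 15, grf_cutoff_hz = 100,
                            threshold_N = 10, n_points = 101, n_steps = 10,
                            selection = selection_config(),
                            effect_threshold = 0.5,
                            out_dir = tempfile("runexp_run_")) {
  if (!inherits(cohort, "cohort_config") && !is.character(cohort))
    stop("cohort must be a cohort_config or a directory path")
  if (is.character(cohort) && !dir.exists(cohort))
    stop("cohort directory does not exist: ", cohort)
  if (!is.null(rule_base_path) && !file.exists(rule_base_path))
    stop("fuzzy rule base not found: ", rule_base_path)
  for (v in c(kin_cutoff_hz, grf_cutoff_hz, threshold_N, n_points, n_steps,
              effect_threshold))
    if (!is.finite(v) || v <= 0) stop("numeric pipeline fields must be positive")
  structure(list(cohort = cohort, rule_base_path = rule_base_path,
                 kin_cutoff_hz = kin_cutoff_hz, grf_cutoff_hz = grf_cutoff_hz,
                 threshold_N = threshold_N, n_points = n_points,
                 n_steps = n_steps, selection = selection,
                 effect_threshold = effect_threshold, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest), fuzzy scoring, preprocessing,
#' discrete GRF extraction, PCA, one-vs-all classification and
#' interpretation, writing every stage's artifact into
#' `config$out_dir` and returning a manifest of seeds, input hashes
#' and output paths. Re-running with the same configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cohort <- run_stage("simulate", {
    if (inherits(config$cohort, "cohort_config")) generate_cohort(config$cohort)
    else read_cohort(config$cohort)
  })
  run_stage("simulate", write_cohort(cohort, file.path(out, "cohort")))

  rules <- run_stage("score", fuzzy_rule_base(config$rule_base_path))
  scored <- run_stage("score", score_cohort(cohort$metadata, rules))
  utils::write.csv(scored, file.path(out, "scores.csv"), row.names = FALSE)
  labels <- stats::setNames(scored$experience_label, scored$subject_id)

  sets <- run_stage("preprocess", preprocess_cohort(
    cohort, n_steps = config$n_steps,
    kin_cutoff_hz = config$kin_cutoff_hz, grf_cutoff_hz = config$grf_cutoff_hz,
    threshold_N = config$threshold_N, n_points = config$n_points))
  run_stage("preprocess", write_waveforms(sets, file.path(out, "waveforms.csv")))

  grf <- run_stage("grf", grf_table(cohort, n_steps = config$n_steps,
                                    grf_cutoff_hz = config$grf_cutoff_hz,
                                    threshold_N = config$threshold_N))
  utils::write.csv(grf, file.path(out, "grf_features.csv"), row.names = FALSE)

  wm <- run_stage("pca", assemble_matrix(sets))
  pca <- run_stage("pca", fit_waveform_pca(wm))
  candidates <- run_stage("pca", build_candidates(pca, grf, labels))
  run_stage("pca", write_candidates(candidates, file.path(out, "features.csv")))
  jsonlite::write_json(
    list(center = unname(pca$center), scale = unname(pca$scale),
         explained_variance_ratio = pca$explained_variance_ratio),
    file.path(out, "pca_model.json"), digits = NA)

  reports <- run_stage("classify", fit_all_classes(candidates, config$selection))
  run_stage("classify", write_reports(reports, file.path(out, "reports.json")))

  summaries <- run_stage("interpret", {
    s <- lapply(reports, summarize_model, pca = pca, wm = wm,
                labels = candidates$labels, threshold = config$effect_threshold)
    names(s) <- names(reports)
    s
  })
  run_stage("interpret", write_interpretation(summaries, file.path(out, "interpretation")))

  artifacts <- c("scores.csv", "waveforms.csv", "grf_features.csv",
                 "features.csv", "pca_model.json", "reports.json",
                 file.path("interpretation", "interpretation.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("runexp")),
    cohort_source = if (inherits(config$cohort, "cohort_config")) "synthetic"
                    else config$cohort,
    seeds = list(cohort = if (inherits(config$cohort, "cohort_config"))
                   config$cohort$seed else NULL,
                 folds = config$selection$seed),
    n_subjects = nrow(cohort$metadata),
    reports = lapply(reports, function(r)
      list(positive_class = r$positive_class, c_value = r$c_value,
           mcc = r$metrics$mcc, accuracy = r$metrics$accuracy,
           min_significant_accuracy = r$min_significant_accuracy)),
    outputs = stats::setNames(
      as.list(file.path(out, artifacts)), basename(artifacts)),
    input_hashes = as.list(tools::md5sum(file.path(out, artifacts))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
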