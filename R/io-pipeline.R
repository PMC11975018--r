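#' Read a long-format cohort panel from CSV
#'
#' Expects columns \code{pid}, \code{visit_month} and feature columns;
#' missing cells empty. Visit months are snapped to the configured grid
#' (exact match required); participants with fewer than two observed visits
#' are dropped with a logged count.
#'
#' @param path CSV path.
#' @param roster expected feature columns (default
#'   \code{\link{default_feature_roster}}); unknown extra columns warn,
#'   absent roster columns error.
#' @param visit_months allowed visit grid.
#' @return an \code{mlbpsp_panel}; the number of dropped participants is in
#'   \code{attr(, "n_dropped")}.
#' @export
read_cohort_panel <- function(path, roster = default_feature_roster(),
                              visit_months = c(0, 6, 12, 18)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pid", "visit_month") %in% names(d)))
    stop("panel CSV must have 'pid' and 'visit_month' columns")
  missing_feat <- setdiff(roster, names(d))
  if (length(missing_feat))
    stop("panel is missing feature column(s): ",
         paste(missing_feat, collapse = ", "))
  extra <- setdiff(names(d), c("pid", "visit_month", roster))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  bad_month <- !d$visit_month %in% visit_months
  if (any(bad_month))
    stop("visit_month outside the configured grid at row(s) ",
         paste(utils::head(which(bad_month), 5L), collapse = ", "))
  dup <- duplicated(d[c("pid", "visit_month")])
  if (any(dup))
    stop("duplicate (pid, visit_month) at row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  d <- d[c("pid", "visit_month", roster)]
  obs <- table(d$pid)
  keep <- names(obs)[obs >= 2L]
  n_dropped <- length(obs) - length(keep)
  if (n_dropped)
    message(n_dropped, " participant(s) with < 2 visits dropped")
  d <- d[d$pid %in% keep, , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "features") <- roster
  attr(d, "n_dropped") <- n_dropped
  class(d) <- c("mlbpsp_panel", "data.frame")
  d
}

#' Read a cohort configuration from YAML
#'
#' Accepts the fields of \code{\link{cohort_config}} (any subset; the rest
#' take their defaults).
#'
#' @param path YAML file path.
#' @return a \code{\link{cohort_config}}.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown cohort config field(s): ", paste(unknown, collapse = ", "))
  do.call(cohort_config, y)
}

#' Write a panel (and companions) to CSV
#'
#' @param panel an \code{mlbpsp_panel}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param archetypes archetype list for simulation runs.
#' @param specs feature specs (\code{\link{default_feature_specs}}).
#' @param variance_threshold PCA retention threshold (default 0.85).
#' @param k_max elbow scan upper bound (default 9).
#' @param k optional forced cluster count.
#' @param screen_threshold,retain_threshold predictor-selection thresholds
#'   (defaults 0.10 / 0.05).
#' @param out_dir artifact directory.
#' @return list of class \code{mlbpsp_pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            archetypes = separable_archetypes(),
                            specs = default_feature_specs(),
                            variance_threshold = 0.85,
                            k_max = 9L, k = NULL,
                            screen_threshold = 0.10,
                            retain_threshold = 0.05,
                            out_dir = tempfile("mlbpsp_run_")) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  if (k_max < 3L) stop("k_max must be >= 3")
  structure(list(cohort = cohort, archetypes = archetypes, specs = specs,
                 variance_threshold = variance_threshold, k_max = k_max,
                 k = k, screen_threshold = screen_threshold,
                 retain_threshold = retain_threshold, out_dir = out_dir),
            class = "mlbpsp_pipeline_config")
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate -> missingness -> trajectory fits -> clustering ->
#' characterization -> predictor models -> baseline classifiers, writing CSV
#' / TSV / JSON artifacts plus a manifest (seed, file hashes) to
#' \code{config$out_dir}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with the in-memory stage results and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "mlbpsp_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    panel0 <- simulate_cohort(config$cohort, config$archetypes)
    panel <- apply_missingness(panel0, config$cohort)
    baseline <- simulate_baseline_covariates(panel, config$cohort)
    write_cohort_panel(panel, file.path(config$out_dir, "panel.csv"))
    utils::write.csv(baseline, file.path(config$out_dir, "baseline.csv"),
                     row.names = FALSE)

    stage <- "fit-trajectories"
    traj <- fit_trajectories(panel, config$specs)
    utils::write.csv(data.frame(pid = rownames(traj$matrix), traj$matrix,
                                check.names = FALSE),
                     file.path(config$out_dir, "random_effects.csv"),
                     row.names = FALSE)

    stage <- "cluster"
    clusters <- cluster_phenotypes(traj$matrix, panel,
                                   threshold = config$variance_threshold,
                                   k_max = config$k_max, k = config$k,
                                   seed = config$cohort$seed)
    utils::write.csv(data.frame(pid = names(clusters$labels),
                                phenotype = unname(clusters$labels)),
                     file.path(config$out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(k = seq_along(clusters$wss), wss = clusters$wss),
                     file.path(config$out_dir, "wss_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(m = clusters$pca$m, cumvar = clusters$pca$cumvar,
                              k = clusters$k, rationale = clusters$rationale),
                         file.path(config$out_dir, "cluster_summary.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "characterize"
    comparisons <- characterize_phenotypes(baseline, clusters$labels)

    stage <- "predict"
    lab_vec <- clusters$labels[baseline$pid]
    binary_vars <- rownames(default_baseline_config()$binary)
    uni <- lapply(stats::setNames(binary_vars, binary_vars), function(v)
      univariable_multinomial(baseline[[v]], lab_vec, name = v))
    screened <- screen_predictors(uni, config$screen_threshold)
    multi <- multivariable_multinomial(baseline, screened, lab_vec,
                                       forced = "education",
                                       retain_threshold = config$retain_threshold)
    uni_tab <- do.call(rbind, lapply(uni, `[[`, "table"))
    multi_tab <- do.call(rbind, lapply(multi$results, `[[`, "table"))
    utils::write.table(rbind(uni_tab, multi_tab),
                       file.path(config$out_dir, "predictors.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(multi$trace,
                         file.path(config$out_dir, "selection_trace.json"),
                         auto_unbox = TRUE)

    stage <- "classify"
    scores <- baseline_summary_scores(panel)
    ok <- stats::complete.cases(scores)
    scores <- scores[ok, , drop = FALSE]
    sl <- clusters$labels[scores$pid]
    rf <- rf_crossval_phenotypes(scores[c("bdi_total", "gds", "paofi_total",
                                          "iadl_total")],
                                 sl, seed = config$cohort$seed)
    bin <- binary_healthy_classifier(scores[c("bdi_total", "gds", "paofi_total",
                                              "iadl_total")],
                                     sl, seed = config$cohort$seed)
    jsonlite::write_json(list(
      four_class = list(accuracy = rf$accuracy,
                        misclassification = rf$misclassification),
      binary = list(accuracy = bin$accuracy,
                    misallocation = as.list(bin$misallocation))),
      file.path(config$out_dir, "classifiers.json"), auto_unbox = TRUE,
      digits = NA)

    list(panel = panel, baseline = baseline, trajectories = traj,
         clusters = clusters, comparisons = comparisons,
         univariable = uni, multivariable = multi,
         rf_report = rf, binary_report = bin, out_dir = config$out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mlbpsp")),
    seed = config$cohort$seed,
    k = res$clusters$k, rationale = res$clusters$rationale,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
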