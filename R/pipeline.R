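# End-to-end orchestration: sites -> counts -> context -> calls ->
# summaries -> associations, with a manifest of outputs, input hashes and
# the thresholds in force.

#' Run the editing pipeline end-to-end
#'
#' Stages: read the site catalog, load paired counts, build per-site
#' context and call editing, summarise samples and sites, and (when
#' annotations are supplied) compare editing-high and -low samples.  Every
#' output is tab-delimited with the thresholds echoed in `#` metadata
#' lines; the manifest records MD5 hashes of inputs and outputs so a rerun
#' on identical inputs can be verified bit-identical.
#'
#' @param config named list or path to a JSON file with elements:
#'   `sites` (site table path), `counts` (count table path), `out_dir`;
#'   optional `mode` (default `"C-to-U"`), `thresholds` (named overrides),
#'   `annotations` (annotation table path with a `sample_id` column) and
#'   `annotation_roles` (list with optional `expression_cols`,
#'   `time_col`, `event_col`).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (f in c("sites", "counts", "out_dir")) {
    if (is.null(config[[f]])) format_error("config is missing '%s'", f)
  }
  for (f in c("sites", "counts", if (!is.null(config$annotations)) "annotations")) {
    if (!file.exists(config[[f]])) format_error("input file not found: %s", config[[f]])
  }
  mode <- if (is.null(config$mode)) "C-to-U" else config$mode
  th <- do.call(thresholds, as.list(config$thresholds))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  meta <- c(mode = mode, unlist(th))

  catalog <- parse_site_table(config$sites, mode = if (mode == "C-to-A") "C-to-A" else "C-to-U")
  evidence <- load_count_table(config$counts)
  calls <- call_cohort(evidence, catalog, mode = mode, th = th)
  write_calls(calls, out("calls.tsv"))
  write_tsv_meta(attr(calls, "reason_tally"), out("reason_tally.tsv"), meta = meta)
  tabs <- cohort_tables(calls, th)
  write_tsv_meta(tabs$sample, out("sample_summary.tsv"), meta = meta)
  write_tsv_meta(tabs$site, out("site_summary.tsv"), meta = meta)
  outputs <- c("calls.tsv", "reason_tally.tsv", "sample_summary.tsv", "site_summary.tsv")

  if (!is.null(config$annotations)) {
    ann <- read_tsv_meta(config$annotations)
    if (is.null(ann$sample_id)) format_error("annotation table needs a sample_id column")
    roles <- config$annotation_roles
    sc <- tabs$sample
    m <- merge(sc, ann, by = "sample_id")
    m <- m[m$group %in% c("HIGH", "LOW"), , drop = FALSE]
    if (length(roles$expression_cols)) {
      scores <- setNames(sc$editing_score, sc$sample_id)
      expr <- ann[, roles$expression_cols, drop = FALSE]
      rownames(expr) <- ann$sample_id
      # too few scorable samples yields an empty (not failed) result table
      corr <- tryCatch(
        score_expression_correlations(scores, expr, roles$expression_cols),
        apobec3edit_format_error = function(e)
          score_expression_correlations(scores, expr, character()))
      write_tsv_meta(corr, out("score_expression.tsv"), meta = meta)
      outputs <- c(outputs, "score_expression.tsv")
      grp <- lapply(roles$expression_cols, function(gn) {
        res <- tryCatch(
          compare_continuous(m[[gn]][m$group == "HIGH"], m[[gn]][m$group == "LOW"]),
          apobec3edit_degenerate = function(e) list(t = NA_real_, p = NA_real_,
                                                    fold_change = NA_real_),
          apobec3edit_format_error = function(e) list(t = NA_real_, p = NA_real_,
                                                      fold_change = NA_real_))
        data.frame(variable = gn, t = res$t, p = res$p,
                   fold_change = res$fold_change, stringsAsFactors = FALSE)
      })
      grp <- do.call(rbind, grp)
      grp$p_adj <- bh_adjust(grp$p)
      write_tsv_meta(grp, out("group_comparisons.tsv"), meta = meta)
      outputs <- c(outputs, "group_comparisons.tsv")
    }
    if (!is.null(roles$time_col) && !is.null(roles$event_col)) {
      empty_sv <- function(e) list(logrank_p = NA_real_, logrank_chisq = NA_real_,
                                   hr = NA_real_, n_events = NA_integer_)
      sv <- tryCatch(
        logrank_cox(m[[roles$time_col]], m[[roles$event_col]], m$group),
        apobec3edit_degenerate = empty_sv,
        apobec3edit_format_error = empty_sv)
      write_tsv_meta(as.data.frame(sv), out("survival.tsv"), meta = meta)
      outputs <- c(outputs, "survival.tsv")
    }
  }

  inputs <- unlist(config[c("sites", "counts", "annotations")])
  manifest <- list(
    mode = mode,
    thresholds = unclass(th),
    inputs = as.list(unname(tools::md5sum(inputs))) |> setNames(basename(inputs)),
    outputs = as.list(unname(tools::md5sum(vapply(outputs, out, "")))) |>
      setNames(outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Thin wrapper over [simulate_cohort()]: writes the site table, the paired
#' count table, the per-sample annotations and the ground-truth tables,
#' plus a JSON echo of the configuration.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
simulate_to_dir <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(cfg)
  paths <- list(
    sites = file.path(dir, "sites.tsv"),
    counts = file.path(dir, "counts.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    config = file.path(dir, "sim_config.json"))
  write_site_table(sim$sites, paths$sites)
  write_count_table(sim$evidence, paths$counts, meta = c(seed = cfg$seed))
  write_tsv_meta(sim$annotations, paths$annotations, meta = c(seed = cfg$seed))
  write_tsv_meta(sim$truth$pairs, paths$truth_pairs, meta = c(seed = cfg$seed))
  write_tsv_meta(sim$truth$samples, paths$truth_samples, meta = c(seed = cfg$seed))
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
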