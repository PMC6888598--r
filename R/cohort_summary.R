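# Per-sample editing scores and per-site prevalence summaries.

#' Summarise calls for one sample
#'
#' The editing score is the fraction of editing-positive sites among
#' editing-determinable sites, computed only for samples with at least
#' `min_score_sites` (default 5) determinable sites.  Samples with a score
#' of 0 are editing-low, score > 0 editing-high; samples with too few
#' determinable sites are unscored.
#'
#' @param calls calls data.frame (rows for one sample).
#' @param th [thresholds()].
#' @return One-row data.frame: `sample_id`, `n_determinable`, `n_edited`,
#'   `editing_score`, `group`, `mean_level_edited`.
#' @export
summarize_sample <- function(calls, th = thresholds()) {
  sid <- if (nrow(calls)) calls$sample_id[[1L]] else NA_character_
  det <- calls$status != "INDETERMINABLE"
  ed <- calls$status == "EDITED"
  n_det <- sum(det); n_ed <- sum(ed)
  score <- if (n_det >= th$min_score_sites) n_ed / n_det else NA_real_
  group <- if (is.na(score)) "UNSCORED" else if (score > 0) "HIGH" else "LOW"
  data.frame(sample_id = sid, n_determinable = n_det, n_edited = n_ed,
             editing_score = score, group = group,
             mean_level_edited = if (n_ed >= 1L) mean(calls$level[ed]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Summarise calls for one site across samples
#'
#' The edited fraction is reported only when the site was determinable in
#' at least `min_score_sites` samples; the mean level averages edited
#' samples only (zero-level samples excluded).
#'
#' @param calls calls data.frame (rows for one site).
#' @param th [thresholds()].
#' @return One-row data.frame: `chrom`, `pos`, `n_determinable_samples`,
#'   `n_edited_samples`, `fraction_edited`, `mean_level`.
#' @export
summarize_site <- function(calls, th = thresholds()) {
  det <- calls$status != "INDETERMINABLE"
  ed <- calls$status == "EDITED"
  n_det <- sum(det); n_ed <- sum(ed)
  data.frame(chrom = if (nrow(calls)) calls$chrom[[1L]] else NA_character_,
             pos = if (nrow(calls)) calls$pos[[1L]] else NA_integer_,
             n_determinable_samples = n_det, n_edited_samples = n_ed,
             fraction_edited = if (n_det >= th$min_score_sites) n_ed / n_det else NA_real_,
             mean_level = if (n_ed >= 1L) mean(calls$level[ed]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Cohort-wide sample and site summary tables
#'
#' @param calls data.frame from [call_cohort()].
#' @param th [thresholds()].
#' @return List with `sample` and `site` data.frames, each ordered by
#'   identifier.
#' @export
cohort_tables <- function(calls, th = thresholds()) {
  if (nrow(calls) == 0L) {
    return(list(
      sample = data.frame(sample_id = character(), n_determinable = integer(),
                          n_edited = integer(), editing_score = numeric(),
                          group = character(), mean_level_edited = numeric(),
                          stringsAsFactors = FALSE),
      site = data.frame(chrom = character(), pos = integer(),
                        n_determinable_samples = integer(),
                        n_edited_samples = integer(),
                        fraction_edited = numeric(), mean_level = numeric(),
                        stringsAsFactors = FALSE)))
  }
  samples <- do.call(rbind, lapply(split(calls, calls$sample_id),
                                   summarize_sample, th = th))
  site_key <- paste(calls$chrom, calls$pos)
  sites <- do.call(rbind, lapply(split(calls, site_key),
                                 summarize_site, th = th))
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(samples) <- rownames(sites) <- NULL
  list(sample = samples, site = sites)
}
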