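# Downstream comparisons between editing-high and editing-low samples:
# continuous variables, incidence tables, survival, and score-expression
# correlations.

#' Two-group comparison of a continuous variable
#'
#' Student's two-sample t-test with pooled variance ("standard" t-test;
#' Welch available behind `var_equal = FALSE`), or the paired variant on
#' differences.  The fold change is the ratio of group means on the natural
#' scale of the supplied values.
#'
#' @param values_high,values_low numeric vectors (equal length if paired).
#' @param paired paired test on differences.
#' @param var_equal pooled-variance (default) vs Welch.
#' @return List with `t`, `p`, `fold_change`, `mean_high`, `mean_low`.
#'   Degenerate (zero) variance is signalled as an
#'   `apobec3edit_degenerate` error.
#' @export
compare_continuous <- function(values_high, values_low, paired = FALSE,
                               var_equal = TRUE) {
  if (length(values_high) < 2L || length(values_low) < 2L) {
    format_error("need at least 2 values per group")
  }
  if (paired && length(values_high) != length(values_low)) {
    format_error("paired comparison requires equal-length groups")
  }
  degenerate <- if (paired) sd(values_high - values_low) == 0 else
    sd(values_high) == 0 && sd(values_low) == 0
  if (degenerate) {
    stop(errorCondition("t-test undefined: zero variance",
                        class = c("apobec3edit_degenerate", "error")))
  }
  tt <- t.test(values_high, values_low, paired = paired, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       fold_change = mean(values_high) / mean(values_low),
       mean_high = mean(values_high), mean_low = mean(values_low))
}

#' Exact incidence test on a 2 x k contingency table
#'
#' 2x2 tables use the two-sided [fisher_exact()]; wider tables use the exact
#' network algorithm (via `stats::fisher.test`), with the total count capped
#' at 200 to keep the computation exact.
#'
#' @param counts 2 x k matrix of non-negative counts (rows are the two
#'   groups).
#' @return p-value.
#' @export
incidence_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L) {
    format_error("contingency table must be 2 x k with k >= 2")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    format_error("counts must be non-negative integers")
  }
  if (ncol(counts) == 2L) {
    return(fisher_exact(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2],
                        alternative = "two.sided"))
  }
  if (sum(counts) > 200) {
    format_error("table total %d too large for exact 2 x %d computation; collapse categories",
                 sum(counts), ncol(counts))
  }
  fisher.test(counts)$p.value
}

#' Log-rank test and Cox hazard ratio for a binary group
#'
#' Standard 1-df log-rank chi-square and the hazard ratio from a
#' single-covariate Cox model (Efron tie handling).  The hazard ratio is
#' reported as LOW-versus-HIGH, so HR > 1 means the editing-high group
#' fares better.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (0/1).
#' @param group `"HIGH"`/`"LOW"` labels (or a factor whose first level is
#'   treated as HIGH).
#' @return List with `logrank_p`, `logrank_chisq`, `hr` and `n_events`.
#' @export
logrank_cox <- function(times, events, group) {
  if (any(times < 0, na.rm = TRUE)) format_error("times must be >= 0")
  if (!all(events %in% c(0, 1, NA))) format_error("events must be 0/1")
  keep <- complete.cases(times, events, group)
  times <- times[keep]; events <- events[keep]; group <- group[keep]
  g <- if (is.factor(group)) droplevels(group) else factor(group, levels = sort(unique(group)))
  if (all(c("HIGH", "LOW") %in% levels(g))) g <- factor(as.character(g), levels = c("HIGH", "LOW"))
  if (nlevels(g) != 2L) format_error("group must have exactly two levels")
  if (min(tapply(events, g, sum)) < 1) {
    stop(errorCondition("hazard ratio undefined: a group has no events",
                        class = c("apobec3edit_degenerate", "error")))
  }
  sd_ <- survdiff(Surv(times, events) ~ g)
  p <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  cx <- coxph(Surv(times, events) ~ g, ties = "efron")
  list(logrank_p = p, logrank_chisq = unname(sd_$chisq),
       hr = unname(exp(cx$coefficients)), n_events = sum(events))
}

#' Correlate per-sample editing scores with gene expression
#'
#' Pearson correlation of the editing score against each listed gene's
#' expression, with Benjamini-Hochberg adjustment across genes.  Genes with
#' zero expression variance yield `NA` statistics.
#'
#' @param scores named numeric vector of editing scores (names are sample
#'   identifiers).
#' @param expression numeric matrix or data.frame, samples in rows (row
#'   names are sample identifiers), genes in columns.
#' @param genes character vector of gene columns to test (default: all).
#' @return data.frame with `gene`, `r`, `p`, `p_adj`, `n`, ordered by `p`.
#' @export
score_expression_correlations <- function(scores, expression,
                                          genes = colnames(expression)) {
  expression <- as.data.frame(expression)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), r = numeric(), p = numeric(),
                      p_adj = numeric(), n = integer(), stringsAsFactors = FALSE))
  }
  common <- intersect(names(scores)[!is.na(scores)], rownames(expression))
  if (length(common) < 3L) format_error("fewer than 3 matched samples with scores")
  res <- lapply(genes, function(gn) {
    if (is.null(expression[[gn]])) format_error("gene '%s' not in expression data", gn)
    x <- scores[common]; y <- expression[common, gn]
    out <- tryCatch(pearson_r(x, y),
                    apobec3edit_degenerate = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(gene = gn, r = out$r, p = out$p, n = length(common),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p), c("gene", "r", "p", "p_adj", "n")]
  rownames(res) <- NULL
  res
}
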