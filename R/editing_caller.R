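# The editing caller: maps paired RNA/DNA base counts at a site to an
# editing level in [0, 1] or an indeterminable/zero verdict with a reason
# code, via an ordered sequence of evidence gates.

REASONS <- c("LOW_RNA_COV", "HOM_POLY", "HET_POLY", "SINGLETON_V",
             "ZERO_CTX_UNMET", "LOW_DNA_COV", "BOSCHLOO_FAIL",
             "DNA_SIGNAL", "STRAND_BIAS", "OK")

#' Decision-tree thresholds
#'
#' Returns the full set of caller constants.  Defaults encode the published
#' determination rules: minimum RNA and DNA coverage of 10 high-quality
#' calls; homozygous-polymorphism gate `R < 6` for `N <= 20` else
#' `R < 0.4 N`; heterozygous gate `R < 0.8 N`; singleton variant (`V = 1`)
#' indeterminable; `V = 0` called zero only when `R` exceeds 3x the site's
#' cohort mean R/V ratio; one-sided Boschloo gate at alpha 0.05; RNA variant
#' fraction required to be >= 10x the DNA fraction unless DNA has no
#' variant calls; strand-bias gate (for `V > 2`) at 8-fold odds ratio or
#' two-sided Fisher p <= 0.01; editing scores only for samples with >= 5
#' determinable sites; base calls counted at phred quality >= 20.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of thresholds (class `editing_thresholds`).
#' @export
thresholds <- function(...) {
  th <- list(min_rna_cov = 10, min_dna_cov = 10,
             hom_R_abs = 6, hom_R_frac = 0.4, het_R_frac = 0.8, small_N = 20,
             zero_ctx_mult = 3, boschloo_alpha = 0.05, rna_dna_fold = 10,
             strandbias_fold = 8, strandbias_alpha = 0.01,
             min_score_sites = 5, min_quality = 20,
             boschloo_grid = 999L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) format_error("unknown threshold(s): %s", paste(unknown, collapse = ", "))
  th[names(dots)] <- dots
  num <- unlist(th)
  if (any(!is.finite(num)) || any(num <= 0)) format_error("thresholds must be positive and finite")
  fr <- c("hom_R_frac", "het_R_frac")
  if (any(unlist(th[fr]) >= 1)) format_error("fraction thresholds must lie in (0, 1)")
  structure(th, class = c("editing_thresholds", "list"))
}

#' RNA-only prefilter gates
#'
#' Applied before any DNA evidence is consulted, in order: poor coverage
#' (`N < 10`); reference count low enough to suggest a homozygous DNA
#' polymorphism (`R < 6` for `N <= 20`, else `R < 0.4 N`) or a heterozygous
#' one (`R < 0.8 N`); a singleton variant call (`V = 1`).
#'
#' @param R,V,N RNA reference count, variant count and total call count.
#' @param th [thresholds()].
#' @return `"pass"` or the failing reason code.
#' @export
rna_prefilter <- function(R, V, N, th = thresholds()) {
  if (N < th$min_rna_cov) return("LOW_RNA_COV")
  if ((N <= th$small_N && R < th$hom_R_abs) ||
      (N > th$small_N && R < th$hom_R_frac * N)) return("HOM_POLY")
  if (R < th$het_R_frac * N) return("HET_POLY")
  if (V == 1) return("SINGLETON_V")
  "pass"
}

#' Cohort context for the zero-variant rule at one site
#'
#' The `V = 0` rule compares a sample's reference depth against the site's
#' typical R/V ratio: the mean of R/V over all cohort samples with `V > 0`
#' (restricted to samples with adequate RNA coverage).  Undefined when no
#' sample contributes.
#'
#' @param R,V,N equal-length vectors of RNA counts across cohort samples.
#' @param th [thresholds()].
#' @return List with `mean_RV_ratio` (`NA` if undefined) and `n_contributors`.
#' @export
build_site_context <- function(R, V, N, th = thresholds()) {
  use <- !is.na(V) & V > 0 & !is.na(N) & N >= th$min_rna_cov
  if (!any(use)) return(list(mean_RV_ratio = NA_real_, n_contributors = 0L))
  list(mean_RV_ratio = mean(R[use] / V[use]), n_contributors = sum(use))
}

#' Zero-variant rule
#'
#' For `V = 0` (after the prefilter), the level is 0 only when the reference
#' depth is deep enough that editing at the site's typical level would have
#' been seen: `R > 3 x` the cohort mean R/V ratio.  Otherwise, and whenever
#' the context is undefined, editing is indeterminable.
#'
#' @param R RNA reference count.
#' @param ctx [build_site_context()] result.
#' @param th [thresholds()].
#' @return `"ZERO"` or `"ZERO_CTX_UNMET"`.
#' @export
zero_variant_rule <- function(R, ctx, th = thresholds()) {
  if (!is.na(ctx$mean_RV_ratio) && R > th$zero_ctx_mult * ctx$mean_RV_ratio) "ZERO"
  else "ZERO_CTX_UNMET"
}

#' RNA sequencing strand-bias test for variant calls
#'
#' Compares the forward/reverse split of variant calls against reference
#' calls.  Biased when the variant-vs-reference strand odds ratio
#' `(V_fwd * R_rev) / (V_rev * R_fwd)` (with +0.5 added to every cell when
#' any cell is zero) exceeds the fold threshold in either direction, or the
#' two-sided Fisher exact p on the 2x2 table is at or below alpha.  Not
#' tested for `V = 2`.
#'
#' @param V_fwd,V_rev,R_fwd,R_rev strand-split variant/reference counts.
#' @param th [thresholds()].
#' @return List with `verdict` (`"biased"`, `"unbiased"`, `"not_tested"`),
#'   `odds_ratio` and `p`.
#' @export
strand_bias_test <- function(V_fwd, V_rev, R_fwd, R_rev, th = thresholds()) {
  V <- V_fwd + V_rev
  if (V < 2) format_error("strand bias is only defined for V >= 2")
  if (V == 2) return(list(verdict = "not_tested", odds_ratio = NA_real_, p = NA_real_))
  cells <- c(V_fwd, V_rev, R_fwd, R_rev)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  p <- if (R_fwd + R_rev == 0) 1 else
    fisher_exact(V_fwd, V_rev, R_fwd, R_rev, alternative = "two.sided")
  biased <- or > th$strandbias_fold || or < 1 / th$strandbias_fold ||
    p <= th$strandbias_alpha
  list(verdict = if (biased) "biased" else "unbiased", odds_ratio = or, p = p)
}

# Memoising Boschloo lookup keyed on the 2x2 table.
boschloo_cached <- function(a, b, c, d, grid_size, cache) {
  key <- paste(a, b, c, d, sep = "_")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- as.numeric(boschloo_one_sided(a, b, c, d, grid_size = grid_size))
  cache[[key]] <- p
  p
}

# Vectorised classifier over paired RV count rows.  `rna`/`dna` are
# data.frames from derive_RV_matrix (dna cells may be NA for unpaired
# evidence); ctx_mean is the per-row site-context mean R/V (NA undefined).
classify_counts <- function(rna, dna, ctx_mean, th = thresholds(),
                            cache = new.env(parent = emptyenv())) {
  n <- nrow(rna)
  status <- rep(NA_character_, n); reason <- rep(NA_character_, n)
  level <- rep(NA_real_, n)
  boschloo_p <- rep(NA_real_, n)
  strand_or <- rep(NA_real_, n); strand_p <- rep(NA_real_, n)

  open <- rep(TRUE, n)
  fail <- function(mask, why) {
    mask[is.na(mask)] <- FALSE
    hit <- open & mask
    status[hit] <<- "INDETERMINABLE"; reason[hit] <<- why
    open[hit] <<- FALSE
  }

  fail(is.na(rna$N) | rna$N < th$min_rna_cov, "LOW_RNA_COV")
  fail((rna$N <= th$small_N & rna$R < th$hom_R_abs) |
       (rna$N > th$small_N & rna$R < th$hom_R_frac * rna$N), "HOM_POLY")
  fail(rna$R < th$het_R_frac * rna$N, "HET_POLY")
  fail(rna$V == 1, "SINGLETON_V")

  # V = 0: zero-variant rule against the site context
  z <- open & rna$V == 0
  zero_ok <- z & !is.na(ctx_mean) & rna$R > th$zero_ctx_mult * ctx_mean
  status[zero_ok] <- "ZERO"; reason[zero_ok] <- "OK"; level[zero_ok] <- 0
  open[zero_ok] <- FALSE
  fail(z, "ZERO_CTX_UNMET")

  # V >= 2: DNA coverage, Boschloo, relative-fraction, strand-bias gates
  fail(is.na(dna$N) | dna$N < th$min_dna_cov, "LOW_DNA_COV")

  idx <- which(open)
  for (i in idx) {
    if (dna$R[i] + dna$V[i] == 0) {            # coverage but no ref/var calls
      boschloo_p[i] <- NA_real_
      next
    }
    boschloo_p[i] <- boschloo_cached(rna$V[i], rna$R[i], dna$V[i], dna$R[i],
                                     th$boschloo_grid, cache)
  }
  fail(is.na(boschloo_p) | boschloo_p > th$boschloo_alpha, "BOSCHLOO_FAIL")

  rna_frac <- rna$V / (rna$R + rna$V)
  dna_frac <- ifelse(dna$R + dna$V > 0, dna$V / (dna$R + dna$V), 0)
  fail(!(dna$V == 0 | rna_frac >= th$rna_dna_fold * dna_frac), "DNA_SIGNAL")

  sb <- which(open & rna$V > 2)
  for (i in sb) {
    res <- strand_bias_test(rna$V_fwd[i], rna$V_rev[i],
                            rna$R_fwd[i], rna$R_rev[i], th)
    strand_or[i] <- res$odds_ratio; strand_p[i] <- res$p
    if (identical(res$verdict, "biased")) {
      status[i] <- "INDETERMINABLE"; reason[i] <- "STRAND_BIAS"; open[i] <- FALSE
    }
  }

  ok <- open
  status[ok] <- "EDITED"; reason[ok] <- "OK"
  level[ok] <- rna_frac[ok]

  data.frame(status = status, reason = reason, level = level,
             boschloo_p = boschloo_p, strand_or = strand_or,
             strand_p = strand_p, stringsAsFactors = FALSE)
}

#' Call editing for one sample at one site
#'
#' Applies the full ordered decision tree to one pair of RNA/DNA
#' strand-split base-count vectors: RNA prefilter, zero-variant rule,
#' DNA coverage, one-sided Boschloo comparison of RNA versus DNA
#' variant/reference counts, relative RNA/DNA variant-fraction requirement,
#' and strand-bias filter, ending in an editing level `V/(R+V)` of the RNA
#' data.
#'
#' @param rna_counts,dna_counts named vectors over `A_fwd ... T_rev`
#'   (`dna_counts` may be `NULL` for unpaired evidence, which becomes
#'   indeterminable at the DNA-coverage gate).
#' @param strand transcription strand of the site (`"+"`/`"-"`).
#' @param ctx [build_site_context()] result for the site.
#' @param mode `"C-to-U"` or `"C-to-A"`.
#' @param th [thresholds()].
#' @return One-row data.frame: `status`, `reason`, `level`, counts and test
#'   statistics.
#' @export
call_editing <- function(rna_counts, dna_counts, strand,
                         ctx = list(mean_RV_ratio = NA_real_, n_contributors = 0L),
                         mode = "C-to-U", th = thresholds()) {
  rv <- resolve_ref_var(strand, mode)
  rna <- as.data.frame(derive_RV(rna_counts, rv$ref, rv$var))
  dna <- if (is.null(dna_counts)) {
    data.frame(R = NA_real_, V = NA_real_, N = NA_real_, R_fwd = NA_real_,
               R_rev = NA_real_, V_fwd = NA_real_, V_rev = NA_real_)
  } else as.data.frame(derive_RV(dna_counts, rv$ref, rv$var))
  cls <- classify_counts(rna, dna, ctx$mean_RV_ratio, th)
  cbind(cls,
        data.frame(R_rna = rna$R, V_rna = rna$V, N_rna = rna$N,
                   R_dna = dna$R, V_dna = dna$V, N_dna = dna$N))
}

#' Call editing across a cohort
#'
#' Two passes over the evidence: the first builds the per-site cohort
#' context (mean R/V over samples with a variant call), the second applies
#' the decision tree to every (site, sample) pair.  Sites present in the
#' evidence but absent from the catalog are dropped with a warning.  Tumor
#' and normal samples should be supplied as separate cohorts, since the
#' context is a cohort property.
#'
#' @param evidence paired count table from [load_count_table()] (or
#'   [simulate_cohort()]).
#' @param catalog a [site_catalog].
#' @param mode editing mode; defaults to the catalog's mode, with
#'   `"negative-control"` catalogs evaluated as C-to-U.
#' @param th [thresholds()].
#' @return data.frame of calls, one row per (sample, site), with attributes
#'   `reason_tally` (per-reason determination counts) and `thresholds`.
#' @export
call_cohort <- function(evidence, catalog, mode = NULL, th = thresholds()) {
  stopifnot(inherits(catalog, "site_catalog"))
  if (is.null(mode)) mode <- catalog_mode(catalog)
  if (mode == "negative-control") mode <- "C-to-U"
  site_key <- paste(evidence$chrom, evidence$pos)
  cat_key <- paste(catalog$chrom, catalog$pos)
  hit <- match(site_key, cat_key)
  if (anyNA(hit)) {
    warning(sprintf("%d evidence row(s) at positions absent from the catalog were dropped",
                    sum(is.na(hit))), call. = FALSE)
    evidence <- evidence[!is.na(hit), , drop = FALSE]
    site_key <- site_key[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  if (nrow(evidence) == 0L) {
    out <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), mode = character(), status = character(),
                      reason = character(), level = numeric(),
                      R_rna = numeric(), V_rna = numeric(), N_rna = numeric(),
                      R_dna = numeric(), V_dna = numeric(), N_dna = numeric(),
                      boschloo_p = numeric(), strand_or = numeric(),
                      strand_p = numeric(), stringsAsFactors = FALSE)
    attr(out, "reason_tally") <- reason_tally(out)
    attr(out, "thresholds") <- th
    return(out)
  }
  strand <- catalog$strand[hit]
  rv <- resolve_ref_var(strand, mode)
  rna <- derive_RV_matrix(evidence, "rna_", rv$ref, rv$var)
  dna <- derive_RV_matrix(evidence, "dna_", rv$ref, rv$var)

  # pass 1: per-site context from RNA counts
  ctx_mean <- rep(NA_real_, nrow(evidence))
  for (k in unique(site_key)) {
    rows <- which(site_key == k)
    ctx <- build_site_context(rna$R[rows], rna$V[rows], rna$N[rows], th)
    ctx_mean[rows] <- ctx$mean_RV_ratio
  }

  # pass 2: classify every pair
  cache <- new.env(parent = emptyenv())
  cls <- classify_counts(rna, dna, ctx_mean, th, cache = cache)
  out <- data.frame(sample_id = evidence$sample_id, chrom = evidence$chrom,
                    pos = evidence$pos, mode = mode, stringsAsFactors = FALSE)
  out <- cbind(out, cls[, c("status", "reason", "level")],
               data.frame(R_rna = rna$R, V_rna = rna$V, N_rna = rna$N,
                          R_dna = dna$R, V_dna = dna$V, N_dna = dna$N),
               cls[, c("boschloo_p", "strand_or", "strand_p")])
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reason_tally") <- reason_tally(out)
  attr(out, "thresholds") <- th
  out
}

#' Per-reason determination tally
#'
#' Counts (site, sample) determinations by status and reason code,
#' mirroring a criteria-fulfillment summary of the calling workflow.
#'
#' @param calls data.frame from [call_cohort()].
#' @return data.frame with `status`, `reason`, `n`.
#' @export
reason_tally <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(status = character(), reason = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  tab <- aggregate(list(n = seq_len(nrow(calls))),
                   by = list(status = calls$status, reason = calls$reason),
                   FUN = length)
  tab[order(-tab$n), , drop = FALSE]
}

#' Write cohort calls as tab-delimited text
#' @param calls data.frame from [call_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  th <- attr(calls, "thresholds", exact = TRUE)
  meta <- if (is.null(th)) NULL else unlist(th)
  write_tsv_meta(calls, path, meta = meta)
}
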