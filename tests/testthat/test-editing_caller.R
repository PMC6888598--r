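test_that("threshold defaults encode the published decision constants", {
  th <- thresholds()
  expect_equal(th$min_rna_cov, 10); expect_equal(th$min_dna_cov, 10)
  expect_equal(th$hom_R_abs, 6); expect_equal(th$hom_R_frac, 0.4)
  expect_equal(th$het_R_frac, 0.8); expect_equal(th$small_N, 20)
  expect_equal(th$zero_ctx_mult, 3); expect_equal(th$boschloo_alpha, 0.05)
  expect_equal(th$rna_dna_fold, 10); expect_equal(th$strandbias_fold, 8)
  expect_equal(th$strandbias_alpha, 0.01); expect_equal(th$min_score_sites, 5)
  expect_equal(th$min_quality, 20)
  expect_equal(thresholds(min_rna_cov = 20)$min_rna_cov, 20)
  expect_error(thresholds(bogus = 1), "unknown")
  expect_error(thresholds(het_R_frac = 1.5), "0, 1")
})

test_that("RNA prefilter gates fire in order with strict boundaries", {
  expect_equal(rna_prefilter(R = 8, V = 1, N = 9), "LOW_RNA_COV")
  expect_equal(rna_prefilter(R = 5, V = 15, N = 20), "HOM_POLY")
  expect_equal(rna_prefilter(R = 70, V = 30, N = 100), "HET_POLY")
  expect_equal(rna_prefilter(R = 98, V = 1, N = 100), "SINGLETON_V")
  expect_equal(rna_prefilter(R = 98, V = 2, N = 100), "pass")
  # boundary semantics: R < 0.8 N is strict
  expect_equal(rna_prefilter(R = 159, V = 40, N = 200), "HET_POLY")
  expect_equal(rna_prefilter(R = 160, V = 40, N = 200), "pass")
  # homozygous boundary: R < 6 at N <= 20, R < 0.4 N above
  expect_equal(rna_prefilter(R = 6, V = 14, N = 20), "HET_POLY")
  expect_equal(rna_prefilter(R = 39, V = 60, N = 100), "HOM_POLY")
  expect_equal(rna_prefilter(R = 40, V = 60, N = 100), "HET_POLY")
})

test_that("site context averages R/V over covered samples with variants", {
  ctx <- build_site_context(R = c(95, 90), V = c(5, 10), N = c(100, 100))
  expect_equal(ctx$mean_RV_ratio, 14)   # mean of 19 and 9
  expect_equal(ctx$n_contributors, 2L)
  expect_equal(build_site_context(R = c(80), V = c(20), N = 100)$mean_RV_ratio, 4)
  ctx0 <- build_site_context(R = c(50, 60), V = c(0, 0), N = c(50, 60))
  expect_true(is.na(ctx0$mean_RV_ratio))
  expect_equal(ctx0$n_contributors, 0L)
  # low-coverage samples never contribute
  ctx1 <- build_site_context(R = c(95, 4), V = c(5, 4), N = c(100, 8))
  expect_equal(ctx1$n_contributors, 1L)
  expect_equal(ctx1$mean_RV_ratio, 19)
})

test_that("the zero-variant rule needs deep reference coverage vs context", {
  ctx <- list(mean_RV_ratio = 20, n_contributors = 3L)
  expect_equal(zero_variant_rule(R = 200, ctx), "ZERO")      # 200 > 60
  expect_equal(zero_variant_rule(R = 50, ctx), "ZERO_CTX_UNMET")
  expect_equal(zero_variant_rule(R = 60, ctx), "ZERO_CTX_UNMET")  # strict >
  expect_equal(zero_variant_rule(R = 1000, list(mean_RV_ratio = NA_real_,
                                                n_contributors = 0L)),
               "ZERO_CTX_UNMET")
})

test_that("strand-bias verdicts follow fold, significance and V=2 rules", {
  expect_equal(strand_bias_test(12, 0, 100, 100)$verdict, "biased")
  res <- strand_bias_test(5, 5, 100, 100)
  expect_equal(res$verdict, "unbiased")
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  expect_equal(strand_bias_test(2, 0, 10, 90)$verdict, "not_tested")
  expect_error(strand_bias_test(1, 0, 10, 10), "V >= 2")
  # fold gate alone (p modest, OR extreme) with zero-cell correction
  res <- strand_bias_test(3, 0, 20, 200)
  expect_true(res$odds_ratio > 8)
  expect_equal(res$verdict, "biased")
})

test_that("single-pair calls traverse the full gate sequence", {
  # clean editing: strong RNA excess, DNA clean
  r <- call_editing(counts_vec(C_fwd = 45, C_rev = 40, T_fwd = 8, T_rev = 7),
                    counts_vec(C_fwd = 25, C_rev = 25), strand = "+")
  expect_equal(r$status, "EDITED")
  expect_equal(r$level, 0.15)
  expect_lte(r$boschloo_p, 0.05)

  # DNA coverage below 10
  r <- call_editing(counts_vec(C_fwd = 50, C_rev = 45, T_fwd = 3, T_rev = 2),
                    counts_vec(C_fwd = 5), strand = "+")
  expect_equal(r$reason, "LOW_DNA_COV")

  # unpaired evidence cannot pass the DNA gate
  r <- call_editing(counts_vec(C_fwd = 50, C_rev = 45, T_fwd = 3, T_rev = 2),
                    NULL, strand = "+")
  expect_equal(r$reason, "LOW_DNA_COV")

  # equal RNA/DNA variant fractions can never be called edited
  r <- call_editing(counts_vec(C_fwd = 45, C_rev = 45, T_fwd = 5, T_rev = 5),
                    counts_vec(C_fwd = 44, C_rev = 44, T_fwd = 6, T_rev = 6),
                    strand = "+")
  expect_equal(r$status, "INDETERMINABLE")
  expect_true(r$reason %in% c("BOSCHLOO_FAIL", "DNA_SIGNAL"))

  # minus-strand site: ref G, var A
  r <- call_editing(counts_vec(G_fwd = 45, G_rev = 40, A_fwd = 8, A_rev = 7),
                    counts_vec(G_fwd = 25, G_rev = 25), strand = "-")
  expect_equal(r$status, "EDITED")
  expect_equal(r$level, 0.15)

  # V = 2 skips the strand-bias test even when both calls share a strand;
  # deep clean DNA against shallow RNA makes two variant reads significant
  r <- call_editing(counts_vec(C_fwd = 4, C_rev = 4, T_fwd = 2),
                    counts_vec(C_fwd = 30, C_rev = 30), strand = "+")
  expect_equal(r$status, "EDITED")
  expect_equal(r$level, 0.2)
  expect_true(is.na(r$strand_p))

  # V > 2 concentrated on one strand is removed
  r <- call_editing(counts_vec(C_fwd = 60, C_rev = 60, T_fwd = 12),
                    counts_vec(C_fwd = 30, C_rev = 30), strand = "+")
  expect_equal(r$reason, "STRAND_BIAS")
})

test_that("raising the DNA variant count never rescues a DNA_SIGNAL call", {
  rna <- counts_vec(C_fwd = 43, C_rev = 42, T_fwd = 8, T_rev = 7)
  seen_edited_after_fail <- FALSE
  failed <- FALSE
  for (vd in 0:12) {
    dna <- counts_vec(C_fwd = 30, C_rev = 30, T_fwd = vd)
    r <- call_editing(rna, dna, strand = "+")
    if (failed && r$status == "EDITED") seen_edited_after_fail <- TRUE
    if (r$status != "EDITED") failed <- TRUE
  }
  expect_false(seen_edited_after_fail)
})

test_that("cohort calling builds context across samples before calling", {
  # one edited sample defines the context; a deep V=0 sample becomes ZERO
  ev <- rbind(
    evidence_row("S1", "chr1", 100L,
                 counts_vec(C_fwd = 45, C_rev = 40, T_fwd = 8, T_rev = 7),
                 counts_vec(C_fwd = 25, C_rev = 25)),
    evidence_row("S2", "chr1", 100L,
                 counts_vec(C_fwd = 60, C_rev = 60),
                 counts_vec(C_fwd = 25, C_rev = 25)))
  cat_ <- site_catalog(data.frame(chrom = "chr1", pos = 100L, strand = "+",
                                  stringsAsFactors = FALSE))
  calls <- call_cohort(ev, cat_)
  expect_equal(calls$status[calls$sample_id == "S1"], "EDITED")
  # context mean R/V = 85/15; 120 > 3 * 5.67
  expect_equal(calls$status[calls$sample_id == "S2"], "ZERO")
  expect_equal(calls$level[calls$sample_id == "S2"], 0)

  # with no variant-bearing sample the context is undefined everywhere
  ev2 <- rbind(
    evidence_row("S1", "chr1", 100L, counts_vec(C_fwd = 500, C_rev = 500),
                 counts_vec(C_fwd = 25)),
    evidence_row("S2", "chr1", 100L, counts_vec(C_fwd = 400, C_rev = 400),
                 counts_vec(C_fwd = 25)))
  calls2 <- call_cohort(ev2, cat_)
  expect_true(all(calls2$reason == "ZERO_CTX_UNMET"))

  # empty evidence yields an empty, well-formed call table
  calls3 <- call_cohort(ev[0, ], cat_)
  expect_equal(nrow(calls3), 0L)
  expect_true(all(c("status", "reason", "level") %in% names(calls3)))

  # evidence at uncataloged positions is dropped with a warning
  ev_extra <- ev
  ev_extra$pos[2] <- 999L
  expect_warning(call_cohort(ev_extra, cat_), "absent from the catalog")
})

test_that("the caller matches a literal transcription of the rules (small sweep)", {
  th <- thresholds()
  cache <- new.env(parent = emptyenv())
  bp <- function(a, b, c_, d) boschloo_cached_test(a, b, c_, d, cache)
  ctx_mean <- 4
  set.seed(91)
  grid <- expand.grid(N = c(0, 5, 9, 10, 12, 15, 20), R_frac = c(0, 0.5, 0.8, 0.9, 1),
                      Nd = c(0, 9, 10, 20), Vd = 0:2)
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]; R <- round(grid$R_frac[i] * N); V <- N - R
    Nd <- grid$Nd[i]; Vd <- min(grid$Vd[i], Nd); Rd <- Nd - Vd
    Vf <- ceiling(V / 2); Vr <- V - Vf
    Rf <- ceiling(R / 2); Rr <- R - Rf
    want <- oracle_call_literal(R, V, N, Rd, Vd, Nd, Vf, Vr, Rf, Rr, ctx_mean, bp)
    rna <- counts_vec(C_fwd = Rf, C_rev = Rr, T_fwd = Vf, T_rev = Vr)
    dna <- counts_vec(C_fwd = Rd, T_fwd = Vd)
    got <- call_editing(rna, dna, strand = "+",
                        ctx = list(mean_RV_ratio = ctx_mean, n_contributors = 1L))
    expect_equal(unname(c(got$status, got$reason)), unname(want),
                 info = sprintf("R=%g V=%g N=%g Rd=%g Vd=%g Nd=%g", R, V, N, Rd, Vd, Nd))
  }
})
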