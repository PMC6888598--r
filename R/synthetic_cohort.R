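# Synthetic paired RNA/DNA cohort generator with known ground truth.
# Emulates the study conditions of an exome + mRNA sequencing cohort:
# negative-binomial per-site depths (means 195/56, dispersions calibrated so
# medians land near 72/31), per-base sequencing error, occasional germline
# heterozygous SNPs at the edited base, presence/absence editing occurrence
# per (site, sample) at a mean per-site prevalence of 20% of samples, with
# per-site Beta-distributed true levels scaled by a per-sample log-normal
# propensity, and a small fraction of sites with pathological variant
# strand imbalance.

#' Simulation configuration
#'
#' @param n_samples,n_sites cohort dimensions.
#' @param rna_depth_mean,rna_depth_size RNA coverage negative-binomial mean
#'   and size (defaults 195 and 0.407; the size is calibrated so the median
#'   is 72).
#' @param dna_depth_mean,dna_depth_size DNA (exome) coverage model
#'   (defaults 56 and 0.65, median 31).
#' @param seq_error per-base miscall rate (default 0.001).
#' @param het_snp_rate fraction of (site, sample) pairs carrying a
#'   heterozygous germline variant at the edited base (default 0.001).
#' @param editable_site_frac fraction of sites truly edited in the cohort
#'   (default 0.3).
#' @param level_beta_a,level_beta_b,level_cap per-site true-level Beta
#'   parameters (1.5, 20) truncated at `level_cap` (0.18).
#' @param site_prevalence mean fraction of samples truly edited at an
#'   editable site (default 0.2, the mean per-site editing prevalence
#'   reported for the cohort the generator emulates).  Editing occurrence
#'   per (site, sample) is Bernoulli with probability
#'   `plogis(qlogis(site_prevalence) + prevalence_slope * log(propensity))`,
#'   so high-propensity samples edit at more sites.
#' @param prevalence_slope logistic slope linking occurrence to log
#'   propensity (see above).
#' @param propensity_sdlog per-sample log-normal editing-propensity sdlog
#'   (default 0.5; meanlog is `-sdlog^2/2` so the scale has mean 1).  The
#'   propensity scales both true levels and, through `prevalence_slope`,
#'   the per-site editing occurrence.
#' @param strand_frac expected forward-strand fraction (default 0.5).
#' @param biased_site_frac fraction of sites whose variant calls are strand
#'   biased (default 0.02), with forward fraction `biased_fwd_frac` (0.95).
#' @param biased_fwd_frac see above.
#' @param survival_hr LOW-vs-HIGH hazard ratio used for the generated
#'   survival endpoint (default 1.75).
#' @param seed mandatory integer seed.
#' @return Named list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 400L, n_sites = 200L,
                              rna_depth_mean = 195, rna_depth_size = 0.407,
                              dna_depth_mean = 56, dna_depth_size = 0.65,
                              seq_error = 0.001, het_snp_rate = 0.001,
                              editable_site_frac = 0.3,
                              level_beta_a = 1.5, level_beta_b = 20,
                              level_cap = 0.18,
                              site_prevalence = 0.2, prevalence_slope = 2,
                              propensity_sdlog = 0.5,
                              strand_frac = 0.5, biased_site_frac = 0.02,
                              biased_fwd_frac = 0.95,
                              survival_hr = 1.75,
                              seed) {
  if (missing(seed)) format_error("a seed is mandatory for simulation")
  cfg <- list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
              rna_depth_mean = rna_depth_mean, rna_depth_size = rna_depth_size,
              dna_depth_mean = dna_depth_mean, dna_depth_size = dna_depth_size,
              seq_error = seq_error, het_snp_rate = het_snp_rate,
              editable_site_frac = editable_site_frac,
              level_beta_a = level_beta_a, level_beta_b = level_beta_b,
              level_cap = level_cap,
              site_prevalence = site_prevalence,
              prevalence_slope = prevalence_slope,
              propensity_sdlog = propensity_sdlog,
              strand_frac = strand_frac, biased_site_frac = biased_site_frac,
              biased_fwd_frac = biased_fwd_frac, survival_hr = survival_hr,
              seed = as.integer(seed))
  probs <- c(cfg$seq_error, cfg$het_snp_rate, cfg$editable_site_frac,
             cfg$site_prevalence, cfg$strand_frac, cfg$biased_site_frac,
             cfg$biased_fwd_frac)
  if (any(probs < 0 | probs > 1)) format_error("probabilities must lie in [0, 1]")
  if (cfg$rna_depth_mean <= 0 || cfg$dna_depth_mean <= 0) {
    format_error("depth means must be positive")
  }
  if (cfg$n_samples < 1L || cfg$n_sites < 1L) format_error("cohort dimensions must be >= 1")
  structure(cfg, class = c("simulation_config", "list"))
}

# Truncated Beta sampler (inverse-CDF truncation at `cap`).
rbeta_trunc <- function(n, a, b, cap) {
  qbeta(runif(n, 0, pbeta(cap, a, b)), a, b)
}

#' Simulate a paired RNA/DNA editing cohort with ground truth
#'
#' Per pair, the DNA variant count is Binomial(N_dna, error) for
#' reference-homozygous genotypes and Binomial(N_dna, 0.5) for heterozygous
#' ones; the RNA variant count is Binomial(N_rna, level + error (1 - level))
#' and Binomial(N_rna, 0.5) respectively.  A small number of remaining
#' calls miscall to the two other bases; strand assignment is Binomial with
#' the configured forward fraction, except that variant calls at designated
#' biased sites are concentrated on the forward strand.  Fully reproducible
#' from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return List with `evidence` (paired count table as from
#'   [load_count_table()]), `truth` (list of `pairs` and `samples`
#'   data.frames), `annotations` (per-sample group label, expression
#'   values, survival time/event) and `sites` (the [site_catalog]).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_private_seed(cfg$seed, {
    ns <- cfg$n_samples; nk <- cfg$n_sites
    sample_ids <- sprintf("S%04d", seq_len(ns))
    sites <- data.frame(
      chrom = "chr1",
      pos = 1000L * seq_len(nk),
      strand = rep_len(c("+", "-"), nk),
      gene = sprintf("GENE%03d", seq_len(nk)),
      region = "CDS", effect = "synonymous", source = "synthetic",
      stringsAsFactors = FALSE)
    editable <- runif(nk) < cfg$editable_site_frac
    base_level <- ifelse(editable,
                         rbeta_trunc(nk, cfg$level_beta_a, cfg$level_beta_b,
                                     cfg$level_cap), 0)
    biased <- runif(nk) < cfg$biased_site_frac
    propensity <- rlnorm(ns, meanlog = -cfg$propensity_sdlog^2 / 2,
                         sdlog = cfg$propensity_sdlog)

    # long layout: site-major blocks of samples
    site_i <- rep(seq_len(nk), each = ns)
    samp_i <- rep(seq_len(ns), times = nk)
    m <- ns * nk
    het <- runif(m) < cfg$het_snp_rate
    p_occur <- plogis(qlogis(cfg$site_prevalence) +
                        cfg$prevalence_slope * log(propensity[samp_i]))
    occurs <- editable[site_i] & runif(m) < p_occur
    true_level <- ifelse(het | !occurs, 0,
                         pmin(base_level[site_i] * propensity[samp_i], 0.2))

    err <- cfg$seq_error
    N_rna <- rnbinom(m, size = cfg$rna_depth_size, mu = cfg$rna_depth_mean)
    N_dna <- rnbinom(m, size = cfg$dna_depth_size, mu = cfg$dna_depth_mean)
    p_rna <- ifelse(het, 0.5, true_level + err * (1 - true_level))
    p_dna <- ifelse(het, 0.5, err)
    V_rna <- rbinom(m, N_rna, p_rna)
    V_dna <- rbinom(m, N_dna, p_dna)
    O_rna <- rbinom(m, N_rna - V_rna, 2 * err / 3)   # miscalls to other bases
    O_dna <- rbinom(m, N_dna - V_dna, 2 * err / 3)
    R_rna <- N_rna - V_rna - O_rna
    R_dna <- N_dna - V_dna - O_dna

    vfwd_p <- ifelse(biased[site_i], cfg$biased_fwd_frac, cfg$strand_frac)
    split_counts <- function(total, fwd_p) {
      fwd <- rbinom(m, total, fwd_p)
      list(fwd = fwd, rev = total - fwd)
    }
    rv <- resolve_ref_var(sites$strand[site_i], "C-to-U")
    other <- t(vapply(seq_len(m), function(i) setdiff(c("A", "C", "G", "T"),
                                                      c(rv$ref[i], rv$var[i])),
                      character(2L)))

    assemble <- function(Rb, Vb, Ob, vp) {
      Rs <- split_counts(Rb, cfg$strand_frac)
      Vs <- split_counts(Vb, vp)
      O1 <- rbinom(m, Ob, 0.5); O2 <- Ob - O1
      O1s <- split_counts(O1, cfg$strand_frac)
      O2s <- split_counts(O2, cfg$strand_frac)
      cnt <- matrix(0L, nrow = m, ncol = 8L, dimnames = list(NULL, COUNT_COLS))
      put <- function(base, s) {
        cnt[cbind(seq_len(m), match(paste0(base, "_fwd"), COUNT_COLS))] <<-
          cnt[cbind(seq_len(m), match(paste0(base, "_fwd"), COUNT_COLS))] + s$fwd
        cnt[cbind(seq_len(m), match(paste0(base, "_rev"), COUNT_COLS))] <<-
          cnt[cbind(seq_len(m), match(paste0(base, "_rev"), COUNT_COLS))] + s$rev
      }
      put(rv$ref, Rs); put(rv$var, Vs)
      put(other[, 1L], O1s); put(other[, 2L], O2s)
      cnt
    }
    rna_cnt <- assemble(R_rna, V_rna, O_rna, vfwd_p)
    dna_cnt <- assemble(R_dna, V_dna, O_dna, cfg$strand_frac)
    colnames(rna_cnt) <- paste0("rna_", COUNT_COLS)
    colnames(dna_cnt) <- paste0("dna_", COUNT_COLS)

    evidence <- cbind(
      data.frame(sample_id = sample_ids[samp_i], chrom = sites$chrom[site_i],
                 pos = sites$pos[site_i], unpaired = FALSE,
                 stringsAsFactors = FALSE),
      as.data.frame(rna_cnt), as.data.frame(dna_cnt))

    truth_pairs <- data.frame(
      sample_id = sample_ids[samp_i], chrom = sites$chrom[site_i],
      pos = sites$pos[site_i],
      genotype = ifelse(het, "het", "ref-hom"),
      true_level = true_level, stringsAsFactors = FALSE)
    truth_samples <- data.frame(sample_id = sample_ids, propensity = propensity,
                                stringsAsFactors = FALSE)
    truth_sites <- data.frame(chrom = sites$chrom, pos = sites$pos,
                              editable = editable, base_level = base_level,
                              strand_biased = biased, stringsAsFactors = FALSE)

    # annotations: propensity-linked driver expression, noise genes, survival
    group <- ifelse(propensity > median(propensity), "HIGH", "LOW")
    expr_driver <- log2(5 * propensity) + rnorm(ns, 0, 0.8)
    expr_noise1 <- rnorm(ns, 4, 1)
    expr_noise2 <- rnorm(ns, 6, 1.5)
    surv <- simulate_survival(ns, hr = cfg$survival_hr, group = group)
    annotations <- data.frame(
      sample_id = sample_ids, group = group,
      APOBEC3A_like = expr_driver, NOISE1 = expr_noise1, NOISE2 = expr_noise2,
      time = surv$time, event = surv$event, stringsAsFactors = FALSE)

    list(evidence = evidence,
         truth = list(pairs = truth_pairs, samples = truth_samples,
                      sites = truth_sites),
         annotations = annotations,
         sites = site_catalog(sites, mode = "C-to-U"))
  })
}

#' Simulate exponential survival for a binary group
#'
#' Exponential event times with baseline hazard for the HIGH group and
#' `hr`-fold hazard for the LOW group, under independent exponential
#' censoring (about 20% at defaults).
#'
#' @param n number of subjects (ignored if `group` supplied).
#' @param hr LOW-vs-HIGH hazard ratio.
#' @param group optional `"HIGH"`/`"LOW"` labels; default a balanced split.
#' @param baseline_hazard events per time unit in the HIGH group.
#' @param censor_rate hazard of the independent censoring process.
#' @param seed optional; if given, draws under a private RNG state.
#' @return data.frame with `group`, `time`, `event`.
#' @export
simulate_survival <- function(n, hr = 1.75, group = NULL,
                              baseline_hazard = 0.1, censor_rate = 0.025,
                              seed = NULL) {
  run <- function() {
    if (is.null(group)) group <- rep_len(c("HIGH", "LOW"), n)
    n <- length(group)
    haz <- ifelse(group == "LOW", baseline_hazard * hr, baseline_hazard)
    t_event <- rexp(n, haz)
    t_cens <- rexp(n, censor_rate)
    data.frame(group = group, time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens), stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_private_seed(seed, run())
}

#' Compare calls with simulation truth
#'
#' @param calls data.frame from [call_cohort()].
#' @param truth truth list from [simulate_cohort()].
#' @param th [thresholds()] (for score computation).
#' @return List of metrics, each a list with `value` and its denominator
#'   `n` (`value` is `NA` when the denominator is zero): false-positive
#'   rate on truly unedited determinable pairs; fraction of heterozygous
#'   pairs called edited; sensitivity and level RMSE on truly edited
#'   pairs; fraction of edited calls whose level lies within 2 binomial
#'   standard errors of truth; Pearson correlation of editing score with
#'   the latent propensity.
#' @export
evaluate_calls <- function(calls, truth, th = thresholds()) {
  key <- function(d) paste(d$sample_id, d$chrom, d$pos)
  idx <- match(key(calls), key(truth$pairs))
  if (anyNA(idx)) format_error("calls contain pairs absent from truth")
  tp <- truth$pairs[idx, , drop = FALSE]
  det <- calls$status != "INDETERMINABLE"
  ed <- calls$status == "EDITED"
  metric <- function(num, den) {
    list(value = if (den > 0) num / den else NA_real_, n = den)
  }
  unedited_det <- det & tp$true_level == 0
  fpr <- metric(sum(ed & tp$true_level == 0), sum(unedited_det))
  het <- tp$genotype == "het"
  het_edit <- metric(sum(ed & het), sum(het))
  edited_det <- det & tp$true_level > 0
  sens <- metric(sum(ed & tp$true_level > 0), sum(edited_det))
  hit <- ed & tp$true_level > 0
  rmse <- if (sum(hit) > 0) {
    list(value = sqrt(mean((calls$level[hit] - tp$true_level[hit])^2)), n = sum(hit))
  } else list(value = NA_real_, n = 0L)
  cover <- if (sum(hit) > 0) {
    se <- sqrt(tp$true_level[hit] * (1 - tp$true_level[hit]) /
                 (calls$R_rna[hit] + calls$V_rna[hit]))
    list(value = mean(abs(calls$level[hit] - tp$true_level[hit]) <= 2 * se),
         n = sum(hit))
  } else list(value = NA_real_, n = 0L)
  tabs <- cohort_tables(calls, th)
  sc <- tabs$sample
  m <- merge(sc, truth$samples, by = "sample_id")
  m <- m[!is.na(m$editing_score), , drop = FALSE]
  score_r <- if (nrow(m) >= 3L && sd(m$editing_score) > 0) {
    list(value = pearson_r(m$editing_score, m$propensity)$r, n = nrow(m))
  } else list(value = NA_real_, n = nrow(m))
  list(false_positive_rate = fpr, het_edited_fraction = het_edit,
       sensitivity = sens, level_rmse = rmse, level_within_2se = cover,
       score_propensity_r = score_r)
}
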