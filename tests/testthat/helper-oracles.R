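# Independent oracles, written against the published rules and basic
# probability only; they deliberately share no code with the package
# internals they check.

# One-sided Fisher p by direct hypergeometric summation.
oracle_fisher_one_sided <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  if (k == 0) return(1)
  xs <- max(0, k - n2):min(n1, k)
  sum(dhyper(xs[xs >= a], k, n1 + n2 - k, n1))
}

# Two-sided Fisher p: sum of point probabilities <= observed.
oracle_fisher_two_sided <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(n1, k)
  dd <- dhyper(xs, k, n1 + n2 - k, n1)
  obs <- dhyper(a, k, n1 + n2 - k, n1)
  min(1, sum(dd[dd <= obs * (1 + 1e-7)]))
}

# Brute-force Boschloo: enumerate every table with the given margins,
# order by one-sided Fisher p, maximise the rejection-region probability
# over the nuisance grid.
oracle_boschloo <- function(a, b, c, d, grid_size = 999) {
  n1 <- a + b; n2 <- c + d
  F <- outer(0:n1, 0:n2,
             Vectorize(function(i, j) oracle_fisher_one_sided(i, n1 - i, j, n2 - j)))
  obs <- F[a + 1, c + 1]
  acc <- F <= obs + obs * 1e-9 + 1e-12
  grid <- seq_len(grid_size) / (grid_size + 1)
  pooled <- (a + c) / (n1 + n2)
  if (pooled > 0 && pooled < 1) grid <- c(grid, pooled)
  best <- 0
  for (p in grid) {
    D <- outer(dbinom(0:n1, n1, p), dbinom(0:n2, n2, p))
    best <- max(best, sum(D[acc]))
  }
  best
}

# Vectorised brute-force Boschloo for ALL tables with margins (n1, n2):
# returns an (n1+1) x (n2+1) matrix of p-values.  Orders tables by Fisher
# p and accumulates region probabilities by cumulative sums per nuisance
# value, handling ties as blocks.
oracle_boschloo_all <- function(n1, n2, grid_size = 999) {
  F <- outer(0:n1, 0:n2,
             Vectorize(function(i, j) oracle_fisher_one_sided(i, n1 - i, j, n2 - j)))
  ord <- order(F)
  Fs <- F[ord]
  # tie blocks: tables whose Fisher p is equal up to tolerance share a rank
  blk <- cumsum(c(TRUE, diff(Fs) > Fs[-length(Fs)] * 1e-9 + 1e-12))
  grid <- seq_len(grid_size) / (grid_size + 1)
  pooled <- unique(as.vector(outer(0:n1, 0:n2, "+")) / (n1 + n2))
  grid <- c(grid, pooled[pooled > 0 & pooled < 1])
  best <- rep(0, length(Fs))
  for (p in grid) {
    D <- outer(dbinom(0:n1, n1, p), dbinom(0:n2, n2, p))
    cs <- cumsum(D[ord])
    # block-wise maximum: every table in a tie block gets the block total
    cs_blk <- tapply(cs, blk, max)[blk]
    best <- pmax(best, cs_blk)
  }
  out <- matrix(NA_real_, n1 + 1, n2 + 1)
  out[ord] <- pmin(best, 1)
  out
}

# Literal transcription of the published editing-determination rules,
# written as a direct sentence-by-sentence translation.  `boschloo_p` is a
# p-value function (a, b, c, d) -> p supplied by the caller.
oracle_call_literal <- function(R, V, N, Rd, Vd, Nd, Vf, Vr, Rf, Rr,
                                ctx_mean, boschloo_p) {
  if (N < 10) return(c("INDETERMINABLE", "LOW_RNA_COV"))
  if (N <= 20) { if (R < 6) return(c("INDETERMINABLE", "HOM_POLY")) } else
    if (R < 0.4 * N) return(c("INDETERMINABLE", "HOM_POLY"))
  if (R < 0.8 * N) return(c("INDETERMINABLE", "HET_POLY"))
  if (V == 1) return(c("INDETERMINABLE", "SINGLETON_V"))
  if (V == 0) {
    if (!is.na(ctx_mean) && R > 3 * ctx_mean) return(c("ZERO", "OK"))
    return(c("INDETERMINABLE", "ZERO_CTX_UNMET"))
  }
  # V >= 2
  if (is.na(Nd) || Nd < 10) return(c("INDETERMINABLE", "LOW_DNA_COV"))
  if (Rd + Vd == 0) return(c("INDETERMINABLE", "BOSCHLOO_FAIL"))
  if (boschloo_p(V, R, Vd, Rd) > 0.05) return(c("INDETERMINABLE", "BOSCHLOO_FAIL"))
  rna_frac <- V / (R + V)
  dna_frac <- Vd / (Rd + Vd)
  if (!(Vd == 0 || rna_frac >= 10 * dna_frac)) return(c("INDETERMINABLE", "DNA_SIGNAL"))
  if (V > 2) {
    cells <- c(Vf, Vr, Rf, Rr)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    p <- if (Rf + Rr == 0) 1 else
      fisher.test(matrix(c(Vf, Rf, Vr, Rr), 2))$p.value
    if (or > 8 || or < 1 / 8 || p <= 0.01) return(c("INDETERMINABLE", "STRAND_BIAS"))
  }
  c("EDITED", "OK")
}

# Hand-computed log-rank statistic: sum over event times of observed minus
# expected events in group 1, variance from the hypergeometric.
oracle_logrank <- function(time, event, group1) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- Vr <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) Vr <- Vr + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / Vr
}

# Memoised package Boschloo, shared by decision-tree sweeps so the tree
# comparison is not dominated by repeated identical exact tests.
boschloo_cached_test <- function(a, b, c, d, cache) {
  key <- paste(a, b, c, d)
  if (is.null(cache[[key]])) {
    cache[[key]] <- as.numeric(boschloo_one_sided(a, b, c, d))
  }
  cache[[key]]
}
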