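# Programmatic fixtures: everything is built in code at test time.

# Named 8-cell strand-split count vector.
counts_vec <- function(...) {
  v <- setNames(integer(8L),
                c("A_fwd", "A_rev", "C_fwd", "C_rev",
                  "G_fwd", "G_rev", "T_fwd", "T_rev"))
  dots <- list(...)
  v[names(dots)] <- as.integer(unlist(dots))
  v
}

# Small plus-strand site table data.frame.
toy_sites <- function(n = 3L) {
  data.frame(chrom = rep("chr1", n), pos = 100L * seq_len(n), strand = rep("+", n),
             gene = sprintf("G%d", seq_len(n)), region = rep("CDS", n),
             effect = rep("synonymous", n), source = rep("unit", n),
             stringsAsFactors = FALSE)
}

# One paired evidence row in the wide layout used by call_cohort.
evidence_row <- function(sample_id, chrom, pos, rna, dna = NULL) {
  r <- as.data.frame(as.list(rna))
  names(r) <- paste0("rna_", names(rna))
  if (is.null(dna)) {
    d <- as.data.frame(as.list(setNames(rep(NA_integer_, 8L), names(rna))))
    unp <- TRUE
  } else {
    d <- as.data.frame(as.list(dna))
    unp <- FALSE
  }
  names(d) <- paste0("dna_", sub("^dna_", "", names(counts_vec())))
  cbind(data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                   unpaired = unp, stringsAsFactors = FALSE), r, d)
}

# Build a pileup line from explicit tokens (bases string + qualities),
# used for parser round-trips.
pileup_line <- function(chrom, pos, ref, bases, quals) {
  paste(chrom, pos, ref, nchar(gsub("[^.,ACGTNacgtn*<>]", "", bases)),
        bases, quals, sep = "\t")
}
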