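q20 <- function(n) strrep("I", n)   # phred 40

test_that("base calls map to strand-split counts with quality filtering", {
  # four calls, all high quality: ref C on both strands + T on both strands
  r <- parse_pileup_line(paste("chr1", "50", "C", "4", ".,Tt", q20(4), sep = "\t"))
  expect_equal(r$counts[["C_fwd"]], 1L)
  expect_equal(r$counts[["C_rev"]], 1L)
  expect_equal(r$counts[["T_fwd"]], 1L)
  expect_equal(r$counts[["T_rev"]], 1L)
  expect_equal(r$N, 4L)

  # the forward T call at phred 5 is dropped
  r <- parse_pileup_line(paste("chr1", "50", "C", "4", ".,Tt", "II&I", sep = "\t"))
  expect_equal(r$counts[["T_fwd"]], 0L)
  expect_equal(r$counts[["T_rev"]], 1L)
  expect_equal(r$N, 3L)

  # start/end markers consume no quality character
  r <- parse_pileup_line(paste("chr1", "50", "C", "2", "^]..$", q20(2), sep = "\t"))
  expect_equal(r$counts[["C_fwd"]], 2L)
  expect_equal(r$N, 2L)

  # indel runs are skipped; *,>,< consume quality but add no call
  r <- parse_pileup_line(paste("chr1", "50", "C", "6", ".+2AG,-1a*><t", q20(6), sep = "\t"))
  expect_equal(r$counts[["C_fwd"]], 1L)
  expect_equal(r$counts[["C_rev"]], 1L)
  expect_equal(r$counts[["T_rev"]], 1L)
  expect_equal(r$N, 3L)

  # N calls consume quality but never count
  r <- parse_pileup_line(paste("chr1", "50", "C", "3", ".Nn", q20(3), sep = "\t"))
  expect_equal(r$N, 1L)
})

test_that("bases/quality length mismatches are reported with the position", {
  expect_error(parse_pileup_line(paste("chr1", "77", "C", "3", "...", "II", sep = "\t")),
               "mismatch.*chr1:77", class = "apobec3edit_format_error")
  expect_error(parse_pileup_line(paste("chr1", "78", "C", "1", ".", "II", sep = "\t")),
               "mismatch.*chr1:78", class = "apobec3edit_format_error")
})

test_that("parsing is insensitive to marker placement around base calls", {
  # randomized valid pileup strings with known truth, markers interleaved
  set.seed(401)
  for (rep in 1:25) {
    n_fwd <- sample(0:5, 1); n_rev <- sample(0:5, 1)
    n_var_f <- sample(0:3, 1); n_var_r <- sample(0:3, 1)
    toks <- c(rep(".", n_fwd), rep(",", n_rev),
              rep("T", n_var_f), rep("t", n_var_r))
    qual <- rep("I", length(toks))
    # sprinkle markers that consume no quality
    extra <- sample(c("^]", "$", "+1A", "-2ac"), 3, replace = TRUE)
    pieces <- sample(c(toks, extra))
    # indel/start tokens must follow a base call in real pileups, but the
    # parser treats them positionally; quality string matches base calls only
    line <- paste("chr1", "9", "C", length(toks),
                  paste(pieces, collapse = ""), paste(qual, collapse = ""),
                  sep = "\t")
    r <- parse_pileup_line(line)
    expect_equal(r$counts[["C_fwd"]], n_fwd)
    expect_equal(r$counts[["C_rev"]], n_rev)
    expect_equal(r$counts[["T_fwd"]], n_var_f)
    expect_equal(r$counts[["T_rev"]], n_var_r)
    expect_equal(r$N, length(toks))
  }
})

test_that("count tables load, pair assays and flag unpaired sites", {
  rna <- data.frame(sample_id = "S1", chrom = "chr1", pos = 100L, assay = "RNA",
                    stringsAsFactors = FALSE)
  rna <- cbind(rna, as.data.frame(as.list(counts_vec(C_fwd = 40, C_rev = 40,
                                                     T_fwd = 3, T_rev = 2))))
  dna <- rna; dna$assay <- "DNA"
  ev <- load_count_table(rbind(rna, dna))
  expect_equal(nrow(ev), 1L)
  expect_false(ev$unpaired)
  expect_equal(ev$rna_C_fwd, 40)
  expect_equal(ev$dna_T_rev, 2)

  ev1 <- load_count_table(rna)        # RNA only
  expect_true(ev1$unpaired)
  expect_true(is.na(ev1$dna_C_fwd))

  expect_error(load_count_table(rbind(rna, rna)), "duplicate",
               class = "apobec3edit_format_error")
  bad <- rna; bad$C_fwd <- -1
  expect_error(load_count_table(bad), "non-negative",
               class = "apobec3edit_format_error")
})

test_that("pileup and count-table readers agree on equivalent input", {
  tf <- withr::local_tempfile(fileext = ".pileup")
  writeLines(paste("chr1", "100", "C", "5", "..,,T", q20(5), sep = "\t"), tf)
  via_pileup <- read_pileup(tf, "S1", "RNA")
  direct <- counts_vec(C_fwd = 2, C_rev = 2, T_fwd = 1)
  expect_equal(unlist(via_pileup[1, names(direct)]), direct)
})

test_that("reference/variant counts sum over strands by designated base", {
  cc <- counts_vec(C_fwd = 40, C_rev = 40, T_fwd = 3, T_rev = 2, A_fwd = 1)
  rv <- derive_RV(cc, "C", "T")
  expect_equal(rv$R, 80); expect_equal(rv$V, 5); expect_equal(rv$N, 86)
  expect_equal(rv$V_fwd, 3); expect_equal(rv$V_rev, 2)
  rv2 <- derive_RV(cc, "C", "A")
  expect_equal(rv2$R, 80); expect_equal(rv2$V, 1)
  rv0 <- derive_RV(counts_vec(), "C", "T")
  expect_equal(c(rv0$R, rv0$V, rv0$N), c(0, 0, 0))
  expect_error(derive_RV(cc, "C", "C"), "differ")
})

test_that("R + V never exceeds N and strand cells sum to totals", {
  set.seed(77)
  for (i in 1:50) {
    cc <- counts_vec()
    cc[] <- rpois(8, 5)
    rv <- derive_RV(cc, "C", "T")
    expect_lte(rv$R + rv$V, rv$N)
    expect_equal(rv$R, rv$R_fwd + rv$R_rev)
    expect_equal(rv$V, rv$V_fwd + rv$V_rev)
  }
})

test_that("count tables round-trip through write and read", {
  ev <- rbind(
    evidence_row("S1", "chr1", 100L, counts_vec(C_fwd = 10, T_rev = 2),
                 counts_vec(C_fwd = 20)),
    evidence_row("S2", "chr1", 100L, counts_vec(C_fwd = 5),
                 counts_vec(C_fwd = 9, C_rev = 3)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ev, tf, meta = c(note = "roundtrip"))
  back <- load_count_table(tf)
  back <- back[order(back$sample_id), ]
  rownames(back) <- NULL
  expect_equal(back[, sort(names(back))], ev[, sort(names(ev))])
})
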