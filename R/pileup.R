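# Pileup parsing and base-count tables: per-position sequencing evidence as
# strand-split, quality-filtered A/C/G/T call counts.

COUNT_COLS <- c("A_fwd", "A_rev", "C_fwd", "C_rev",
                "G_fwd", "G_rev", "T_fwd", "T_rev")

empty_base_counts <- function() {
  setNames(integer(8L), COUNT_COLS)
}

#' Parse one samtools mpileup text record into strand-split base counts
#'
#' Handles the standard 6-column mpileup dialect (`chrom pos ref depth bases
#' quals`).  `.`/`,` count as the reference base on the forward/reverse
#' strand; explicit base letters encode strand by case (upper = forward).
#' `^x` read-start markers (including the mapping-quality character), `$`
#' end markers and `+n`/`-n` indel runs are skipped and consume no quality
#' character; `*`, `>` and `<` consume a quality character but contribute no
#' base call.  Calls below `min_quality` (phred+33) are dropped; `N` calls
#' never count.
#'
#' @param line one mpileup text line.
#' @param min_quality minimum phred base quality (default 20).
#' @return Named list: `chrom`, `pos`, `ref`, `counts` (named integer vector
#'   over `A_fwd ... T_rev`) and `N` (sum of the eight cells).
#' @export
parse_pileup_line <- function(line, min_quality = 20L) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 6L) format_error("mpileup line has %d field(s); expected >= 6", length(f))
  chrom <- f[[1L]]
  pos <- as.integer(f[[2L]])
  ref <- toupper(f[[3L]])
  bases <- strsplit(f[[5L]], "", fixed = TRUE)[[1L]]
  quals <- strsplit(f[[6L]], "", fixed = TRUE)[[1L]]
  counts <- empty_base_counts()
  qi <- 0L
  i <- 1L
  nb <- length(bases)
  add_call <- function(base, fwd, q) {
    if (q >= min_quality && base %in% c("A", "C", "G", "T")) {
      cell <- paste0(base, if (fwd) "_fwd" else "_rev")
      counts[[cell]] <<- counts[[cell]] + 1L
    }
  }
  next_qual <- function() {
    qi <<- qi + 1L
    if (qi > length(quals)) {
      format_error("pileup bases/quality length mismatch at %s:%d", chrom, pos)
    }
    utf8ToInt(quals[[qi]]) - 33L
  }
  while (i <= nb) {
    ch <- bases[[i]]
    if (ch == "^") {
      i <- i + 2L                     # marker + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= nb && bases[[j]] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(bases[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(len)) format_error("malformed indel token at %s:%d", chrom, pos)
      i <- j + len                    # skip inserted/deleted sequence
    } else if (ch == "." ) {
      q <- next_qual(); add_call(ref, TRUE, q); i <- i + 1L
    } else if (ch == ",") {
      q <- next_qual(); add_call(ref, FALSE, q); i <- i + 1L
    } else if (ch %in% c("*", ">", "<")) {
      next_qual(); i <- i + 1L        # consumes quality, no base call
    } else if (grepl("[ACGTNacgtn]", ch)) {
      q <- next_qual()
      add_call(toupper(ch), ch %in% c("A", "C", "G", "T", "N"), q)
      i <- i + 1L
    } else {
      format_error("unexpected pileup character '%s' at %s:%d", ch, chrom, pos)
    }
  }
  if (qi != length(quals)) {
    format_error("pileup bases/quality length mismatch at %s:%d", chrom, pos)
  }
  list(chrom = chrom, pos = pos, ref = ref, counts = counts,
       N = sum(counts))
}

#' Read a whole single-sample mpileup file into a count table
#'
#' @param path mpileup text file (6-column, one sample).
#' @param sample_id sample identifier to attach.
#' @param assay `"RNA"` or `"DNA"`.
#' @param min_quality minimum phred base quality.
#' @return data.frame in count-table layout: `sample_id chrom pos assay`
#'   plus the eight strand-split base-count columns.
#' @export
read_pileup <- function(path, sample_id, assay = c("RNA", "DNA"),
                        min_quality = 20L) {
  assay <- match.arg(assay)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, parse_pileup_line, min_quality = min_quality)
  df <- data.frame(sample_id = sample_id,
                   chrom = vapply(rows, `[[`, "", "chrom"),
                   pos = vapply(rows, `[[`, 0L, "pos"),
                   assay = assay,
                   stringsAsFactors = FALSE)
  cnt <- do.call(rbind, lapply(rows, `[[`, "counts"))
  cbind(df, as.data.frame(cnt))
}

#' Load a tab-delimited paired RNA/DNA count table
#'
#' Expected columns: `sample_id chrom pos assay` (`RNA` or `DNA`) followed
#' by the eight strand-split base-count columns `A_fwd ... T_rev`.  RNA and
#' DNA rows are paired per (sample, site); a site with only one assay is
#' retained and flagged `unpaired`, with the missing assay's counts `NA`.
#'
#' @param path file path, or a data.frame already in that layout.
#' @return data.frame with one row per (sample, site): `sample_id`, `chrom`,
#'   `pos`, `unpaired`, and `rna_*` / `dna_*` count columns.
#' @export
load_count_table <- function(path) {
  df <- if (is.data.frame(path)) path else read_tsv_meta(path)
  need <- c("sample_id", "chrom", "pos", "assay", COUNT_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    format_error("count table missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (!all(df$assay %in% c("RNA", "DNA"))) {
    format_error("assay column must be 'RNA' or 'DNA'")
  }
  cnt <- as.matrix(df[, COUNT_COLS])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    format_error("base counts must be non-negative integers")
  }
  key <- paste(df$sample_id, df$chrom, df$pos, df$assay)
  if (anyDuplicated(key)) {
    format_error("duplicate (sample, site, assay) row(s), e.g. %s",
                 key[duplicated(key)][1L])
  }
  pair_key <- paste(df$sample_id, df$chrom, df$pos, sep = "\r")
  keys <- unique(pair_key)
  rna <- df[df$assay == "RNA", , drop = FALSE]
  dna <- df[df$assay == "DNA", , drop = FALSE]
  rna_idx <- match(keys, paste(rna$sample_id, rna$chrom, rna$pos, sep = "\r"))
  dna_idx <- match(keys, paste(dna$sample_id, dna$chrom, dna$pos, sep = "\r"))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1L], chrom = parts[, 2L],
                    pos = as.integer(parts[, 3L]),
                    unpaired = is.na(rna_idx) | is.na(dna_idx),
                    stringsAsFactors = FALSE)
  rna_cnt <- as.matrix(rna[, COUNT_COLS])[rna_idx, , drop = FALSE]
  dna_cnt <- as.matrix(dna[, COUNT_COLS])[dna_idx, , drop = FALSE]
  colnames(rna_cnt) <- paste0("rna_", COUNT_COLS)
  colnames(dna_cnt) <- paste0("dna_", COUNT_COLS)
  cbind(out, as.data.frame(rna_cnt), as.data.frame(dna_cnt))
}

#' Write site evidence back to the long count-table format
#' @param evidence data.frame as returned by [load_count_table].
#' @param path output path.
#' @param meta optional metadata lines.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(evidence, path, meta = NULL) {
  long <- list()
  for (assay in c("RNA", "DNA")) {
    pre <- if (assay == "RNA") "rna_" else "dna_"
    cnt <- as.matrix(evidence[, paste0(pre, COUNT_COLS)])
    keep <- rowSums(is.na(cnt)) == 0L
    d <- data.frame(sample_id = evidence$sample_id[keep],
                    chrom = evidence$chrom[keep], pos = evidence$pos[keep],
                    assay = assay, stringsAsFactors = FALSE)
    cnt <- cnt[keep, , drop = FALSE]
    colnames(cnt) <- COUNT_COLS
    long[[assay]] <- cbind(d, as.data.frame(cnt))
  }
  long <- do.call(rbind, long)
  long <- long[order(long$sample_id, long$chrom, long$pos, long$assay), ]
  rownames(long) <- NULL
  write_tsv_meta(long, path, meta = meta)
}

#' Reference/variant counts from strand-split base counts
#'
#' Given the eight-cell strand-split counts and the designated reference and
#' variant bases, returns the strand-summed reference count R, variant count
#' V, their per-strand components and the total call count N.  Bases other
#' than ref/var contribute to N only.
#'
#' @param counts named numeric vector (or 1-row data.frame/matrix) with the
#'   `A_fwd ... T_rev` cells; `NA` cells are treated as a missing assay.
#' @param ref_base,var_base distinct bases in `A`,`C`,`G`,`T`.
#' @return Named list with `R`, `V`, `N`, `R_fwd`, `R_rev`, `V_fwd`, `V_rev`.
#' @export
derive_RV <- function(counts, ref_base, var_base) {
  if (ref_base == var_base) format_error("ref_base and var_base must differ")
  cc <- unlist(counts)[COUNT_COLS]
  list(R = unname(cc[[paste0(ref_base, "_fwd")]] + cc[[paste0(ref_base, "_rev")]]),
       V = unname(cc[[paste0(var_base, "_fwd")]] + cc[[paste0(var_base, "_rev")]]),
       N = sum(cc),
       R_fwd = unname(cc[[paste0(ref_base, "_fwd")]]),
       R_rev = unname(cc[[paste0(ref_base, "_rev")]]),
       V_fwd = unname(cc[[paste0(var_base, "_fwd")]]),
       V_rev = unname(cc[[paste0(var_base, "_rev")]]))
}

# Vectorised internal version: evidence columns with prefix ("rna_"/"dna_"),
# per-row ref/var base vectors.  Returns a data.frame of R,V,N and strand
# components; NA counts (missing assay) propagate to NA.
derive_RV_matrix <- function(evidence, prefix, ref, var) {
  cnt <- as.matrix(evidence[, paste0(prefix, COUNT_COLS), drop = FALSE])
  colnames(cnt) <- COUNT_COLS
  n <- nrow(cnt)
  pick <- function(base, strand) cnt[cbind(seq_len(n), match(paste0(base, strand), COUNT_COLS))]
  R_fwd <- pick(ref, "_fwd"); R_rev <- pick(ref, "_rev")
  V_fwd <- pick(var, "_fwd"); V_rev <- pick(var, "_rev")
  data.frame(R = R_fwd + R_rev, V = V_fwd + V_rev, N = rowSums(cnt),
             R_fwd = R_fwd, R_rev = R_rev, V_fwd = V_fwd, V_rev = V_rev)
}
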