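# Editing-site catalog: reading, validation, ref/var resolution, and
# negative-control position selection.

REGIONS <- c("CDS", "5'UTR", "3'UTR", "noncoding", "intergenic")
EFFECTS <- c("synonymous", "nonsynonymous", "stopgain", "none")
MODES   <- c("C-to-U", "C-to-A", "negative-control")

#' Construct a site catalog from a data.frame
#'
#' A site catalog is an ordered table of genomic positions known (or, for
#' negative controls, known not) to undergo APOBEC3-mediated C-to-U RNA
#' editing.  Coordinates are 1-based fully-closed; `strand` is the
#' transcription strand, which determines the reference/variant base pair at
#' the site (C/T on `+`, G/A on `-` for C-to-U).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand` and
#'   optionally `gene`, `region`, `effect`, `source`.
#' @param mode editing mode of the analysis this catalog feeds:
#'   `"C-to-U"`, `"C-to-A"` (hypothetical-control mode) or
#'   `"negative-control"`.
#' @return An object of class `site_catalog`: the validated data.frame with
#'   attribute `mode`.
#' @export
site_catalog <- function(sites, mode = "C-to-U") {
  mode <- match.arg(mode, MODES)
  if (!is.data.frame(sites) || nrow(sites) == 0L) {
    format_error("site catalog must be a non-empty data.frame")
  }
  need <- c("chrom", "pos", "strand")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    format_error("site table is missing required column(s): %s",
                 paste(miss, collapse = ", "))
  }
  for (col in c("gene", "region", "effect", "source")) {
    if (is.null(sites[[col]])) {
      sites[[col]] <- if (col == "region") "noncoding" else
        if (col == "effect") "none" else ""
    }
  }
  sites$chrom <- as.character(sites$chrom)
  pos <- suppressWarnings(as.numeric(sites$pos))
  bad <- which(is.na(pos) | pos < 1 | pos != floor(pos))
  if (length(bad)) {
    format_error("malformed 1-based coordinate in row(s): %s",
                 paste(head(bad, 10L), collapse = ", "))
  }
  sites$pos <- as.integer(pos)
  bad <- which(!sites$strand %in% c("+", "-"))
  if (length(bad)) {
    format_error("strand must be '+' or '-'; offending row(s): %s",
                 paste(head(bad, 10L), collapse = ", "))
  }
  bad <- which(!sites$region %in% REGIONS)
  if (length(bad)) {
    format_error("region not in {%s}; offending row(s): %s",
                 paste(REGIONS, collapse = ", "), paste(head(bad, 10L), collapse = ", "))
  }
  bad <- which(!sites$effect %in% EFFECTS)
  if (length(bad)) {
    format_error("effect not in {%s}; offending row(s): %s",
                 paste(EFFECTS, collapse = ", "), paste(head(bad, 10L), collapse = ", "))
  }
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (chrom,pos) row(s) collapsed to first occurrence",
                    sum(duplicated(key))), call. = FALSE)
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  rownames(sites) <- NULL
  sites <- sites[, c("chrom", "pos", "strand", "gene", "region", "effect", "source")]
  structure(sites, class = c("site_catalog", "data.frame"), mode = mode)
}

#' Editing mode of a site catalog
#' @param catalog a `site_catalog`.
#' @return The mode string.
#' @export
catalog_mode <- function(catalog) attr(catalog, "mode", exact = TRUE)

#' Read an editing-site catalog from a tab-delimited file
#'
#' Accepts either the native 7-column format (`chrom pos strand gene region
#' effect source`, header required, 1-based positions) or 6-column BED
#' (no header, 0-based half-open, strand in column 6; converted on read).
#' Duplicate (chrom,pos) rows are collapsed to the first occurrence with a
#' warning; malformed coordinates are rejected with row-numbered diagnostics.
#'
#' @param path file path.
#' @param mode editing mode for the run (a property of the analysis, not of
#'   the file; one site file serves C-to-U, C-to-A and control runs).
#' @return A [site_catalog].
#' @export
parse_site_table <- function(path, mode = "C-to-U") {
  if (!file.exists(path)) format_error("site file not found: %s", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (!length(first)) format_error("site file is empty: %s", path)
  fields <- strsplit(first[[1L]], "\t", fixed = TRUE)[[1L]]
  is_bed <- length(fields) == 6L && !any(c("chrom", "pos") %in% fields)
  if (is_bed) {
    bed <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = "")
    if (ncol(bed) != 6L) format_error("BED site file must have 6 columns")
    df <- data.frame(chrom = as.character(bed[[1L]]),
                     pos = bed[[2L]] + 1L,   # 0-based half-open start -> 1-based
                     strand = as.character(bed[[6L]]),
                     gene = as.character(bed[[4L]]),
                     stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_meta(path)
  }
  site_catalog(df, mode = mode)
}

#' Write a site catalog as tab-delimited text
#' @param catalog a [site_catalog].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(catalog, path) {
  write_tsv_meta(as.data.frame(catalog), path, meta = c(mode = catalog_mode(catalog)))
}

#' Reference and variant base for a site
#'
#' Site lists are recorded as the transcribed C position; on the genome the
#' examined base pair follows the transcription strand.  For C-to-U editing
#' the variant appears as T on `+`-strand genes and A on `-`-strand genes.
#' The hypothetical C-to-A mode (a workflow negative control) swaps the
#' variant to A (`+`) / T (`-`).
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param mode `"C-to-U"` or `"C-to-A"`; `"negative-control"` sites are
#'   evaluated with C-to-U base pairs.
#' @return data.frame with columns `ref` and `var`.
#' @export
resolve_ref_var <- function(strand, mode = "C-to-U") {
  if (!all(strand %in% c("+", "-"))) format_error("strand must be '+' or '-'")
  if (!mode %in% MODES) format_error("unknown editing mode: %s", mode)
  plus <- strand == "+"
  if (mode == "C-to-A") {
    data.frame(ref = ifelse(plus, "C", "G"), var = ifelse(plus, "A", "T"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ref = ifelse(plus, "C", "G"), var = ifelse(plus, "T", "A"),
               stringsAsFactors = FALSE)
  }
}

#' Select negative-control positions near catalog sites
#'
#' Draws `n` positions adjacent to cataloged editing sites (within
#' `offset_range` bp, same chromosome and transcription strand) that do not
#' coincide with any cataloged position.  Without a reference genome the
#' "transcribed as C" property of a candidate cannot be verified from
#' sequence, so a vetted candidate table (columns `chrom`, `pos`, `strand`)
#' may be supplied; otherwise candidates are the offset positions themselves
#' and the caller is responsible for the base-identity assumption.
#'
#' @param catalog a [site_catalog].
#' @param n number of control positions to select.
#' @param offset_range maximum distance (bp) from a cataloged site.
#' @param seed integer seed; selection is deterministic given the seed.
#' @param candidates optional data.frame of pre-vetted candidate positions.
#' @return A [site_catalog] with mode `"negative-control"`.
#' @export
pick_negative_controls <- function(catalog, n, offset_range = 12L, seed,
                                   candidates = NULL) {
  stopifnot(inherits(catalog, "site_catalog"))
  if (n == 0L) {
    empty <- as.data.frame(catalog)[0, , drop = FALSE]
    return(structure(empty, class = c("site_catalog", "data.frame"),
                     mode = "negative-control"))
  }
  if (is.null(candidates)) {
    offs <- setdiff(seq(-offset_range, offset_range), 0L)
    candidates <- do.call(rbind, lapply(offs, function(o) {
      data.frame(chrom = catalog$chrom, pos = catalog$pos + o,
                 strand = catalog$strand, stringsAsFactors = FALSE)
    }))
  }
  candidates <- candidates[candidates$pos >= 1L, , drop = FALSE]
  key <- paste(candidates$chrom, candidates$pos)
  candidates <- candidates[!duplicated(key), , drop = FALSE]
  in_catalog <- paste(candidates$chrom, candidates$pos) %in%
    paste(catalog$chrom, catalog$pos)
  candidates <- candidates[!in_catalog, , drop = FALSE]
  if (n > nrow(candidates)) {
    format_error("requested %d control positions but only %d candidates available",
                 n, nrow(candidates))
  }
  idx <- with_private_seed(seed, sample.int(nrow(candidates), n))
  sel <- candidates[sort(idx), , drop = FALSE]
  sel$gene <- ""
  sel$region <- "noncoding"
  sel$effect <- "none"
  sel$source <- "negative-control"
  rownames(sel) <- NULL
  structure(sel[, c("chrom", "pos", "strand", "gene", "region", "effect", "source")],
            class = c("site_catalog", "data.frame"), mode = "negative-control")
}
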