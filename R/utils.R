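# Internal helpers shared across modules.

# Run code with a private RNG state: seeds reproducibly, then restores the
# caller's .Random.seed so library calls never perturb user randomness.
with_private_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Write a tab-delimited table with `#` metadata header lines
#'
#' All pipeline outputs are plain UTF-8 TSV with optional `# key=value`
#' metadata lines before the column header, so that thresholds and run
#' parameters travel with the data.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param meta named character/numeric vector written as `# name=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a tab-delimited table, skipping `#` metadata lines
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_meta <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, quote = "")
}

# Abort with a consistent error class so callers/tests can discriminate
# malformed-input failures from programming errors.
format_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("apobec3edit_format_error", "error")))
}
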