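#' Write a result table as TSV with a provenance comment line
#'
#' All pipeline outputs are tab-separated with a header preceded by a single
#' `#`-prefixed provenance line (package version and timestamp are omitted
#' when `reproducible = TRUE` so that identical inputs give byte-identical
#' files).
#'
#' @param x data frame to write.
#' @param path output path.
#' @param what short description recorded on the provenance line.
#' @param reproducible logical; if `TRUE` (default) the provenance line
#'   contains no timestamp.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, what = "result", reproducible = TRUE) {
  stamp <- if (reproducible) "" else paste0(" generated=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  header <- paste0("# somaticASE ", what, stamp)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

# Internal: stop with a consistent error class
ase_stop <- function(msg, class = "somaticASE_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Internal: condition-logged messages, silenced via option
ase_log <- function(...) {
  if (isTRUE(getOption("somaticASE.quiet", FALSE))) return(invisible(NULL))
  message("[somaticASE] ", ...)
}

# Internal: a unique variant key used across all result tables
variant_key <- function(sample_id, chrom, pos, ref, alt) {
  paste(sample_id, chrom, pos, ref, alt, sep = ":")
}
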