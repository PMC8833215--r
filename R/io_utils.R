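#' Write a TSV with a serialized config header
#'
#' Every pipeline output carries its full run configuration as a
#' `# config: {json}` first line, so any downstream number can be traced to
#' the exact parameters that produced it. Readers in this package skip
#' `#`-prefixed lines.
#'
#' @param df data frame.
#' @param path output file.
#' @param config optional list; serialized compactly as JSON.
#' @return `path`, invisibly.
#' @export
write_tsv_with_config <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# config: ",
                      jsonlite::toJSON(config, auto_unbox = TRUE)), con)
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  for (nm in names(df)[list_cols])
    df[[nm]] <- vapply(df[[nm]], paste, character(1), collapse = ",")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path file path.
#' @return data frame (config header lines skipped).
#' @export
read_tsv_with_config <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
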