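# TSV writers with a reproducibility header.  Every table written by the
# pipeline starts with comment lines recording the tool version, a
# configuration fingerprint and the seed, and contains no wall-clock
# content, so re-running a command on identical inputs is byte-identical.

output_header <- function(config_hash = "none", seed = NA) {
  c(sprintf("# scfvtools=%s",
            as.character(utils::packageVersion("scfvtools"))),
    sprintf("# config=%s", config_hash),
    sprintf("# seed=%s", ifelse(is.na(seed), "none", seed)))
}

#' Write a pipeline table as headered TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @param config_hash fingerprint string (see [hash_config()]).
#' @param seed seed recorded in the header.
#' @return invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, config_hash = "none", seed = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(config_hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a headered pipeline TSV
#' @param path file written by [write_tsv_report()].
#' @return data.frame (header comments dropped).
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Fingerprint a configuration object
#' @param config any list; serialized canonically to JSON and hashed.
#' @return 8-hex-digit string.
#' @export
hash_config <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE))
}
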