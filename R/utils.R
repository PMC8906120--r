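`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom methods is
#' @importFrom stats pnorm pwilcox p.adjust rnbinom rbinom sd dist
#' @importFrom utils head
NULL

# Write a data.frame atomically (temp file in the same directory, then rename)
# so partially-written outputs never appear under the final name.
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  data.table::fwrite(df, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# dense numeric matrix from either base matrix or Matrix classes
as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else m
}
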