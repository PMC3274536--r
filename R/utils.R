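#' @keywords internal
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @useDynLib uniwrs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

# write a TSV atomically: temp file in the same directory, then rename
write_atomic_tsv <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv.tmp")
  readr::write_tsv(x, tmp, progress = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
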