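#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm pchisq pt qchisq rnorm runif setNames
#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (a <= b within machine precision)
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

two_sided_p <- function(z) 2 * pnorm(abs(z), lower.tail = FALSE)

# TSV writer used by every output path: one commented header line carrying
# provenance, then readr's deterministic formatting.
write_mrpipe_tsv <- function(x, path, seed = NULL) {
  ver <- as.character(utils::packageVersion("mrpipe"))
  hdr <- paste0("# mrpipe ", ver,
                if (!is.null(seed)) paste0(" seed=", seed) else "")
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_mrpipe_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}
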