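#' @keywords internal
#' @noRd
clampPct <- function(x, lower = 0, upper = 100) {
  pmin(pmax(x, lower), upper)
}

#' Derive a deterministic per-component substream seed from a global seed
#'
#' Keeps every derived seed inside the 32-bit signed integer range so it can
#' be passed to set.seed() on any platform.
#' @keywords internal
#' @noRd
substreamSeed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 7919 + as.double(component) * 104729) %%
               2147483629)
}

#' Polynomial rolling hash of a character string (hex digest)
#'
#' Content fingerprint for provenance manifests: base-31 polynomial hash
#' modulo the Mersenne prime 2^31 - 1. All intermediates stay well below
#' 2^53, so the arithmetic is exact in doubles. Not cryptographic.
#' @keywords internal
#' @noRd
contentHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

assertPct <- function(x, what = deparse(substitute(x))) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop(sprintf("%s must lie in [0, 100]; offending positions: %s",
                 what, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
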