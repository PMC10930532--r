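#' Normalize gene symbols
#'
#' Upper-cases, strips surrounding whitespace, and removes a trailing
#' DepMap-style \code{" (ENTREZID)"} suffix so that symbol-keyed datasets from
#' different sources (GEO, TCGA, DepMap) can be merged on a common key.
#'
#' @param x Character vector of raw gene identifiers.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbols(c("WWTR1 (25937)", " ctgf "))
#' @export
normalize_symbols <- function(x) {
  x <- sub("\\s*\\([0-9]+\\)\\s*$", "", x)
  toupper(trimws(x))
}

# Derive a stream-specific 32-bit seed from a base seed, so independent
# generators never share RNG state.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(expression = 101L, contrasts = 211L, dependency = 307L,
               tumors = 401L, peaks = 503L, gsea = 601L, perm = 701L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    sum(utf8ToInt(stream)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
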