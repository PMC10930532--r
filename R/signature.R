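#' Derive a consensus up/down signature from oriented DE contrasts
#'
#' A gene enters the Up set iff it is called up (per
#' \code{\link{call_regulated}}) in the anchor contrast AND in at least
#' \code{min_support} of the supporting contrasts, all in the same
#' orientation-corrected direction; the Down set is symmetric. A gene that
#' meets the up rule in the anchor but the down rule in any support (or vice
#' versa) is direction-inconsistent and dropped entirely. Genes absent from a
#' support table count as non-supporting, not contradicting.
#'
#' @param anchor Oriented \code{DETable} for the anchor cell line.
#' @param supports List of oriented \code{DETable}s.
#' @param min_support Minimum number of supporting contrasts (default 2).
#' @param fc_threshold,fdr_threshold Passed to \code{\link{call_regulated}}.
#' @param name Prefix for the emitted gene set names (\code{<name>_UP},
#'   \code{<name>_DOWN}).
#' @return list of class \code{GeneSignature}: \code{up}, \code{down}
#'   (\code{GeneSet}s, possibly NULL when empty) and \code{provenance}, a
#'   data.frame mapping each member to the contrast ids supporting it.
#' @export
derive_consensus <- function(anchor, supports, min_support = 2,
                             fc_threshold = 2, fdr_threshold = 0.05,
                             name = "YAP_TAZ") {
  stopifnot(inherits(anchor, "DETable"), length(supports) >= 1L)
  if (min_support > length(supports))
    stop("min_support exceeds the number of supporting contrasts")
  calls <- lapply(supports, call_regulated, fc_threshold, fdr_threshold)
  anchor_call <- call_regulated(anchor, fc_threshold, fdr_threshold)
  ids <- vapply(supports, function(s) attr(s, "contrast_id"), "")

  count_support <- function(genes, direction) {
    vapply(genes, function(g)
      sum(vapply(calls, function(cl) g %in% cl[[direction]], NA)), 0L)
  }
  conflicted <- function(genes, opposite) {
    vapply(genes, function(g)
      any(vapply(calls, function(cl) g %in% cl[[opposite]], NA)), NA)
  }
  pick <- function(direction, opposite) {
    cand <- anchor_call[[direction]]
    n_sup <- count_support(cand, direction)
    keep <- n_sup >= min_support & !conflicted(cand, opposite)
    sort(cand[keep])
  }
  up <- pick("up", "down")
  down <- pick("down", "up")
  stopifnot(length(intersect(up, down)) == 0L)

  provenance <- do.call(rbind, lapply(c(up, down), function(g) {
    dir <- if (g %in% up) "up" else "down"
    sup <- ids[vapply(calls, function(cl) g %in% cl[[dir]], NA)]
    data.frame(gene = g, direction = dir,
               anchor = attr(anchor, "contrast_id"),
               supports = paste(sup, collapse = ","),
               n_support = length(sup), stringsAsFactors = FALSE)
  }))

  structure(list(
    up   = if (length(up))   gene_set(paste0(name, "_UP"),   up,
                                      "consensus up-regulated") else NULL,
    down = if (length(down)) gene_set(paste0(name, "_DOWN"), down,
                                      "consensus down-regulated") else NULL,
    provenance = provenance %||% data.frame()
  ), class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature: %d up / %d down\n",
              length(x$up$genes), length(x$down$genes)))
  invisible(x)
}

#' Write a signature as GMT plus provenance TSV
#'
#' @param sig A \code{GeneSignature}.
#' @param gmt_path,provenance_path Output paths.
#' @export
write_signature <- function(sig, gmt_path, provenance_path = NULL) {
  stopifnot(inherits(sig, "GeneSignature"))
  write_gmt(Filter(Negate(is.null), list(sig$up, sig$down)), gmt_path)
  if (!is.null(provenance_path))
    utils::write.table(sig$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(gmt_path)
}

#' Venn region counts for 2-4 gene sets
#'
#' Returns the size of every membership region (all 2^k - 1 label
#' combinations); regions partition the union of the sets.
#'
#' @param sets Named list of character vectors (2 to 4 sets).
#' @return Named integer vector; names are label combinations joined by
#'   \code{"&"}, e.g. \code{"A"}, \code{"A&B"}.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("venn_counts needs 2-4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}
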