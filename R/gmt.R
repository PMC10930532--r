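#' Gene set constructor
#'
#' @param name Set name.
#' @param genes Character vector of member symbols; normalized and
#'   deduplicated (first occurrence wins, order preserved).
#' @param description Free-text description (GMT column 2).
#' @return An object of class \code{GeneSet}.
#' @export
gene_set <- function(name, genes, description = "na") {
  genes <- normalize_symbols(genes)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    warning("duplicate gene(s) in set '", name, "' deduplicated")
    genes <- genes[!duplicated(genes)]
  }
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = name, description = description, genes = genes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' (%d genes)\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line is \code{name TAB description TAB gene TAB gene ...}. Lines with
#' fewer than three fields are an error (reported with the line number);
#' duplicate genes within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of \code{GeneSet} objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes...",
                   i, length(f)))
    gene_set(f[1L], f[-(1:2)], description = f[2L])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param genesets A \code{GeneSet} or list of them.
#' @param path Output path.
#' @export
write_gmt <- function(genesets, path) {
  if (inherits(genesets, "GeneSet")) genesets <- list(genesets)
  lines <- vapply(genesets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
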