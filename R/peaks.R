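#' Simplified gene model
#'
#' One record per gene: chromosome, strand, transcript span as a 0-based
#' half-open interval, and exon intervals within it. The TSS is derived from
#' the strand: span start on +, span end - 1 on -. UTR intervals are not part
#' of this model, so the annotation cascade skips the UTR categories.
#'
#' @param gene_id,chrom,strand Character vectors (strand "+" or "-").
#' @param start,end Integer span bounds, 0-based half-open.
#' @param exon_starts,exon_ends Lists (or comma-joined strings) of exon
#'   bounds, 0-based half-open, within the span.
#' @return data.frame of class \code{GeneModel} with list-columns
#'   \code{exon_starts}/\code{exon_ends} and a derived \code{tss} column.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exon_starts = NULL, exon_ends = NULL) {
  gene_id <- normalize_symbols(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in model")
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(start >= end)) stop("gene span must have start < end")
  parse_list <- function(v, n) {
    if (is.null(v)) return(vector("list", n))
    if (is.list(v)) return(v)
    lapply(strsplit(as.character(v), ","), function(s) as.integer(s[nzchar(s)]))
  }
  es <- parse_list(exon_starts, length(gene_id))
  ee <- parse_list(exon_ends, length(gene_id))
  for (i in seq_along(gene_id)) {
    if (length(es[[i]]) != length(ee[[i]]))
      stop("exon bound mismatch for ", gene_id[i])
    if (length(es[[i]]) &&
        (any(es[[i]] >= ee[[i]]) || any(es[[i]] < start[i]) || any(ee[[i]] > end[i])))
      stop("exon outside span for ", gene_id[i])
  }
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   tss = ifelse(strand == "+", as.integer(start),
                                as.integer(end) - 1L),
                   stringsAsFactors = FALSE)
  df$exon_starts <- es
  df$exon_ends <- ee
  class(df) <- c("GeneModel", "data.frame")
  df
}

#' Read a gene model TSV
#'
#' Columns: gene_id, chrom, strand, start, end, exon_starts, exon_ends
#' (comma-joined lists; 0-based half-open coordinates).
#'
#' @param path TSV path.
#' @return A \code{GeneModel}.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(exon_starts = "character",
                                         exon_ends = "character"))
  gene_model(df$gene_id, df$chrom, df$strand, df$start, df$end,
             df$exon_starts, df$exon_ends)
}

#' Write a gene model TSV (inverse of \code{read_gene_model})
#' @param model A \code{GeneModel}.
#' @param path Output path.
#' @export
write_gene_model <- function(model, path) {
  join <- function(l) vapply(l, paste, "", collapse = ",")
  df <- data.frame(gene_id = model$gene_id, chrom = model$chrom,
                   strand = model$strand, start = model$start, end = model$end,
                   exon_starts = join(model$exon_starts),
                   exon_ends = join(model$exon_ends), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peaks from a BED file (3-6 columns, 0-based half-open)
#'
#' @param path BED path.
#' @return data.frame: chrom, start, end, and name/score when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (any(df$start >= df$end)) stop("BED interval with start >= end")
  df
}

#' Write peaks as BED
#' @param peaks data.frame with chrom, start, end (plus optional name).
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(peaks))
  utils::write.table(peaks[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 0-based half-open -> GRanges (1-based closed).
gr0 <- function(chrom, start, end, seqlevels)
  GenomicRanges::GRanges(factor(chrom, levels = seqlevels),
                         IRanges::IRanges(start + 1L, end))

#' Annotate ChIP-seq peaks to genes with a fixed priority cascade
#'
#' Each peak is tested against genomic features in the priority order
#' Promoter, Exon, Intron, Downstream, Intergenic (the UTR categories of the
#' full order are skipped because the simplified gene model carries no UTRs);
#' the first matching category wins and the peak is assigned to the owning
#' gene. The promoter is the strand-adjusted window [tss - w, tss + w]
#' (inclusive of both ends); Downstream extends \code{downstream_window} bp
#' past the gene's 3' end. A peak overlapping promoters of several genes goes
#' to the gene with the smallest |distance to TSS| (ties broken
#' lexicographically). Intergenic peaks record their nearest gene by TSS
#' distance for context but are assigned no gene.
#'
#' All coordinates are BED-style 0-based half-open; distance_to_tss is the
#' signed strand-aware offset of the peak midpoint from the TSS (positive =
#' downstream of the TSS).
#'
#' @param peaks data.frame with chrom, start, end (0-based half-open).
#' @param model A \code{GeneModel}.
#' @param tss_window Promoter half-width in bp (default 1000).
#' @param downstream_window Downstream extent in bp (default 3000).
#' @return data.frame: peak coordinates, category, gene_id (NA for
#'   Intergenic), nearest_gene, distance_to_tss.
#' @export
annotate_peaks <- function(peaks, model, tss_window = 1000,
                           downstream_window = 3000) {
  stopifnot(inherits(model, "GeneModel"))
  if (tss_window <= 0 || downstream_window <= 0) stop("windows must be > 0")
  known <- unique(model$chrom)
  unknown <- !(peaks$chrom %in% known)
  if (any(unknown))
    warning(sum(unknown), " peak(s) on chromosome(s) absent from the model; ",
            "annotated Intergenic")
  seqlv <- unique(c(known, peaks$chrom))

  peak_gr <- gr0(peaks$chrom, peaks$start, peaks$end, seqlv)
  w <- as.integer(tss_window)
  prom_gr <- gr0(model$chrom, model$tss - w, model$tss + w + 1L, seqlv)
  span_gr <- gr0(model$chrom, model$start, model$end, seqlv)
  down_gr <- gr0(model$chrom,
                 ifelse(model$strand == "+", model$end,
                        model$start - as.integer(downstream_window)),
                 ifelse(model$strand == "+",
                        model$end + as.integer(downstream_window),
                        model$start), seqlv)
  nex <- lengths(model$exon_starts)
  exon_gene <- rep.int(seq_len(nrow(model)), nex)
  exon_gr <- gr0(model$chrom[exon_gene],
                 unlist(model$exon_starts) %||% integer(),
                 unlist(model$exon_ends) %||% integer(), seqlv)

  mid <- (peaks$start + peaks$end - 1) / 2
  # signed strand-aware distance of peak i's midpoint to gene g's TSS
  tss_dist <- function(i, g)
    ifelse(model$strand[g] == "+", mid[i] - model$tss[g], model$tss[g] - mid[i])

  hits_by_peak <- function(subject_gr, gene_of_subject) {
    h <- GenomicRanges::findOverlaps(peak_gr, subject_gr)
    split(gene_of_subject[S4Vectors::subjectHits(h)],
          factor(S4Vectors::queryHits(h), levels = seq_len(nrow(peaks))))
  }
  prom_hits <- hits_by_peak(prom_gr, seq_len(nrow(model)))
  span_hits <- hits_by_peak(span_gr, seq_len(nrow(model)))
  exon_hits <- hits_by_peak(exon_gr, exon_gene)
  down_hits <- hits_by_peak(down_gr, seq_len(nrow(model)))

  pick <- function(i, gs) {
    d <- tss_dist(i, gs)
    gs[order(abs(d), model$gene_id[gs])][1L]
  }
  n <- nrow(peaks)
  category <- character(n); gene_id <- rep(NA_character_, n)
  nearest <- character(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    g <- NULL
    if (length(prom_hits[[i]])) { category[i] <- "Promoter"; g <- pick(i, prom_hits[[i]]) }
    else if (length(exon_hits[[i]])) { category[i] <- "Exon"; g <- pick(i, exon_hits[[i]]) }
    else if (length(span_hits[[i]])) { category[i] <- "Intron"; g <- pick(i, span_hits[[i]]) }
    else if (length(down_hits[[i]])) { category[i] <- "Downstream"; g <- pick(i, down_hits[[i]]) }
    else category[i] <- "Intergenic"
    if (!is.null(g)) {
      gene_id[i] <- model$gene_id[g]
      nearest[i] <- model$gene_id[g]
      dist[i] <- tss_dist(i, g)
    } else {
      same <- which(model$chrom == peaks$chrom[i])
      if (length(same)) {
        d <- tss_dist(i, same)
        j <- same[order(abs(d), model$gene_id[same])][1L]
        nearest[i] <- model$gene_id[j]
        dist[i] <- tss_dist(i, j)
      } else {
        nearest[i] <- NA_character_; dist[i] <- NA_real_
      }
    }
  }
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             category = category, gene_id = gene_id, nearest_gene = nearest,
             distance_to_tss = dist, stringsAsFactors = FALSE)
}

#' Binary gene x dataset peak matrix
#'
#' Cell (g, d) is 1 iff at least one non-Intergenic peak in dataset d was
#' assigned to gene g — the "at least 1 peak mapped to that gene" semantics
#' of the signature/ChIP comparison heatmap. Intergenic nearest-gene context
#' never contributes.
#'
#' @param annotations_by_dataset Named list of \code{annotate_peaks} outputs.
#' @param genes Genes for the rows (order preserved).
#' @param model Optional \code{GeneModel}; genes absent from it trigger a
#'   warning (their rows are all zero by construction).
#' @return Integer matrix, genes x datasets.
#' @export
gene_peak_matrix <- function(annotations_by_dataset, genes, model = NULL) {
  if (length(annotations_by_dataset) == 0L) stop("no datasets")
  if (is.null(names(annotations_by_dataset)))
    stop("datasets must be named")
  genes <- normalize_symbols(genes)
  if (!is.null(model)) {
    absent <- setdiff(genes, model$gene_id)
    if (length(absent))
      warning("gene(s) absent from the model: ", paste(absent, collapse = ", "))
  }
  m <- vapply(annotations_by_dataset, function(ann) {
    assigned <- unique(ann$gene_id[!is.na(ann$gene_id)])
    as.integer(genes %in% assigned)
  }, integer(length(genes)))
  if (length(genes) == 1L)
    m <- matrix(m, nrow = 1L, dimnames = list(genes, names(annotations_by_dataset)))
  else rownames(m) <- genes
  m
}
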