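# Overlap accounting between externally predicted horizontal-gene-transfer
# (HGT) intervals and the genome/duplicate set. Interval predictions come
# from compositional scanners run outside this package; here they are
# merged, clipped, and intersected with replicons and genes using the
# GenomicRanges machinery.

#' Read a BED3 file of HGT intervals against a genome bundle
#'
#' BED intervals are 0-based half-open; they are converted to 1-based
#' closed ranges, clipped to their replicon's length (with a warning),
#' and merged. Records on replicons absent from the bundle are an error.
#'
#' @param path BED3 file.
#' @param bundle A [genome_bundle()] supplying replicon lengths.
#' @return A merged [GenomicRanges::GRanges-class] (possibly empty).
#' @export
read_bed <- function(path, bundle) {
  stopifnot(file.exists(path))
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1)) == 0)
    return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  unknown <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                     bundle$replicons$replicon_id)
  if (length(unknown))
    stop("BED interval(s) on unknown replicon: ",
         paste(unknown, collapse = ", "))
  rlen <- setNames(bundle$replicons$length, bundle$replicons$replicon_id)
  ends <- GenomicRanges::end(gr)
  lim <- rlen[as.character(GenomicRanges::seqnames(gr))]
  if (any(ends > lim)) {
    warning("interval(s) extend past replicon end; clipped")
    GenomicRanges::end(gr) <- pmin(ends, lim)
  }
  GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
  GenomicRanges::reduce(gr)
}

#' Per-replicon coverage of HGT intervals
#'
#' @param intervals Merged GRanges from [read_bed()].
#' @param bundle A [genome_bundle()].
#' @return data.frame: `replicon_id`, `covered_nt`, `fraction` (of the
#'   replicon length), one row per bundle replicon.
#' @export
replicon_coverage <- function(intervals, bundle) {
  r <- bundle$replicons
  covered <- vapply(r$replicon_id, function(id) {
    sub <- intervals[as.character(GenomicRanges::seqnames(intervals)) == id]
    sum(GenomicRanges::width(GenomicRanges::reduce(sub)))
  }, numeric(1))
  data.frame(replicon_id = r$replicon_id, covered_nt = unname(covered),
             fraction = unname(covered / r$length),
             stringsAsFactors = FALSE)
}

#' Genes (and duplicated genes) inside HGT regions
#'
#' A gene counts as inside when it overlaps any interval by at least
#' `min_overlap` nucleotides (default 1); a gene merely abutting an
#' interval does not overlap.
#'
#' @param intervals Merged GRanges from [read_bed()].
#' @param bundle A [genome_bundle()].
#' @param dup_pairs Optional data.frame from [call_duplicate_pairs()];
#'   its member loci define the duplicated-gene subset.
#' @param min_overlap Minimum overlap in nt.
#' @return List with `genes_inside` and `dup_genes_inside` (character
#'   vectors of locus tags).
#' @export
genes_in_regions <- function(intervals, bundle, dup_pairs = NULL,
                             min_overlap = 1L) {
  g <- bundle$genes
  if (nrow(g) == 0 || length(intervals) == 0)
    return(list(genes_inside = character(0),
                dup_genes_inside = character(0)))
  gr <- GenomicRanges::GRanges(
    seqnames = g$replicon_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end))
  hits <- GenomicRanges::findOverlaps(gr, intervals,
                                      minoverlap = min_overlap)
  inside <- sort(unique(g$locus_tag[S4Vectors::queryHits(hits)]))
  dup <- character(0)
  if (!is.null(dup_pairs) && nrow(dup_pairs) > 0)
    dup <- intersect(inside, c(dup_pairs$gene_a, dup_pairs$gene_b))
  list(genes_inside = inside, dup_genes_inside = sort(dup))
}
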