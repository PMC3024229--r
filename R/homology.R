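# Reciprocal homology search and duplicate-pair calling. The search is the
# classic two-step scheme: every protein is aligned against every other in
# its own genome, hits are kept when the expectation value and percent
# identity both pass, an edge survives only if its reciprocal does too, and
# homolog families are the connected components of the reciprocal graph.
# Families of exactly two members become duplicate gene pairs.

#' Default homology thresholds
#'
#' Hits qualify when E <= `e_max` and percent identity >= `id_min`.
#' Defaults: E <= 1e-20 and identity >= 30, the level above which gene
#' duplication can be reliably identified in bacterial genomes.
#'
#' @param e_max Maximum expectation value.
#' @param id_min Minimum percent amino-acid identity.
#' @return A list with elements `e_max`, `id_min`.
#' @export
homology_thresholds <- function(e_max = 1e-20, id_min = 30) {
  list(e_max = e_max, id_min = id_min)
}

# Directed hit between two encoded proteins, or NULL below thresholds.
# The expectation-value filter runs on a score-only pass; the full
# traceback (needed for percent identity) is computed only for survivors.
.pair_hit_idx <- function(id_a, id_b, ai, bi, scheme, thresholds) {
  score <- gotoh_score_idx(ai, bi, scheme$matrix, scheme$gap_open,
                           scheme$gap_ext)
  ev <- evalue(score, length(ai), length(bi), scheme)
  if (ev > thresholds$e_max) return(NULL)
  res <- gotoh_align_idx(ai, bi, scheme$matrix, scheme$gap_open,
                         scheme$gap_ext)
  pa <- res$path_a; pb <- res$path_b
  paired <- pa > 0 & pb > 0
  ident <- sum(ai[pa[paired]] == bi[pb[paired]])
  cols <- length(pa)
  pid <- 100 * ident / cols
  if (pid < thresholds$id_min) return(NULL)
  data.frame(query = id_a, subject = id_b, score = score,
             aligned_cols = cols, identities = ident,
             percent_identity = pid, evalue = ev,
             query_len = length(ai), subject_len = length(bi),
             stringsAsFactors = FALSE)
}

.pair_hit <- function(id_a, id_b, seq_a, seq_b, scheme, thresholds) {
  .pair_hit_idx(id_a, id_b, .encode_prot(seq_a, scheme),
                .encode_prot(seq_b, scheme), scheme, thresholds)
}

#' All-vs-all protein similarity search within a genome
#'
#' Aligns every protein against every other protein of the bundle
#' (self-hits excluded) with the exact affine-gap kernel and keeps directed
#' hits passing both thresholds. The global alignment is symmetric, so each
#' qualifying unordered pair yields both directed hits with identical
#' score, identity, and E-value.
#'
#' @param bundle A [genome_bundle()].
#' @param thresholds See [homology_thresholds()].
#' @param scheme An [align_scheme()].
#' @return data.frame of hits: `query`, `subject`, `score`, `aligned_cols`,
#'   `identities`, `percent_identity`, `evalue`, `query_len`, `subject_len`.
#' @export
all_vs_all <- function(bundle, thresholds = homology_thresholds(),
                       scheme = align_scheme()) {
  g <- bundle$genes
  stopifnot(nrow(g) >= 1)
  n <- nrow(g)
  enc <- .encode_bundle(bundle, scheme)
  hits <- vector("list", 0L)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        h <- .pair_hit_idx(g$locus_tag[i], g$locus_tag[j],
                           enc[[i]], enc[[j]], scheme, thresholds)
        if (!is.null(h)) {
          rev <- h
          rev$query <- h$subject; rev$subject <- h$query
          rev$query_len <- h$subject_len; rev$subject_len <- h$query_len
          hits[[length(hits) + 1L]] <- rbind(h, rev)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), aligned_cols = integer(0),
                      identities = integer(0), percent_identity = numeric(0),
                      evalue = numeric(0), query_len = integer(0),
                      subject_len = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# union-find over locus tags
.components <- function(vertices, edges_a, edges_b) {
  parent <- setNames(seq_along(vertices), vertices)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_along(edges_a)) {
    ra <- find(match(edges_a[k], vertices))
    rb <- find(match(edges_b[k], vertices))
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(vertices), find, integer(1))
  split(vertices, roots)
}

#' Build homolog families from directed hits
#'
#' An undirected edge is kept only when the hit qualifies in BOTH
#' directions (reciprocal pairing). Families are the connected components
#' of the reciprocal graph; singletons are dropped, so every family has
#' copy number >= 2.
#'
#' @param hits data.frame from [all_vs_all()] (already thresholded).
#' @return A list with `families` (list of character vectors of locus
#'   tags, sorted) and `histogram` (named integer vector over copy-number
#'   classes `"2"`, `"3"`, `"4"`, `"5+"`).
#' @export
build_families <- function(hits) {
  if (nrow(hits) == 0)
    return(list(families = list(),
                histogram = c(`2` = 0L, `3` = 0L, `4` = 0L, `5+` = 0L)))
  key <- paste(hits$query, hits$subject, sep = "\r")
  rev_key <- paste(hits$subject, hits$query, sep = "\r")
  reciprocal <- key %in% rev_key
  h <- hits[reciprocal & hits$query < hits$subject, , drop = FALSE]
  verts <- sort(unique(c(h$query, h$subject)))
  fams <- .components(verts, h$query, h$subject)
  fams <- lapply(unname(fams), sort)
  fams <- fams[order(vapply(fams, `[`, character(1), 1))]
  sizes <- lengths(fams)
  histogram <- c(`2` = sum(sizes == 2L), `3` = sum(sizes == 3L),
                 `4` = sum(sizes == 4L), `5+` = sum(sizes >= 5L))
  list(families = fams, histogram = histogram)
}

# CI = longest chromosome, CII = second; any plasmid = P
.replicon_code <- function(bundle) {
  r <- bundle$replicons
  chroms <- r[r$class == "chromosome", , drop = FALSE]
  chroms <- chroms$replicon_id[order(-chroms$length)]
  code <- setNames(rep("P", nrow(r)), r$replicon_id)
  if (length(chroms) >= 1) code[chroms[1]] <- "CI"
  if (length(chroms) >= 2) code[chroms[2]] <- "CII"
  if (length(chroms) > 2) code[chroms[-(1:2)]] <- "CII"  # rare; treat as CII
  code
}

#' Location class of a two-gene pair
#'
#' `CI-CI`, `CI-CII`, `CII-CII` for chromosomal pairs (CI is the longest
#' chromosome), `C-P` for chromosome-plasmid, `P-P` for plasmid-plasmid.
#'
#' @param bundle A [genome_bundle()].
#' @param locus_a,locus_b Locus tags.
#' @return Single string.
#' @export
location_class <- function(bundle, locus_a, locus_b) {
  code <- .replicon_code(bundle)
  g <- bundle$genes
  ra <- code[[g$replicon_id[match(locus_a, g$locus_tag)]]]
  rb <- code[[g$replicon_id[match(locus_b, g$locus_tag)]]]
  if (ra == "P" && rb == "P") return("P-P")
  if (ra == "P" || rb == "P") return("C-P")
  paste(sort(c(ra, rb), method = "radix"), collapse = "-")
}

#' Call duplicate gene pairs from homolog families
#'
#' One pair per copy-number-2 family, plus any curated `forced_pairs`
#' (previously reported duplications below the search thresholds). Each
#' pair carries its percent identity, divergence (100 - identity), and
#' location class.
#'
#' @param families Output of [build_families()] (or its `families` field).
#' @param bundle A [genome_bundle()].
#' @param forced_pairs Optional data.frame with columns `gene_a`, `gene_b`.
#' @param scheme An [align_scheme()] used to (re)compute identities.
#' @return data.frame: `pair_id`, `gene_a`, `gene_b`, `percent_identity`,
#'   `divergence`, `location_class`.
#' @export
call_duplicate_pairs <- function(families, bundle, forced_pairs = NULL,
                                 scheme = align_scheme()) {
  if (is.list(families) && !is.null(families$families))
    families <- families$families
  twos <- families[lengths(families) == 2L]
  pairs <- lapply(twos, function(f) c(gene_a = f[1], gene_b = f[2]))
  if (!is.null(forced_pairs) && nrow(forced_pairs) > 0) {
    unknown <- setdiff(c(forced_pairs$gene_a, forced_pairs$gene_b),
                       bundle$genes$locus_tag)
    if (length(unknown))
      stop("forced pair references unknown locus: ",
           paste(unknown, collapse = ", "))
    pairs <- c(pairs, lapply(seq_len(nrow(forced_pairs)), function(i)
      c(gene_a = forced_pairs$gene_a[i], gene_b = forced_pairs$gene_b[i])))
  }
  if (!length(pairs))
    return(data.frame(pair_id = character(0), gene_a = character(0),
                      gene_b = character(0), percent_identity = numeric(0),
                      divergence = numeric(0), location_class = character(0),
                      stringsAsFactors = FALSE))
  g <- bundle$genes
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sa <- g$protein_seq[match(p[["gene_a"]], g$locus_tag)]
    sb <- g$protein_seq[match(p[["gene_b"]], g$locus_tag)]
    aln <- align_global(sa, sb, scheme)
    data.frame(pair_id = sprintf("pair%04d", i),
               gene_a = p[["gene_a"]], gene_b = p[["gene_b"]],
               percent_identity = aln$percent_identity,
               divergence = 100 - aln$percent_identity,
               location_class = location_class(bundle, p[["gene_a"]],
                                               p[["gene_b"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
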