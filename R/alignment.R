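#' Scoring scheme for protein global alignment
#'
#' Bundles a substitution matrix with affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw scores into expectation
#' values. Defaults mirror the common gapped BLASTP setup: BLOSUM62 with
#' gap open 11 and gap extension 1, and the published gapped constants
#' lambda = 0.267, K = 0.041 for that scheme. A gap run of length k costs
#' `gap_open + k * gap_ext`.
#'
#' @param matrix Square numeric substitution matrix with residue letters as
#'   dimnames. Defaults to BLOSUM62 from Biostrings.
#' @param gap_open,gap_ext Non-negative gap penalties.
#' @param lambda,K Karlin-Altschul parameters (per scoring scheme);
#'   both must be positive.
#' @return An object of class `"align_scheme"`.
#' @export
align_scheme <- function(matrix = NULL, gap_open = 11, gap_ext = 1,
                         lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            !is.null(rownames(matrix)),
            gap_open >= 0, gap_ext >= 0, lambda > 0, K > 0)
  storage.mode(matrix) <- "double"
  structure(list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext,
                 lambda = lambda, K = K),
            class = "align_scheme")
}

# integer residue codes against the scheme's matrix rows
.encode_prot <- function(seq, scheme) {
  v <- strsplit(seq, "")[[1]]
  idx <- match(v, rownames(scheme$matrix))
  if (anyNA(idx))
    stop("symbol(s) absent from substitution matrix: ",
         paste(unique(v[is.na(idx)]), collapse = ", "))
  idx
}

.encode_bundle <- function(bundle, scheme)
  lapply(bundle$genes$protein_seq, .encode_prot, scheme = scheme)

#' Global affine-gap alignment of two protein sequences
#'
#' Exact Needleman-Wunsch / Gotoh dynamic programming under an affine gap
#' model. The traceback is deterministic: ties are resolved preferring a
#' paired column, then a column consuming sequence `a`, then one consuming
#' `b`, so the same inputs always yield the same alignment.
#'
#' Percent identity is defined as 100 * identities / alignment columns,
#' where columns include gap columns. This is the denominator used for the
#' divergence (100 - identity) reported for duplicate pairs.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param scheme An [align_scheme()].
#' @return A list of class `"alignment_result"` with fields `query_id`,
#'   `subject_id` (filled by callers), `score`, `aligned_a`, `aligned_b`
#'   (gapped strings), `aligned_cols`, `identities`, `percent_identity`,
#'   `query_len`, `subject_len`.
#' @export
align_global <- function(a, b, scheme = align_scheme()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1,
            nzchar(a), nzchar(b))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ai <- .encode_prot(a, scheme)
  bi <- .encode_prot(b, scheme)
  res <- gotoh_align_idx(ai, bi, scheme$matrix, scheme$gap_open,
                         scheme$gap_ext)
  ga <- ifelse(res$path_a == 0, "-", av[pmax(res$path_a, 1)])
  gb <- ifelse(res$path_b == 0, "-", bv[pmax(res$path_b, 1)])
  ident <- sum(ga == gb & ga != "-")
  cols <- length(ga)
  structure(list(
    query_id = NA_character_, subject_id = NA_character_,
    score = res$score,
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    aligned_cols = cols,
    identities = ident,
    percent_identity = 100 * ident / cols,
    query_len = length(av), subject_len = length(bv)
  ), class = "alignment_result")
}

#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * score): the expected number of chance
#' alignments at or above `score` between sequences of lengths m and n
#' under the scheme's statistical parameters. Monotone decreasing in score
#' and linear in each sequence length.
#'
#' @param score Raw alignment score.
#' @param m,n Query and subject lengths (>= 1).
#' @param scheme An [align_scheme()] supplying lambda and K.
#' @return Expectation value (non-negative scalar).
#' @export
evalue <- function(score, m, n, scheme = align_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$K * m * n * exp(-scheme$lambda * score)
}
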