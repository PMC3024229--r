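# Deterministic progressive multiple alignment for quartets: pairwise
# global distances feed an average-linkage (UPGMA-style) guide tree, and
# groups are merged by profile-profile Needleman-Wunsch with affine gaps.
# Column-vs-column profile scores are expected substitution-matrix scores
# over residue frequencies (gap fractions contribute zero), computed as a
# single matrix product so the kernel stays in compiled code.

.profile_freqs <- function(rows, residues) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  F <- matrix(0, length(residues), L, dimnames = list(residues, NULL))
  for (r in residues)
    F[r, ] <- colSums(m == r)
  F / nrow(m)
}

.merge_profiles <- function(rows_a, rows_b, scheme) {
  residues <- rownames(scheme$matrix)
  residues <- setdiff(residues, c("*", "-"))
  Fa <- .profile_freqs(rows_a, residues)
  Fb <- .profile_freqs(rows_b, residues)
  B <- scheme$matrix[residues, residues]
  sim <- t(Fa) %*% B %*% Fb
  res <- gotoh_align(sim, scheme$gap_open, scheme$gap_ext)
  expand <- function(rows, path) {
    vapply(rows, function(s) {
      v <- strsplit(s, "")[[1]]
      paste(ifelse(path == 0, "-", v[pmax(path, 1)]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  c(expand(rows_a, res$path_a), expand(rows_b, res$path_b))
}

#' Progressive alignment of four protein sequences
#'
#' Builds pairwise distances (100 - percent identity of global
#' alignments), clusters them by average linkage with deterministic
#' tie-breaks (lowest index first), and merges clusters by
#' profile-profile affine-gap alignment. Ungapping any output row
#' recovers the corresponding input sequence.
#'
#' @param seqs Character vector of 4 non-empty protein sequences
#'   (names preserved).
#' @param scheme An [align_scheme()].
#' @return Character vector of 4 aligned rows (equal length, `-` gaps) in
#'   the input order.
#' @export
align_quartet <- function(seqs, scheme = align_scheme()) {
  stopifnot(length(seqs) == 4, all(nzchar(seqs)))
  n <- 4L
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    aln <- align_global(seqs[[i]], seqs[[j]], scheme)
    D[i, j] <- D[j, i] <- 100 - aln$percent_identity
  }
  clusters <- lapply(seq_len(n), function(i) i)          # member indices
  rows <- lapply(seqs, identity)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < best[1] - 1e-12) best <- c(d, a, b)
    }
    a <- best[2]; b <- best[3]
    merged_rows <- .merge_profiles(unlist(rows[a]), unlist(rows[b]), scheme)
    merged_members <- c(clusters[[a]], clusters[[b]])
    keep <- setdiff(seq_len(k), c(a, b))
    clusters <- c(clusters[keep], list(merged_members))
    rows <- c(rows[keep], list(merged_rows))
  }
  out <- character(n)
  out[clusters[[1]]] <- rows[[1]]
  names(out) <- names(seqs)
  out
}
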