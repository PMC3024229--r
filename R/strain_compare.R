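# Duplicate retention across related strains: each duplicate pair's first
# member ("Orf 1") is searched against every other strain's proteome with
# the same thresholds as the homology search, and the per-strain counts
# of qualifying matches (0 / 1 / 2 / >2) summarize gene loss and
# retention. Pairs with exactly two matches in every strain are the
# "common pairs" carried into the selection analysis.

#' Count qualifying matches of one gene in another strain's proteome
#'
#' @param query_locus Locus tag of the query gene in `bundle`.
#' @param bundle The focal [genome_bundle()].
#' @param strain_bundle Target strain's [genome_bundle()].
#' @param thresholds See [homology_thresholds()].
#' @param scheme An [align_scheme()].
#' @param target_enc Optional precomputed residue encoding of the target
#'   proteome (internal optimization for batch callers).
#' @return List with `count` and `loci` (matched locus tags ordered by
#'   expectation value, then score, then tag).
#' @export
count_matches <- function(query_locus, bundle, strain_bundle,
                          thresholds = homology_thresholds(),
                          scheme = align_scheme(), target_enc = NULL) {
  g <- bundle$genes
  seq_q <- g$protein_seq[match(query_locus, g$locus_tag)]
  if (is.na(seq_q)) stop("unknown query locus: ", query_locus)
  enc_q <- .encode_prot(seq_q, scheme)
  tg <- strain_bundle$genes
  if (is.null(target_enc)) target_enc <- .encode_bundle(strain_bundle, scheme)
  rows <- lapply(seq_len(nrow(tg)), function(i)
    .pair_hit_idx(query_locus, tg$locus_tag[i], enc_q, target_enc[[i]],
                  scheme, thresholds))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(list(count = 0L, loci = character(0)))
  h <- do.call(rbind, rows)
  h <- h[order(h$evalue, -h$score, h$subject), , drop = FALSE]
  list(count = nrow(h), loci = h$subject)
}

#' Match profiles of duplicate pairs across strains
#'
#' By convention only the pair's first member (`gene_a`, "Orf 1") is
#' queried; `both_members = TRUE` additionally requires nothing but
#' reports the union of matches of both members (an extension, off by
#' default).
#'
#' @param pairs data.frame from [call_duplicate_pairs()].
#' @param bundle The focal [genome_bundle()].
#' @param strain_bundles Named list of strain [genome_bundle()]s.
#' @param thresholds See [homology_thresholds()].
#' @param scheme An [align_scheme()].
#' @param both_members Query both pair members and pool their matches.
#' @return data.frame: `pair_id`, `strain`, `count`, `loci`
#'   (comma-separated).
#' @export
match_profiles <- function(pairs, bundle, strain_bundles,
                           thresholds = homology_thresholds(),
                           scheme = align_scheme(),
                           both_members = FALSE) {
  rows <- list()
  encs <- lapply(strain_bundles, .encode_bundle, scheme = scheme)
  for (i in seq_len(nrow(pairs))) {
    for (s in names(strain_bundles)) {
      m <- count_matches(pairs$gene_a[i], bundle, strain_bundles[[s]],
                         thresholds, scheme, target_enc = encs[[s]])
      if (both_members) {
        m2 <- count_matches(pairs$gene_b[i], bundle, strain_bundles[[s]],
                            thresholds, scheme, target_enc = encs[[s]])
        loci <- union(m$loci, m2$loci)
        m <- list(count = length(loci), loci = loci)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], strain = s, count = m$count,
        loci = paste(m$loci, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pair_id = character(0), strain = character(0),
                      count = integer(0), loci = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of match counts per strain
#'
#' @param profiles data.frame from [match_profiles()].
#' @return data.frame with one row per strain and columns `0`, `1`, `2`,
#'   `>2`; rows sum to the number of pairs.
#' @export
match_distribution <- function(profiles) {
  if (nrow(profiles) == 0)
    return(data.frame(strain = character(0), `0` = integer(0),
                      `1` = integer(0), `2` = integer(0),
                      `>2` = integer(0), check.names = FALSE,
                      stringsAsFactors = FALSE))
  bands <- c("0", "1", "2", ">2")
  band_of <- function(n) ifelse(n > 2, ">2", as.character(n))
  out <- do.call(rbind, lapply(split(profiles, profiles$strain), function(p) {
    tb <- table(factor(band_of(p$count), levels = bands))
    cbind(data.frame(strain = p$strain[1], stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(tb))))
  }))
  names(out) <- c("strain", bands)
  rownames(out) <- NULL
  out
}

#' Pairs with exactly two matches in every strain
#'
#' These "common pairs" retain a full duplicate pair in all strains and
#' feed the cross-strain selection analysis.
#'
#' @param profiles data.frame from [match_profiles()].
#' @return Character vector of pair IDs.
#' @export
common_pairs <- function(profiles) {
  if (nrow(profiles) == 0) return(character(0))
  ok <- vapply(split(profiles, profiles$pair_id),
               function(p) all(p$count == 2L), logical(1))
  sort(names(ok)[ok])
}
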