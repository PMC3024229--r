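# Quartet maximum-likelihood dating of duplications. For each duplicate
# pair (P1, P2) and one ortholog per copy (O1, O2), the three unrooted
# 4-leaf topologies are fit under the WAG model by Felsenstein pruning
# with per-branch scalar optimization. The ML topology classifies the
# pair: paralogs-as-sisters ((P1,P2),(O1,O2)) is Type-B (duplication after
# speciation); either mixed topology is Type-A (duplication before
# speciation). Support comes from nonparametric bootstrap over alignment
# columns.

# Leaf order is always (P1, P2, O1, O2). Topology k splits the leaves into
# two cherries; branch lengths are indexed 1-4 for the leaves in order,
# 5 for the internal branch.
QUARTET_TOPOLOGIES <- list(
  TA1 = list(pair1 = c(1L, 3L), pair2 = c(2L, 4L),
             label = "((P1,O1),(P2,O2))", call = "TypeA"),
  TA2 = list(pair1 = c(1L, 4L), pair2 = c(2L, 3L),
             label = "((P1,O2),(P2,O1))", call = "TypeA"),
  TB  = list(pair1 = c(1L, 2L), pair2 = c(3L, 4L),
             label = "((P1,P2),(O1,O2))", call = "TypeB"))

# Encode a 4-row gapped protein MSA into integer patterns (1-20 residues,
# 21 = gap/unknown, marginalized as missing data) with column weights.
encode_quartet_msa <- function(msa, states = WAG_ORDER) {
  stopifnot(length(msa) == 4, length(unique(nchar(msa))) == 1)
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  code <- match(m, states)
  code[is.na(code)] <- 21L
  dim(code) <- dim(m)
  all_gap <- colSums(code == 21L) == 4L
  if (any(all_gap)) {
    warning(sum(all_gap), " all-gap column(s) skipped")
    code <- code[, !all_gap, drop = FALSE]
  }
  if (ncol(code) == 0) stop("alignment has no informative columns")
  key <- apply(code, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- code[, first, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(patterns = pat, weights = w, pattern_of_site = match(key, key[first]),
       n_sites = length(key))
}

# P(t) with a 21st column of ones so a gap leaf contributes a flat
# conditional likelihood (missing data).
.pg <- function(model, t) cbind(prob_matrix(model, t), 1)

.loglik_enc <- function(enc, topology, bl, model, weights = NULL) {
  w <- if (is.null(weights)) enc$weights else weights
  top <- QUARTET_TOPOLOGIES[[topology]]
  i <- top$pair1[1]; j <- top$pair1[2]
  k <- top$pair2[1]; l <- top$pair2[2]
  pat <- enc$patterns
  W1 <- .pg(model, bl[i])[, pat[i, ], drop = FALSE] *
        .pg(model, bl[j])[, pat[j, ], drop = FALSE]
  W2 <- .pg(model, bl[k])[, pat[k, ], drop = FALSE] *
        .pg(model, bl[l])[, pat[l, ], drop = FALSE]
  site <- colSums(model$pi * (W1 * (prob_matrix(model, bl[5]) %*% W2)))
  sum(w * log(site))
}

#' Quartet log-likelihood under a substitution model
#'
#' Felsenstein pruning on an unrooted 4-leaf tree: per-site likelihoods
#' are products over sites of the probability of the observed column given
#' the topology, the five branch lengths, and the model's stationary
#' distribution at the (arbitrary) root. Gaps and unknown residues are
#' marginalized as missing data; all-gap columns are skipped with a
#' warning. The value is invariant to where the unrooted tree is rooted.
#'
#' @param msa Character vector of 4 aligned (equal-length, possibly
#'   gapped) protein strings in leaf order (P1, P2, O1, O2).
#' @param topology `"TA1"`, `"TA2"`, or `"TB"` (see
#'   `QUARTET_TOPOLOGIES`).
#' @param branch_lengths Numeric vector of 5 non-negative lengths: leaves
#'   1-4 then the internal branch.
#' @param model A [wag_model()].
#' @return Log-likelihood (scalar).
#' @export
quartet_loglik <- function(msa, topology, branch_lengths,
                           model = wag_model()) {
  stopifnot(length(branch_lengths) == 5, all(branch_lengths >= 0))
  enc <- encode_quartet_msa(msa, model$states)
  .loglik_enc(enc, topology, branch_lengths, model)
}

# Coordinate-wise branch-length optimization for one topology. Each branch
# is optimized by bounded scalar search on [min_bl, max_bl]; cycles stop
# when the cycle's log-likelihood gain drops below tol. Parts of the
# pruning that do not involve the branch being optimized are cached.
.fit_topology <- function(enc, topology, model, start = rep(0.1, 5),
                          tol = 1e-6, max_cycles = 50,
                          min_bl = 1e-8, max_bl = 10, weights = NULL) {
  w <- if (is.null(weights)) enc$weights else weights
  top <- QUARTET_TOPOLOGIES[[topology]]
  pat <- enc$patterns
  bl <- start
  leafcol <- function(br, t) .pg(model, t)[, pat[br, ], drop = FALSE]
  obj_ll <- function(bl) .loglik_enc(enc, topology, bl, model, weights = w)
  ll <- obj_ll(bl)
  ord <- c(top$pair1, top$pair2, 5L)
  for (cycle in seq_len(max_cycles)) {
    ll_start <- ll
    for (br in ord) {
      if (br == 5L) {
        W1 <- leafcol(top$pair1[1], bl[top$pair1[1]]) *
              leafcol(top$pair1[2], bl[top$pair1[2]])
        W2 <- leafcol(top$pair2[1], bl[top$pair2[1]]) *
              leafcol(top$pair2[2], bl[top$pair2[2]])
        piW1 <- model$pi * W1
        f <- function(x) -sum(w * log(colSums(piW1 * (prob_matrix(model, x) %*% W2))))
      } else {
        in_p1 <- br %in% top$pair1
        sib <- if (in_p1) setdiff(top$pair1, br) else setdiff(top$pair2, br)
        othr <- if (in_p1) top$pair2 else top$pair1
        Wo <- leafcol(othr[1], bl[othr[1]]) * leafcol(othr[2], bl[othr[2]])
        M <- (model$pi * leafcol(sib, bl[sib])) *
             (prob_matrix(model, bl[5]) %*% Wo)
        f <- function(x) -sum(w * log(colSums(leafcol(br, x) * M)))
      }
      opt <- stats::optimize(f, interval = c(min_bl, max_bl), tol = 1e-5)
      if (-opt$objective > ll + 1e-12) {
        bl[br] <- opt$minimum
        ll <- -opt$objective
      }
    }
    if (ll - ll_start < tol) break
  }
  list(branch_lengths = bl, logL = ll)
}

#' Fit all three quartet topologies and pick the maximum-likelihood one
#'
#' Branch lengths of each topology are optimized by coordinate-wise
#' bounded scalar search (each branch in [1e-8, 10], cycling until the
#' per-cycle log-likelihood gain is below 1e-6, at most 50 cycles). The
#' topology with the highest log-likelihood is reported; ties within 1e-6
#' are broken toward the Type-A topologies, then in the fixed order TA1,
#' TA2, TB.
#'
#' @param msa Character vector of 4 aligned protein strings in leaf order
#'   (P1, P2, O1, O2).
#' @param model A [wag_model()].
#' @param start Initial branch lengths.
#' @return List of class `"quartet_result"`: `topology`, `label`, `call`,
#'   `branch_lengths`, `logL`, `logL_all` (all three), `tie` (TRUE when
#'   the top two log-likelihoods are within 1e-6), `bootstrap_support`
#'   (NA until [bootstrap_support()] is run).
#' @export
fit_quartet <- function(msa, model = wag_model(), start = rep(0.1, 5)) {
  enc <- encode_quartet_msa(msa, model$states)
  fits <- lapply(names(QUARTET_TOPOLOGIES), function(tp)
    .fit_topology(enc, tp, model, start = start))
  names(fits) <- names(QUARTET_TOPOLOGIES)
  ll <- vapply(fits, `[[`, numeric(1), "logL")
  best <- names(ll)[which(ll >= max(ll) - 1e-6)][1]  # order TA1, TA2, TB
  tie <- sum(ll >= max(ll) - 1e-6) > 1
  structure(list(topology = best,
                 label = QUARTET_TOPOLOGIES[[best]]$label,
                 call = QUARTET_TOPOLOGIES[[best]]$call,
                 branch_lengths = fits[[best]]$branch_lengths,
                 logL = fits[[best]]$logL,
                 logL_all = ll, tie = tie,
                 bootstrap_support = NA_integer_),
            class = "quartet_result")
}

#' Bootstrap support for the maximum-likelihood quartet topology
#'
#' Resamples alignment columns with replacement `n` times, refits the
#' three topologies on each replicate (warm-started from the full-data
#' branch lengths), and reports the percentage of replicates whose ML
#' topology matches the full-data ML topology. Bit-reproducible for a
#' fixed seed.
#'
#' @param msa Character vector of 4 aligned protein strings.
#' @param model A [wag_model()].
#' @param n Number of replicates (default 100).
#' @param seed Integer RNG seed.
#' @param full_fit Optional precomputed [fit_quartet()] result for `msa`.
#' @return Integer support percentage in 0..100.
#' @export
bootstrap_support <- function(msa, model = wag_model(), n = 100,
                              seed = 1L, full_fit = NULL) {
  stopifnot(n >= 1)
  enc <- encode_quartet_msa(msa, model$states)
  if (is.null(full_fit)) full_fit <- fit_quartet(msa, model)
  set.seed(seed)
  hits <- 0L
  npat <- length(enc$weights)
  for (r in seq_len(n)) {
    sites <- sample.int(enc$n_sites, enc$n_sites, replace = TRUE)
    w <- tabulate(enc$pattern_of_site[sites], nbins = npat)
    keep <- w > 0
    sub <- list(patterns = enc$patterns[, keep, drop = FALSE],
                weights = w[keep])
    fits <- lapply(names(QUARTET_TOPOLOGIES), function(tp)
      .fit_topology(sub, tp, model, start = full_fit$branch_lengths,
                    max_cycles = 20))
    ll <- vapply(fits, `[[`, numeric(1), "logL")
    best <- names(QUARTET_TOPOLOGIES)[which(ll >= max(ll) - 1e-6)][1]
    if (best == full_fit$topology) hits <- hits + 1L
  }
  as.integer(round(100 * hits / n))
}

#' Classify a fitted quartet as Type-A or Type-B
#'
#' Type-B iff the ML topology places the two paralogs as sisters,
#' ((P1,P2),(O1,O2)); both other topologies are Type-A (each copy groups
#' with an ortholog, so the duplication predates speciation).
#'
#' @param result A `"quartet_result"` from [fit_quartet()].
#' @return `"TypeA"` or `"TypeB"`.
#' @export
classify_topology <- function(result) {
  stopifnot(inherits(result, "quartet_result"))
  if (result$topology == "TB") "TypeB" else "TypeA"
}

#' Newick string for a fitted quartet
#'
#' @param result A `"quartet_result"`.
#' @param tip_names Character vector of 4 names in leaf order
#'   (P1, P2, O1, O2).
#' @return Newick string with branch lengths.
#' @export
quartet_newick <- function(result, tip_names) {
  stopifnot(length(tip_names) == 4)
  top <- QUARTET_TOPOLOGIES[[result$topology]]
  bl <- result$branch_lengths
  cherry <- function(idx)
    sprintf("(%s:%.6f,%s:%.6f)", tip_names[idx[1]], bl[idx[1]],
            tip_names[idx[2]], bl[idx[2]])
  sprintf("(%s:%.6f,%s:0.0);", cherry(top$pair1), bl[5], cherry(top$pair2))
}

#' Select one ortholog per paralog from an ortholog database
#'
#' Each paralog is aligned against every database protein; qualifying hits
#' (same thresholds as the homology search) are ranked by lowest
#' expectation value, then highest score, then subject ID. If both
#' paralogs' best hits are the same database sequence, the paralog with
#' the weaker best score is reassigned to its next-best distinct ortholog
#' (`same_best_resolved = TRUE`). When fewer than two distinct orthologs
#' can be assigned the choice is `"unresolvable"` rather than an error,
#' mirroring real searches where one or both orthologs are missing.
#'
#' @param pair List or one-row data.frame with `gene_a`, `gene_b` locus
#'   tags.
#' @param bundle The focal [genome_bundle()] holding the paralogs.
#' @param ortholog_db A [genome_bundle()] of candidate orthologs from
#'   other (fully sequenced) species; must not contain the focal strain.
#' @param thresholds See [homology_thresholds()].
#' @param scheme An [align_scheme()].
#' @param db_enc Optional precomputed residue encoding of the database
#'   proteins (internal optimization for batch callers).
#' @return List of class `"ortholog_choice"`: `status` ("ok" or
#'   "unresolvable"), `ortholog_a`, `ortholog_b` (each a list with `id`,
#'   `species`, `percent_identity`), `same_best_resolved`.
#' @export
select_orthologs <- function(pair, bundle, ortholog_db,
                             thresholds = homology_thresholds(),
                             scheme = align_scheme(), db_enc = NULL) {
  unresolved <- structure(list(status = "unresolvable", ortholog_a = NULL,
                               ortholog_b = NULL, same_best_resolved = FALSE),
                          class = "ortholog_choice")
  db <- ortholog_db$genes
  if (is.null(db) || nrow(db) == 0) return(unresolved)
  if (is.null(db_enc)) db_enc <- .encode_bundle(ortholog_db, scheme)
  g <- bundle$genes
  ranked_hits <- function(locus) {
    enc_q <- .encode_prot(g$protein_seq[match(locus, g$locus_tag)], scheme)
    rows <- lapply(seq_len(nrow(db)), function(i) {
      h <- .pair_hit_idx(locus, db$locus_tag[i], enc_q, db_enc[[i]],
                         scheme, thresholds)
      if (!is.null(h)) cbind(h, species = db$strain[i]) else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, rows)
    out[order(out$evalue, -out$score, out$subject), , drop = FALSE]
  }
  ha <- ranked_hits(pair$gene_a)
  hb <- ranked_hits(pair$gene_b)
  if (is.null(ha) || is.null(hb)) return(unresolved)
  pick <- function(h, i) list(id = h$subject[i], species = h$species[i],
                              percent_identity = h$percent_identity[i],
                              score = h$score[i])
  oa <- pick(ha, 1L); ob <- pick(hb, 1L)
  flag <- FALSE
  if (oa$id == ob$id) {
    flag <- TRUE
    if (oa$score >= ob$score) {     # weaker paralog takes its next-best
      alt <- which(hb$subject != oa$id)
      if (!length(alt)) return(unresolved)
      ob <- pick(hb, alt[1L])
    } else {
      alt <- which(ha$subject != ob$id)
      if (!length(alt)) return(unresolved)
      oa <- pick(ha, alt[1L])
    }
  }
  if (oa$id == ob$id) return(unresolved)
  structure(list(status = "ok", ortholog_a = oa, ortholog_b = ob,
                 same_best_resolved = flag),
            class = "ortholog_choice")
}
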