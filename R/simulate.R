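# Synthetic multi-replicon genomes with known duplication history. Each
# gene family is evolved along an explicit species/gene tree under the
# GY94-style codon model: "pre-speciation" families duplicate on the root
# branch before the focal lineage splits from its relatives (true Type-A
# quartets), "post-speciation" families duplicate inside the focal
# lineage (true Type-B). Two fully sequenced relative species (X, the
# closer, and Y, the outgroup) supply the ortholog database; three
# focal-species strains apply per-copy gene loss. Everything is
# reproducible from the master seed, and the emitted bundles satisfy the
# genome-bundle invariants by construction.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package targets: two-copy
#' families whose duplications are predominantly ancient (77% predate
#' speciation), purifying selection with mean omega 0.13 (lognormal, sd
#' chosen to give a cross-pair spread of about 0.033), kappa = 2, 300
#' codons per gene, a two-chromosome-plus-plasmid replicon layout, and
#' moderate per-strain copy loss.
#'
#' Times are expected substitutions per codon site measured from the
#' present: the focal species splits from species X at `t_speciation`,
#' from outgroup Y at `t_outgroup`; pre-speciation duplications occur at
#' `t_dup_pre` (> `t_outgroup`), post-speciation ones at `t_dup_post`
#' (< `t_speciation`); strains diverge at `t_strain`.
#'
#' @param n_families Number of gene families.
#' @param frac_duplicated Fraction of families with two focal copies.
#' @param p_pre Probability a duplicated family is pre-speciation
#'   (Type-A truth).
#' @param n_codons Codons per gene.
#' @param kappa Transition/transversion ratio.
#' @param omega_mean,omega_sd Mean and sd of the lognormal family omega.
#' @param gc GC content for ancestral codon frequencies.
#' @param t_speciation,t_outgroup,t_dup_pre,t_dup_post,t_strain Event
#'   times (see above).
#' @param p_loss Per-strain, per-copy loss probability for duplicated
#'   copies.
#' @param replicon_props Probabilities of placing a gene on CI, CII, or
#'   the plasmid.
#' @param p_cog,p_two_cogs Probability a gene carries one (resp. a
#'   second) COG letter.
#' @param n_hgt Number of planted HGT intervals (on the chromosomes).
#' @param hgt_width Width of each HGT interval in nt.
#' @param seed Master seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 50,
                       frac_duplicated = 0.6,
                       p_pre = 0.77,
                       n_codons = 300,
                       kappa = 2,
                       omega_mean = 0.13,
                       omega_sd = 0.033,
                       gc = 0.5,
                       t_speciation = 0.3,
                       t_outgroup = 0.5,
                       t_dup_pre = 0.6,
                       t_dup_post = 0.15,
                       t_strain = 0.02,
                       p_loss = 0.3,
                       replicon_props = c(CI = 0.65, CII = 0.25, pA = 0.10),
                       p_cog = 0.8,
                       p_two_cogs = 0.03,
                       n_hgt = 3,
                       hgt_width = 2e4,
                       seed = 1L) {
  stopifnot(p_pre >= 0, p_pre <= 1, frac_duplicated >= 0,
            frac_duplicated <= 1, p_loss >= 0, p_loss <= 1,
            t_dup_pre > t_outgroup, t_outgroup > t_speciation,
            t_speciation > t_dup_post, t_dup_post > t_strain,
            all(c(t_speciation, t_outgroup, t_dup_pre, t_dup_post,
                  t_strain) >= 0))
  structure(as.list(environment()), class = "sim_config")
}

# lognormal parameterized by arithmetic mean/sd
.rlnorm_mean_sd <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# place genes on replicons and return a genes data.frame + replicon table
.place_genes <- function(loci, strain, replicon_assign, cds, prot, cogs,
                         spacing = 200L) {
  stopifnot(length(loci) == length(cds))
  ord <- order(replicon_assign, seq_along(loci))
  starts <- integer(length(loci))
  ends <- integer(length(loci))
  cursor <- list()
  for (k in ord) {
    r <- replicon_assign[k]
    at <- if (is.null(cursor[[r]])) 1L + spacing else cursor[[r]]
    starts[k] <- at
    ends[k] <- at + nchar(cds[k]) - 1L
    cursor[[r]] <- ends[k] + spacing
  }
  rep_ids <- sort(unique(replicon_assign))
  lens <- vapply(rep_ids, function(r)
    max(ends[replicon_assign == r]) + 500L, integer(1))
  classes <- ifelse(grepl("^C", rep_ids), "chromosome", "plasmid")
  # the longest chromosome must be CI for location coding to be stable
  if (all(c("CI", "CII") %in% rep_ids) && lens[["CII"]] >= lens[["CI"]])
    lens[["CI"]] <- lens[["CII"]] + 1000L
  replicons <- data.frame(replicon_id = rep_ids, class = classes,
                          length = unname(lens), stringsAsFactors = FALSE)
  genes <- data.frame(
    locus_tag = loci, strain = strain, replicon_id = replicon_assign,
    replicon_class = classes[match(replicon_assign, rep_ids)],
    start = starts, end = ends,
    strand = sample(c("+", "-"), length(loci), replace = TRUE),
    cogs = cogs, protein_seq = prot, cds_seq = cds,
    stringsAsFactors = FALSE)
  list(genes = genes, replicons = replicons)
}

.random_cogs <- function(n, p_cog, p_two) {
  vapply(seq_len(n), function(i) {
    if (stats::runif(1) > p_cog) return("")
    l <- sample(COG_LETTERS, 1)
    if (stats::runif(1) < p_two)
      paste0(l, sample(setdiff(COG_LETTERS, l), 1))
    else l
  }, character(1))
}

#' Simulate a full study cohort with known truth
#'
#' Generates the focal genome bundle, three strain bundles, the ortholog
#' database bundle (species X and Y), planted HGT intervals, and a truth
#' table recording each family's age class (A = pre-speciation, B =
#' post-speciation), true omega, member loci, and per-strain retention.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_cohort"`: `focal`, `strains` (named list
#'   of 3 bundles), `ortholog_db`, `truth` (data.frame), `hgt`
#'   (data.frame `replicon_id`, `start`, `end`, 0-based half-open),
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  cfg <- config
  pi_cod <- codon_freqs(cfg$gc)
  strains <- c("strainA", "strainB", "strainC")

  n_dup <- round(cfg$n_families * cfg$frac_duplicated)
  duplicated_fam <- seq_len(cfg$n_families) <= n_dup
  type <- ifelse(duplicated_fam,
                 ifelse(stats::runif(cfg$n_families) < cfg$p_pre, "A", "B"),
                 NA_character_)
  omega_true <- .rlnorm_mean_sd(cfg$n_families, cfg$omega_mean, cfg$omega_sd)

  focal_rows <- list(); strain_rows <- stats::setNames(
    rep(list(list()), 3), strains)
  db_rows <- list()
  truth_rows <- list()

  add_row <- function(store, locus, seq, fam) {
    store[[length(store) + 1L]] <- list(locus = locus, cds = seq, fam = fam)
    store
  }

  for (f in seq_len(cfg$n_families)) {
    model <- codon_model(cfg$kappa, omega_true[f], pi_cod)
    ev <- function(s, t) evolve_codon_seq(s, t, model = model)
    anc <- random_cds(cfg$n_codons, pi_cod)
    fid <- sprintf("fam%03d", f)

    emit_focal_copy <- function(copy_seq_at_strain_split, copy_label) {
      # returns focal locus + per-strain loci (NA when lost)
      focal_seq <- ev(copy_seq_at_strain_split, cfg$t_strain)
      locus <- sprintf("F_%s%s", fid, copy_label)
      focal_rows <<- add_row(focal_rows, locus, focal_seq, fid)
      strain_loci <- character(3)
      for (si in seq_along(strains)) {
        lost <- duplicated_fam[f] && stats::runif(1) < cfg$p_loss
        if (lost) {
          strain_loci[si] <- NA_character_
        } else {
          sseq <- ev(copy_seq_at_strain_split, cfg$t_strain)
          slocus <- sprintf("%s_%s%s", c("SA", "SB", "SC")[si], fid,
                            copy_label)
          strain_rows[[strains[si]]] <<- add_row(strain_rows[[strains[si]]],
                                                 slocus, sseq, fid)
          strain_loci[si] <- slocus
        }
      }
      list(locus = locus, strain_loci = strain_loci)
    }
    emit_ortholog <- function(seq_at_split, species, label, t_branch) {
      oseq <- ev(seq_at_split, t_branch)
      olocus <- sprintf("%s_%s%s", species, fid, label)
      db_rows <<- add_row(db_rows, list(locus = olocus, species = species),
                          oseq, fid)
      olocus
    }

    if (isTRUE(duplicated_fam[f]) && type[f] == "A") {
      # duplication at t_dup_pre, then Y split, then X split, then strains
      c1 <- ev(anc, cfg$t_dup_pre - cfg$t_outgroup)
      c2 <- ev(anc, cfg$t_dup_pre - cfg$t_outgroup)
      y1 <- emit_ortholog(c1, "Y", "a", cfg$t_outgroup)
      y2 <- emit_ortholog(c2, "Y", "b", cfg$t_outgroup)
      c1 <- ev(c1, cfg$t_outgroup - cfg$t_speciation)
      c2 <- ev(c2, cfg$t_outgroup - cfg$t_speciation)
      x1 <- emit_ortholog(c1, "X", "a", cfg$t_speciation)
      x2 <- emit_ortholog(c2, "X", "b", cfg$t_speciation)
      c1 <- ev(c1, cfg$t_speciation - cfg$t_strain)
      c2 <- ev(c2, cfg$t_speciation - cfg$t_strain)
      copy1 <- emit_focal_copy(c1, "a")
      copy2 <- emit_focal_copy(c2, "b")
      orthologs <- paste(c(x1, x2, y1, y2), collapse = ",")
    } else {
      # single lineage down to (possibly) a post-speciation duplication
      y1 <- emit_ortholog(anc, "Y", "a", cfg$t_outgroup)
      b <- ev(anc, cfg$t_outgroup - cfg$t_speciation)
      x1 <- emit_ortholog(b, "X", "a", cfg$t_speciation)
      if (isTRUE(duplicated_fam[f])) {
        c0 <- ev(b, cfg$t_speciation - cfg$t_dup_post)
        c1 <- ev(c0, cfg$t_dup_post - cfg$t_strain)
        c2 <- ev(c0, cfg$t_dup_post - cfg$t_strain)
        copy1 <- emit_focal_copy(c1, "a")
        copy2 <- emit_focal_copy(c2, "b")
      } else {
        c1 <- ev(b, cfg$t_speciation - cfg$t_strain)
        copy1 <- emit_focal_copy(c1, "a")
        copy2 <- NULL
      }
      orthologs <- paste(c(x1, y1), collapse = ",")
    }

    truth_rows[[f]] <- data.frame(
      family = fid, duplicated = duplicated_fam[f], type = type[f],
      omega_true = omega_true[f],
      locus_a = copy1$locus,
      locus_b = if (is.null(copy2)) NA_character_ else copy2$locus,
      orthologs = orthologs,
      strainA_retained = sum(!is.na(c(copy1$strain_loci[1],
                                      copy2$strain_loci[1]))),
      strainB_retained = sum(!is.na(c(copy1$strain_loci[2],
                                      copy2$strain_loci[2]))),
      strainC_retained = sum(!is.na(c(copy1$strain_loci[3],
                                      copy2$strain_loci[3]))),
      stringsAsFactors = FALSE)
  }

  build_bundle <- function(rows, strain, species_field = FALSE) {
    loci <- vapply(rows, function(r)
      if (species_field) r$locus$locus else r$locus, character(1))
    cds <- vapply(rows, `[[`, character(1), "cds")
    strain_col <- if (species_field)
      vapply(rows, function(r) r$locus$species, character(1)) else strain
    prot <- .translate_batch(cds)
    cogs <- .random_cogs(length(loci), cfg$p_cog, cfg$p_two_cogs)
    assign <- sample(names(cfg$replicon_props), length(loci), replace = TRUE,
                     prob = cfg$replicon_props)
    placed <- .place_genes(loci, strain_col, assign, cds, prot, cogs)
    genome_bundle(strain, placed$replicons, placed$genes)
  }

  focal <- build_bundle(focal_rows, "focal")
  strain_bundles <- lapply(strains, function(s)
    build_bundle(strain_rows[[s]], s))
  names(strain_bundles) <- strains
  db <- build_bundle(db_rows, "multi-species", species_field = TRUE)

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  # planted HGT intervals on the chromosomes (0-based half-open)
  hgt <- NULL
  if (cfg$n_hgt > 0) {
    reps <- focal$replicons[focal$replicons$class == "chromosome", ]
    picks <- lapply(seq_len(cfg$n_hgt), function(i) {
      r <- reps[1 + (i - 1) %% nrow(reps), ]
      maxs <- max(r$length - cfg$hgt_width, 1)
      s <- floor(stats::runif(1, 0, maxs))
      data.frame(replicon_id = r$replicon_id, start = s,
                 end = min(s + cfg$hgt_width, r$length),
                 stringsAsFactors = FALSE)
    })
    hgt <- do.call(rbind, picks)
  } else {
    hgt <- data.frame(replicon_id = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  }

  structure(list(focal = focal, strains = strain_bundles, ortholog_db = db,
                 truth = truth, hgt = hgt, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort to a directory tree
#'
#' Emits `focal/`, `strains/<name>/`, `ortholog_db/` bundle directories,
#' `hgt.bed` (BED3, 0-based half-open), and `truth.tsv`.
#'
#' @param cohort A `"sim_cohort"` from [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bundle(cohort$focal, file.path(dir, "focal"))
  for (s in names(cohort$strains))
    write_bundle(cohort$strains[[s]], file.path(dir, "strains", s))
  write_bundle(cohort$ortholog_db, file.path(dir, "ortholog_db"))
  utils::write.table(cohort$hgt, file.path(dir, "hgt.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
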