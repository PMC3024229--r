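# End-to-end orchestration: homology -> duplicate pairs -> COG statistics
# -> quartet dating -> strain comparison -> selection -> HGT overlap ->
# report tables. Configuration is a single YAML document; every output
# file carries the configuration hash and master seed in a comment header
# so a report can be tied to the run that produced it.

#' Default pipeline configuration
#'
#' All thresholds surfaced with their standard defaults: expectation
#' value 1e-20 and identity 30% for homology, BLOSUM62 with gaps 11/1 and
#' Karlin-Altschul (0.267, 0.041) for scoring, 100 bootstrap replicates,
#' selection reference marks 0.3/1/3, 100-kb COG cluster windows.
#'
#' @param focal,strains,ortholog_db,hgt_bed Input bundle directories
#'   (`strains` is a named list) and optional BED path.
#' @param out Output directory.
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(focal, strains = list(), ortholog_db = NULL,
                            hgt_bed = NULL, out = "genedup-report",
                            seed = 1L) {
  list(
    input = list(focal = focal, strains = strains,
                 ortholog_db = ortholog_db, hgt_bed = hgt_bed),
    thresholds = list(e_max = 1e-20, id_min = 30),
    scoring = list(gap_open = 11, gap_ext = 1, lambda = 0.267, K = 0.041),
    quartet = list(bootstrap_n = 100),
    cog = list(window = 1e5, min_count = 3),
    seed = as.integer(seed),
    out = out)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[setdiff(names(config), "out")]), tmp)
  unname(tools::md5sum(tmp))
}

.write_stamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full duplicate-gene analysis pipeline
#'
#' Stages run in order: homology search, family construction, duplicate
#' pair calling, COG statistics, quartet dating with bootstrap, strain
#' comparison, selection (Ka/Ks on common pairs per strain plus one-way
#' ANOVA on omega), HGT overlap (when a BED file is configured), and
#' report-table generation. Per-stage record counts are logged via
#' `message()`. Reruns with the same configuration and seed produce
#' byte-identical output files.
#'
#' @param config A configuration list (see [pipeline_config()]) or the
#'   path to a YAML file holding one.
#' @return Invisibly, a list with all intermediate and final objects
#'   (`hits`, `families`, `pairs`, `cog`, `quartets`, `profiles`,
#'   `selection`, `hgt`, `report`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfgin <- config$input
  if (is.null(cfgin$focal) || !dir.exists(cfgin$focal))
    stop("config error: input$focal bundle directory not found")
  for (s in names(cfgin$strains))
    if (!dir.exists(cfgin$strains[[s]]))
      stop("config error: strain bundle not found: ", s)
  if (!is.null(cfgin$ortholog_db) && !dir.exists(cfgin$ortholog_db))
    stop("config error: ortholog_db bundle directory not found")
  if (!is.null(cfgin$hgt_bed) && !file.exists(cfgin$hgt_bed))
    stop("config error: hgt_bed file not found")

  seed <- as.integer(config$seed %||% 1L)
  hash <- .config_hash(config)
  out_dir <- config$out %||% "genedup-report"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  scheme <- align_scheme(gap_open = config$scoring$gap_open %||% 11,
                         gap_ext = config$scoring$gap_ext %||% 1,
                         lambda = config$scoring$lambda %||% 0.267,
                         K = config$scoring$K %||% 0.041)
  thr <- homology_thresholds(e_max = config$thresholds$e_max %||% 1e-20,
                             id_min = config$thresholds$id_min %||% 30)
  model <- wag_model()

  focal <- .stage("read_input", read_bundle(cfgin$focal))
  strains <- .stage("read_input", {
    out <- lapply(cfgin$strains, read_bundle)
    names(out) <- names(cfgin$strains)
    out
  })
  db <- if (!is.null(cfgin$ortholog_db))
    .stage("read_input", read_bundle(cfgin$ortholog_db)) else NULL

  hits <- .stage("homology", all_vs_all(focal, thr, scheme))
  message("homology: ", nrow(hits), " directed hits")
  fams <- .stage("families", build_families(hits))
  message("families: ", length(fams$families), " (copy classes ",
          paste(fams$histogram, collapse = "/"), ")")
  pairs <- .stage("pairs", call_duplicate_pairs(fams, focal, scheme = scheme))
  message("pairs: ", nrow(pairs), " duplicate pairs")

  # COG statistics on the individual duplicated genes vs the full genome
  cogres <- .stage("cog", {
    dup_loci <- c(pairs$gene_a, pairs$gene_b)
    dup_genes <- focal$genes[focal$genes$locus_tag %in% dup_loci, ,
                             drop = FALSE]
    dup_genes <- merge(
      dup_genes,
      data.frame(locus_tag = c(pairs$gene_a, pairs$gene_b),
                 divergence = rep(pairs$divergence, 2),
                 stringsAsFactors = FALSE),
      by = "locus_tag")
    res <- list()
    for (lev in c("general", "subgroup")) {
      obs <- tally_cogs(dup_genes, lev)
      genome <- tally_cogs(focal$genes, lev)
      props <- genome$counts / genome$total
      res[[lev]] <- list(observed = obs, genome = genome,
                         gof = chisq_gof(obs, props))
    }
    res$divergence_bins <- bin_divergence(pairs)
    res$clusters <- find_cog_clusters(dup_genes,
                                      window = config$cog$window %||% 1e5,
                                      min_count = config$cog$min_count %||% 3)
    res
  })
  message("cog: general chi2 = ",
          formatC(cogres$general$gof$chi2, digits = 4, format = "f"))

  quartets <- .stage("quartets", {
    if (is.null(db) || nrow(pairs) == 0) {
      data.frame(pair_id = character(0), status = character(0),
                 ortholog_a = character(0), ortholog_b = character(0),
                 topology = character(0), call = character(0),
                 logL = numeric(0), bootstrap_support = integer(0),
                 location_class = character(0), newick = character(0),
                 stringsAsFactors = FALSE)
    } else {
      bn <- config$quartet$bootstrap_n %||% 100
      g <- focal$genes
      db_enc <- .encode_bundle(db, scheme)
      rows <- lapply(seq_len(nrow(pairs)), function(i) {
        p <- pairs[i, ]
        ch <- select_orthologs(p, focal, db, thr, scheme, db_enc = db_enc)
        if (ch$status != "ok")
          return(data.frame(pair_id = p$pair_id, status = "unresolvable",
                            ortholog_a = NA, ortholog_b = NA,
                            topology = NA, call = NA, logL = NA,
                            bootstrap_support = NA,
                            location_class = p$location_class, newick = NA,
                            stringsAsFactors = FALSE))
        seqs <- c(g$protein_seq[match(p$gene_a, g$locus_tag)],
                  g$protein_seq[match(p$gene_b, g$locus_tag)],
                  db$genes$protein_seq[match(ch$ortholog_a$id,
                                             db$genes$locus_tag)],
                  db$genes$protein_seq[match(ch$ortholog_b$id,
                                             db$genes$locus_tag)])
        msa <- align_quartet(setNames(seqs, c(p$gene_a, p$gene_b,
                                              ch$ortholog_a$id,
                                              ch$ortholog_b$id)), scheme)
        fit <- fit_quartet(msa, model)
        support <- if (bn > 0)
          bootstrap_support(msa, model, n = bn, seed = seed + i,
                            full_fit = fit) else NA_integer_
        data.frame(pair_id = p$pair_id, status = "ok",
                   ortholog_a = ch$ortholog_a$id,
                   ortholog_b = ch$ortholog_b$id,
                   topology = fit$topology, call = fit$call, logL = fit$logL,
                   bootstrap_support = support,
                   location_class = p$location_class,
                   newick = quartet_newick(fit, c(p$gene_a, p$gene_b,
                                                  ch$ortholog_a$id,
                                                  ch$ortholog_b$id)),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  })
  message("quartets: ", sum(quartets$status == "ok"), " classified, ",
          sum(quartets$status != "ok"), " unresolvable")

  profiles <- .stage("strains", match_profiles(pairs, focal, strains,
                                               thr, scheme))
  dist_tab <- match_distribution(profiles)
  common <- common_pairs(profiles)
  message("strains: ", length(common), " common pairs across ",
          length(strains), " strains")

  selection <- .stage("selection", {
    if (!length(common) || !length(strains)) {
      list(kaks = data.frame(), anova = NULL)
    } else {
      g <- focal$genes
      rows <- list()
      for (pid in common) {
        p <- pairs[pairs$pair_id == pid, ]
        members <- list(focal = c(p$gene_a, p$gene_b))
        for (s in names(strains)) {
          loci <- strsplit(profiles$loci[profiles$pair_id == pid &
                                           profiles$strain == s], ",")[[1]]
          members[[s]] <- loci
        }
        for (s in names(members)) {
          gb <- if (s == "focal") focal else strains[[s]]
          la <- members[[s]][1]; lb <- members[[s]][2]
          ga <- gb$genes[match(la, gb$genes$locus_tag), ]
          gbb <- gb$genes[match(lb, gb$genes$locus_tag), ]
          aln <- align_global(ga$protein_seq, gbb$protein_seq, scheme)
          caln <- backtranslate_pair(c(aln$aligned_a, aln$aligned_b),
                                     ga$cds_seq, gbb$cds_seq)
          kk <- kaks_myn(caln)
          rows[[length(rows) + 1L]] <- data.frame(
            pair_id = pid, strain = s, gene_a = la, gene_b = lb,
            Ka = kk$Ka, Ks = kk$Ks, omega = kk$omega, S = kk$S, N = kk$N,
            Sd = kk$Sd, Nd = kk$Nd, kappa_hat = kk$kappa_hat,
            method = kk$method, label = as.character(kk$label),
            stringsAsFactors = FALSE)
        }
      }
      kaks <- do.call(rbind, rows)
      groups <- lapply(split(kaks, kaks$strain), function(d)
        d$omega[!is.na(d$omega)])
      groups <- groups[lengths(groups) >= 2]
      anv <- if (length(groups) >= 2) anova_oneway(groups) else NULL
      list(kaks = kaks, anova = anv)
    }
  })
  if (!is.null(selection$anova))
    message("selection: mean omega = ",
            formatC(mean(selection$kaks$omega, na.rm = TRUE), digits = 3,
                    format = "f"),
            ", ANOVA p = ", formatC(selection$anova$p, digits = 3,
                                    format = "f"))

  hgt <- .stage("hgt", {
    if (is.null(cfgin$hgt_bed)) NULL else {
      iv <- read_bed(cfgin$hgt_bed, focal)
      list(intervals = iv,
           coverage = replicon_coverage(iv, focal),
           genes = genes_in_regions(iv, focal, pairs))
    }
  })

  report <- .stage("report", {
    n_pairs <- nrow(pairs)
    loc_tab <- table(factor(pairs$location_class,
                            levels = c("CI-CI", "CI-CII", "CII-CII",
                                       "C-P", "P-P")))
    list(
      copy_histogram = fams$histogram,
      n_genes = nrow(focal$genes),
      n_homologs = sum(lengths(fams$families)),
      n_pairs = n_pairs,
      location = data.frame(class = names(loc_tab),
                            n = as.integer(loc_tab),
                            pct = if (n_pairs > 0)
                              pct(as.integer(loc_tab), n_pairs)
                            else rep(NA_real_, length(loc_tab))),
      divergence_bins = cogres$divergence_bins,
      tree_types = tree_type_table(quartets),
      type_counts = table(factor(quartets$call[quartets$status == "ok"],
                                 levels = c("TypeA", "TypeB"))),
      match_distribution = dist_tab,
      n_common_pairs = length(common))
  })

  # write the report bundle
  .write_stamped(hits, file.path(out_dir, "hits.tsv"), hash, seed)
  .write_stamped(pairs, file.path(out_dir, "pairs.tsv"), hash, seed)
  .write_stamped(quartets, file.path(out_dir, "quartets.tsv"), hash, seed)
  .write_stamped(profiles, file.path(out_dir, "match_profiles.tsv"),
                 hash, seed)
  .write_stamped(dist_tab, file.path(out_dir, "match_distribution.tsv"),
                 hash, seed)
  if (nrow(selection$kaks %||% data.frame()) > 0)
    .write_stamped(selection$kaks, file.path(out_dir, "kaks.tsv"),
                   hash, seed)
  .write_stamped(
    data.frame(class = names(fams$histogram),
               n = as.integer(fams$histogram)),
    file.path(out_dir, "copy_histogram.tsv"), hash, seed)
  .write_stamped(
    data.frame(bin = names(cogres$divergence_bins),
               n = as.integer(cogres$divergence_bins)),
    file.path(out_dir, "divergence_bins.tsv"), hash, seed)
  .write_stamped(report$tree_types, file.path(out_dir, "tree_types.tsv"),
                 hash, seed)
  .write_stamped(report$location, file.path(out_dir, "location.tsv"),
                 hash, seed)
  cog_tab <- data.frame(
    level = rep(c("general", "subgroup"),
                c(length(cogres$general$observed$counts),
                  length(cogres$subgroup$observed$counts))),
    category = c(names(cogres$general$observed$counts),
                 names(cogres$subgroup$observed$counts)),
    dup_count = c(as.integer(cogres$general$observed$counts),
                  as.integer(cogres$subgroup$observed$counts)),
    genome_count = c(as.integer(cogres$general$genome$counts),
                     as.integer(cogres$subgroup$genome$counts)))
  .write_stamped(cog_tab, file.path(out_dir, "cog_distribution.tsv"),
                 hash, seed)
  stats_tab <- data.frame(
    quantity = c("cog_general_chi2", "cog_general_p",
                 "cog_subgroup_chi2", "cog_subgroup_p",
                 "anova_F", "anova_p", "pooled_sd", "n_common_pairs"),
    value = c(cogres$general$gof$chi2, cogres$general$gof$p,
              cogres$subgroup$gof$chi2, cogres$subgroup$gof$p,
              if (is.null(selection$anova)) NA else selection$anova$F,
              if (is.null(selection$anova)) NA else selection$anova$p,
              if (is.null(selection$anova)) NA
              else selection$anova$pooled_sd,
              length(common)))
  .write_stamped(stats_tab, file.path(out_dir, "summary_stats.tsv"),
                 hash, seed)
  if (!is.null(hgt))
    .write_stamped(hgt$coverage, file.path(out_dir, "hgt_coverage.tsv"),
                   hash, seed)
  nwk <- quartets$newick[quartets$status == "ok"]
  if (length(nwk)) {
    con <- file(file.path(out_dir, "trees.nwk"), "w")
    writeLines(nwk, con)
    close(con)
  }

  invisible(list(hits = hits, families = fams, pairs = pairs, cog = cogres,
                 quartets = quartets, profiles = profiles,
                 match_distribution = dist_tab, common_pairs = common,
                 selection = selection, hgt = hgt, report = report,
                 config = config, config_md5 = hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
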