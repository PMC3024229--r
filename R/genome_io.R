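# Genome bundles: a strain's protein FASTA + CDS FASTA + gene table,
# validated into one in-memory object. Coordinates are 1-based inclusive on
# the forward strand; cds_seq is stored already strand-resolved (reverse
# complemented for "-" genes) so codon-level code never touches strand.

#' The 25-letter COG category alphabet
#'
#' Single-letter functional categories, grouped into four general classes
#' (information storage and processing; cellular processes and signaling;
#' metabolism; poorly characterized). Genes without any category form the
#' fifth, unclassified general group 0.
#' @export
COG_LETTERS <- c("J", "A", "K", "L", "B",
                 "D", "Y", "V", "T", "M", "N", "Z", "W", "U", "O",
                 "C", "G", "E", "F", "H", "I", "P", "Q",
                 "R", "S")

#' Map COG letters to the four general groups
#'
#' Group 1 = information storage and processing, 2 = cellular processes and
#' signaling, 3 = metabolism, 4 = poorly characterized. Unannotated genes
#' are group 0.
#' @export
COG_GENERAL_GROUP <- c(
  J = 1L, A = 1L, K = 1L, L = 1L, B = 1L,
  D = 2L, Y = 2L, V = 2L, T = 2L, M = 2L, N = 2L, Z = 2L, W = 2L,
  U = 2L, O = 2L,
  C = 3L, G = 3L, E = 3L, F = 3L, H = 3L, I = 3L, P = 3L, Q = 3L,
  R = 4L, S = 4L)

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; record order is preserved. Duplicate IDs,
#' empty sequences, and gap characters are rejected. The ID is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  if (any(grepl("[-.]", seqs)))
    stop("gap characters are not allowed in input FASTA")
  setNames(as.character(seqs), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a CDS under the bacterial genetic code (table 11)
#'
#' Length must be divisible by 3. A terminal stop codon is stripped;
#' internal stop codons are an error. Ambiguous bases are accepted only
#' when the degeneracy still determines a unique amino acid.
#'
#' @param dna Single nucleotide string.
#' @return Amino-acid string.
#' @export
translate_cds <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1)
  .translate_batch(dna)
}

# vectorized translation with the same semantics as translate_cds()
.translate_batch <- function(dna) {
  if (!length(dna)) return(character(0))
  dna <- toupper(dna)
  if (any(nchar(dna) %% 3 != 0))
    stop("CDS length not divisible by 3")
  aa <- tryCatch(
    as.character(Biostrings::translate(
      Biostrings::DNAStringSet(dna),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "solve", no.init.codon = TRUE)),
    error = function(e) stop("untranslatable codon: ", conditionMessage(e),
                             call. = FALSE))
  n <- nchar(aa)
  term <- n > 0 & substr(aa, n, n) == "*"
  aa[term] <- substr(aa[term], 1L, n[term] - 1L)
  if (any(grepl("*", aa, fixed = TRUE)))
    stop("internal stop codon in CDS")
  if (any(grepl("X", aa, fixed = TRUE)))
    stop("ambiguous codon does not determine a unique amino acid")
  unname(aa)
}

#' Construct and validate a genome bundle
#'
#' @param strain Strain name.
#' @param replicons data.frame with columns `replicon_id`, `class`
#'   ("chromosome" or "plasmid"), `length` (nt).
#' @param genes data.frame with columns `locus_tag`, `strain`,
#'   `replicon_id`, `replicon_class`, `start`, `end`, `strand`, `cogs`
#'   (concatenated letters, "" for none), `protein_seq`, `cds_seq`.
#' @return Object of class `"genome_bundle"`.
#' @export
genome_bundle <- function(strain, replicons, genes) {
  b <- structure(list(strain = strain, replicons = replicons, genes = genes),
                 class = "genome_bundle")
  validate_bundle(b)
  b
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", x$strain, "-", nrow(x$genes), "genes on",
      nrow(x$replicons), "replicon(s)\n")
  invisible(x)
}

#' Validate a genome bundle's invariants
#'
#' Checks locus-tag uniqueness, coordinate sanity against replicon lengths,
#' CDS/protein consistency (code 11, terminal stop stripped), and COG
#' letters against the 25-letter alphabet.
#'
#' @param bundle A [genome_bundle()].
#' @return `bundle`, invisibly; stops with an informative error otherwise.
#' @export
validate_bundle <- function(bundle) {
  g <- bundle$genes
  r <- bundle$replicons
  stopifnot(is.data.frame(g), is.data.frame(r))
  if (anyDuplicated(g$locus_tag))
    stop("duplicate locus tags: ",
         paste(unique(g$locus_tag[duplicated(g$locus_tag)]), collapse = ", "))
  if (!all(g$replicon_id %in% r$replicon_id))
    stop("gene(s) on unknown replicon: ",
         paste(g$locus_tag[!g$replicon_id %in% r$replicon_id], collapse = ", "))
  if (any(g$start > g$end))
    stop("start > end for: ", paste(g$locus_tag[g$start > g$end], collapse = ", "))
  if (any(g$start < 1))
    stop("coordinates must be 1-based positive")
  rlen <- setNames(r$length, r$replicon_id)
  over <- g$end > rlen[g$replicon_id]
  if (any(over))
    stop("gene extends past replicon end: ",
         paste(g$locus_tag[over], collapse = ", "))
  if (!all(g$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(g$replicon_class %in% c("chromosome", "plasmid")))
    stop("replicon_class must be 'chromosome' or 'plasmid'")
  bad_cog <- vapply(strsplit(g$cogs, ""), function(x)
    any(!x %in% COG_LETTERS), logical(1))
  if (any(bad_cog))
    stop("unknown COG letter(s) for: ",
         paste(g$locus_tag[bad_cog], collapse = ", "))
  if (nrow(g) > 0) {
    tr <- .translate_batch(g$cds_seq)
    bad <- tr != g$protein_seq
    if (any(bad))
      stop("protein/CDS mismatch for ",
           paste(g$locus_tag[bad], collapse = ", "))
  }
  invisible(bundle)
}

#' Read a gene table plus its FASTA files into a genome bundle
#'
#' The gene table is a TSV with header
#' `locus_tag strain replicon_id replicon_class start end strand cogs`
#' (`cogs` is a string of concatenated category letters, `-` for none).
#' Every row must have both a protein and a CDS FASTA entry under its locus
#' tag. Replicon lengths can be supplied as a data.frame or TSV
#' (`replicon_id class length`); if absent they are inferred as the largest
#' gene end per replicon.
#'
#' @param path Gene table TSV.
#' @param fasta_prot,fasta_cds Paths to the protein and CDS FASTA files.
#' @param replicons Optional data.frame or TSV path with replicon lengths.
#' @return A [genome_bundle()].
#' @export
read_gene_table <- function(path, fasta_prot, fasta_cds, replicons = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("locus_tag", "strain", "replicon_id", "replicon_class",
            "start", "end", "strand", "cogs")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$cogs <- ifelse(tab$cogs == "-", "", tab$cogs)
  prot <- read_fasta(fasta_prot)
  cds <- read_fasta(fasta_cds)
  missing <- setdiff(tab$locus_tag, intersect(names(prot), names(cds)))
  if (length(missing))
    stop("gene table row(s) lacking FASTA entry: ",
         paste(missing, collapse = ", "))
  tab$protein_seq <- unname(prot[tab$locus_tag])
  tab$cds_seq <- unname(cds[tab$locus_tag])
  if (is.character(replicons) && length(replicons) == 1)
    replicons <- utils::read.delim(replicons, stringsAsFactors = FALSE)
  if (is.null(replicons)) {
    replicons <- do.call(rbind, lapply(split(tab, tab$replicon_id), function(d)
      data.frame(replicon_id = d$replicon_id[1], class = d$replicon_class[1],
                 length = max(d$end), stringsAsFactors = FALSE)))
    rownames(replicons) <- NULL
  }
  strain <- unique(tab$strain)
  # a concatenated ortholog database legitimately mixes species; the
  # bundle is then labelled by convention
  strain <- if (length(strain) == 1) strain else "multi-species"
  genome_bundle(strain, replicons, tab)
}

#' Write a genome bundle's gene table as TSV
#'
#' Inverse of [read_gene_table()] (together with [write_fasta()] for the
#' two sequence files).
#'
#' @param bundle A [genome_bundle()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(bundle, path) {
  g <- bundle$genes
  out <- g[, c("locus_tag", "strain", "replicon_id", "replicon_class",
               "start", "end", "strand", "cogs")]
  out$cogs <- ifelse(out$cogs == "", "-", out$cogs)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full genome bundle to a directory
#'
#' Emits `proteins.faa`, `cds.fna`, `genes.tsv`, and `replicons.tsv`.
#'
#' @param bundle A [genome_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(bundle$genes$protein_seq, bundle$genes$locus_tag),
              file.path(dir, "proteins.faa"))
  write_fasta(setNames(bundle$genes$cds_seq, bundle$genes$locus_tag),
              file.path(dir, "cds.fna"))
  write_gene_table(bundle, file.path(dir, "genes.tsv"))
  utils::write.table(bundle$replicons, file.path(dir, "replicons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a genome bundle written by [write_bundle()]
#'
#' @param dir Directory holding `proteins.faa`, `cds.fna`, `genes.tsv`,
#'   `replicons.tsv`.
#' @return A [genome_bundle()].
#' @export
read_bundle <- function(dir) {
  read_gene_table(file.path(dir, "genes.tsv"),
                  file.path(dir, "proteins.faa"),
                  file.path(dir, "cds.fna"),
                  replicons = file.path(dir, "replicons.tsv"))
}
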