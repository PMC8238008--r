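#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic genome / expression generator. All downstream
#' modules can be exercised on data produced from a `SimConfig`; the generator
#' also emits machine-readable truth tables so recovered calls can be compared
#' with what was planted.
#'
#' @slot n_chromosomes number of chromosomes.
#' @slot chrom_length chromosome length in bp (all chromosomes equal).
#' @slot n_genes total number of protein-coding genes.
#' @slot family_sizes named integer vector, kinase family name -> member count.
#' @slot kinase_cds_codons codon length of every kinase founder CDS (a common
#'   length keeps the substitution-only family evolution gap-free, so the raw
#'   member sequences already form a valid alignment).
#' @slot duplication_plan data.frame with columns `class`
#'   (tandem/proximal/dispersed/wgd_segmental) and `count` (number of planted
#'   pairs; for wgd_segmental the count is the block size in pairs, >= 5).
#' @slot collinear_block_plan data.frame with columns `chromA`, `chromB`,
#'   `n_pairs` (each row one planted inter-chromosomal collinear chain).
#' @slot promoter_motif_plan data.frame with columns `family`, `motif_id`,
#'   `fg_fraction`, `bg_fraction` (fractions of promoters carrying a planted
#'   motif occurrence in the family foreground vs the rest of the genome).
#' @slot de_plan data.frame with columns `family`, `n_up`, `mean_log2FC`.
#' @slot omega_plan numeric vector of selection intensities (Ka/Ks acceptance
#'   probabilities) for simulated CDS pairs.
#' @slot divergence per-site nucleotide substitution rate between duplicate
#'   copies (default 0.02, low enough to keep similarity hits unambiguous).
#' @slot duplication_omega selection intensity under which duplicate and
#'   family copies diverge (default 0.2: purifying, the regime typical of
#'   retained duplicates).
#' @slot seed integer seed; a fixed seed gives byte-identical outputs.
#' @export
setClass("SimConfig", representation(
  n_chromosomes = "integer",
  chrom_length = "integer",
  n_genes = "integer",
  family_sizes = "integer",
  kinase_cds_codons = "integer",
  duplication_plan = "data.frame",
  collinear_block_plan = "data.frame",
  promoter_motif_plan = "data.frame",
  de_plan = "data.frame",
  omega_plan = "numeric",
  divergence = "numeric",
  duplication_omega = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x <= 0L)
      msg <<- c(msg, sprintf("%s must be a single positive value", what))
  }
  pos(object@n_chromosomes, "n_chromosomes")
  pos(object@chrom_length, "chrom_length")
  pos(object@n_genes, "n_genes")
  pos(object@kinase_cds_codons, "kinase_cds_codons")
  if (length(object@family_sizes) &&
      (is.null(names(object@family_sizes)) || any(object@family_sizes <= 0L)))
    msg <- c(msg, "family_sizes must be a named vector of positive counts")
  dp <- object@duplication_plan
  if (nrow(dp)) {
    bad <- setdiff(dp$class, c("tandem", "proximal", "dispersed", "wgd_segmental"))
    if (length(bad))
      msg <- c(msg, paste("unknown duplication class:", paste(bad, collapse = ", ")))
    if (any(dp$count <= 0)) msg <- c(msg, "duplication_plan counts must be positive")
    if (any(dp$class == "wgd_segmental" & dp$count < 5))
      msg <- c(msg, "wgd_segmental blocks must contain at least 5 gene pairs")
  }
  cb <- object@collinear_block_plan
  if (nrow(cb)) {
    if (any(cb$n_pairs < 5))
      msg <- c(msg, "collinear blocks must contain at least 5 gene pairs")
    if (any(cb$chromA > object@n_chromosomes | cb$chromB > object@n_chromosomes))
      msg <- c(msg, "collinear_block_plan references a chromosome beyond n_chromosomes")
  }
  pm <- object@promoter_motif_plan
  if (nrow(pm) && (any(pm$fg_fraction < 0 | pm$fg_fraction > 1) ||
                   any(pm$bg_fraction < 0 | pm$bg_fraction > 1)))
    msg <- c(msg, "motif plan fractions must lie in [0, 1]")
  if (any(object@omega_plan < 0)) msg <- c(msg, "omega values must be >= 0")
  if (object@divergence < 0 || object@divergence > 0.2)
    msg <- c(msg, "divergence must lie in [0, 0.2]")
  if (length(object@duplication_omega) != 1 || object@duplication_omega < 0)
    msg <- c(msg, "duplication_omega must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Genome annotation container
#'
#' A thin wrapper around a [GenomicRanges::GRanges] of gene-model features
#' (gene, mRNA, exon, CDS, five_prime_UTR, three_prime_UTR) with `type`, `ID`
#' and `Parent` metadata columns, using 1-based inclusive coordinates as in
#' GFF3.
#'
#' @slot features GRanges of all features.
#' @export
setClass("GenomeAnnotation", representation(features = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  gr <- object@features
  md <- S4Vectors::mcols(gr)
  msg <- character()
  need <- c("type", "ID", "Parent")
  missing_cols <- setdiff(need, colnames(md))
  if (length(missing_cols))
    return(paste("missing metadata columns:", paste(missing_cols, collapse = ", ")))
  known <- c("gene", "mRNA", "exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  bad <- setdiff(unique(as.character(md$type)), known)
  if (length(bad)) msg <- c(msg, paste("unknown feature types:", paste(bad, collapse = ", ")))
  gid <- md$ID[md$type == "gene"]
  if (anyDuplicated(gid)) msg <- c(msg, "duplicate gene IDs")
  if (length(msg)) msg else TRUE
})

#' Kinase catalog
#'
#' One row per candidate kinase locus: family assignment, group (the family
#' prefix before the first underscore), number of qualifying kinase-domain
#' hits, and catalog status. Status is `candidate` until the tree-concordance
#' filter promotes members to `bona_fide` or demotes them to `UNK`.
#'
#' @slot table data.frame with columns protein_id, family, group, n_domains,
#'   status.
#' @export
setClass("KinaseCatalog", representation(table = "data.frame"))

setValidity("KinaseCatalog", function(object) {
  tb <- object@table
  need <- c("protein_id", "family", "group", "n_domains", "status")
  missing_cols <- setdiff(need, colnames(tb))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(tb$protein_id)) msg <- c(msg, "duplicate protein ids")
  if (!all(tb$status %in% c("candidate", "bona_fide", "UNK")))
    msg <- c(msg, "status must be candidate, bona_fide or UNK")
  if (any(tb$n_domains < 1)) msg <- c(msg, "candidates must have >= 1 kinase domain")
  if (length(msg)) msg else TRUE
})
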