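#' Average residue masses (Da) for the 20 standard amino acids
#'
#' Monoisotopic-free average masses of amino-acid residues (i.e. minus one
#' water); a peptide mass is the residue sum plus one water (18.0153 Da).
#' @export
RESIDUE_MASSES <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Default pKa table for isoelectric-point calculation
#'
#' Henderson-Hasselbalch pKa values for the ionizable groups: the N- and
#' C-termini and the side chains of K, R, H (basic) and D, E, C, Y (acidic).
#' @export
PKA_TABLE <- c(Nterm = 9.69, Cterm = 2.34, K = 10.5, R = 12.4, H = 6.0,
               D = 3.9, E = 4.1, C = 8.3, Y = 10.1)

.checkProtein <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), names(RESIDUE_MASSES))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  chars
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @param masses residue mass table (defaults to [RESIDUE_MASSES]).
#' @return molecular weight in daltons.
#' @examples
#' proteinMW("G")  # 75.0672
#' @export
proteinMW <- function(sequence, masses = RESIDUE_MASSES) {
  chars <- .checkProtein(sequence)
  sum(masses[chars]) + 18.0153
}

# net charge at a given pH for a residue-composition vector
.netCharge <- function(pH, counts, pka) {
  pos <- 1 / (1 + 10^(pH - pka["Nterm"]))
  for (r in c("K", "R", "H"))
    pos <- pos + counts[r] / (1 + 10^(pH - pka[r]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - pH))
  for (r in c("D", "E", "C", "Y"))
    neg <- neg + counts[r] / (1 + 10^(pka[r] - pH))
  unname(pos - neg)
}

#' Protein isoelectric point
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge (N-terminus plus
#' K/R/H side chains, minus C-terminus plus D/E/C/Y side chains) vanishes. The
#' charge is strictly decreasing in pH, so bisection on (0, 14) converges to
#' the unique root.
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @param tolerance stop when `|net charge| < tolerance` (default 1e-4).
#' @param pka pKa table (defaults to [PKA_TABLE]).
#' @return pI in pH units.
#' @examples
#' proteinPi("G")  # 6.015, midpoint of the two terminal pKa values
#' @export
proteinPi <- function(sequence, tolerance = 1e-4, pka = PKA_TABLE) {
  chars <- .checkProtein(sequence)
  counts <- stats::setNames(numeric(length(names(RESIDUE_MASSES))),
                            names(RESIDUE_MASSES))
  tt <- table(chars)
  counts[names(tt)] <- as.numeric(tt)
  lo <- 0; hi <- 14
  for (it in seq_len(100)) {
    mid <- (lo + hi) / 2
    q <- .netCharge(mid, counts, pka)
    if (abs(q) < tolerance) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- gene structural features ---------------------------------------------

.childrenOf <- function(gr, parent_id, type) {
  md <- S4Vectors::mcols(gr)
  gr[md$type == type & md$Parent %in% parent_id]
}

#' Per-gene structural features
#'
#' Computes the 12 gene-structure parameters on the primary transcript of a
#' gene (the mRNA with the greatest total exon length; ties broken by
#' lexicographic transcript id): mature transcript length (sum of exon
#' lengths), exon/intron counts and total lengths, CDS chunk count and total
#' length, 5'/3' UTR counts and total lengths, and the number of kinase
#' domains supplied by the caller. Introns are the gaps between sorted exons.
#' UTRs are taken from five_prime_UTR/three_prime_UTR records when present,
#' otherwise derived as exon minus CDS on the appropriate side of the CDS
#' span. The genomic span (exons plus introns) is reported alongside the
#' mature transcript length.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param gene_id single gene identifier.
#' @param domain_counts named integer vector gene/protein id -> kinase-domain
#'   count (0 when absent).
#' @return one-row data.frame of the features.
#' @export
computeGeneFeatures <- function(annotation, gene_id, domain_counts = integer(0)) {
  gr <- annFeatures(annotation)
  md <- S4Vectors::mcols(gr)
  mrnas <- .childrenOf(gr, gene_id, "mRNA")
  if (!length(mrnas))
    stop("gene ", gene_id, " has no mRNA")
  exon_len <- vapply(S4Vectors::mcols(mrnas)$ID, function(tx)
    sum(BiocGenerics::width(.childrenOf(gr, tx, "exon"))), numeric(1))
  ord <- order(-exon_len, S4Vectors::mcols(mrnas)$ID)
  tx_id <- S4Vectors::mcols(mrnas)$ID[ord[1]]
  tx <- mrnas[ord[1]]
  strand <- as.character(BiocGenerics::strand(tx))

  exons <- .childrenOf(gr, tx_id, "exon")
  if (!length(exons)) stop("transcript ", tx_id, " has no exons")
  exons <- exons[order(BiocGenerics::start(exons))]
  st <- BiocGenerics::start(exons); en <- BiocGenerics::end(exons)
  if (length(exons) > 1 && any(st[-1] <= en[-length(en)]))
    stop("overlapping exons in transcript ", tx_id)
  n_exons <- length(exons)
  exon_total <- sum(en - st + 1)
  span <- max(en) - min(st) + 1
  n_introns <- n_exons - 1L
  intron_total <- span - exon_total

  cds <- .childrenOf(gr, tx_id, "CDS")
  if (length(cds)) {
    inside <- IRanges::overlapsAny(IRanges::IRanges(BiocGenerics::start(cds),
                                                    BiocGenerics::end(cds)),
                                   IRanges::IRanges(st, en), type = "within")
    if (!all(inside))
      stop("CDS outside exons in transcript ", tx_id)
  }
  n_cds <- length(cds)
  cds_total <- sum(BiocGenerics::width(cds))

  utr5 <- .childrenOf(gr, tx_id, "five_prime_UTR")
  utr3 <- .childrenOf(gr, tx_id, "three_prime_UTR")
  if (length(utr5) || length(utr3) || !length(cds)) {
    n_u5 <- length(utr5); u5_total <- sum(BiocGenerics::width(utr5))
    n_u3 <- length(utr3); u3_total <- sum(BiocGenerics::width(utr3))
  } else {
    # derive UTRs as exon minus CDS on each side of the CDS span
    cds_start <- min(BiocGenerics::start(cds))
    cds_end <- max(BiocGenerics::end(cds))
    ex <- IRanges::IRanges(st, en)
    left <- IRanges::restrict(ex, end = cds_start - 1L)
    right <- IRanges::restrict(ex, start = cds_end + 1L)
    left <- left[IRanges::width(left) > 0]
    right <- right[IRanges::width(right) > 0]
    if (strand == "-") { tmp <- left; left <- right; right <- tmp }
    n_u5 <- length(left); u5_total <- sum(IRanges::width(left))
    n_u3 <- length(right); u3_total <- sum(IRanges::width(right))
  }

  nd <- if (gene_id %in% names(domain_counts)) domain_counts[[gene_id]]
        else if (tx_id %in% names(domain_counts)) domain_counts[[tx_id]]
        else 0L
  data.frame(
    gene_id = gene_id, transcript_id = tx_id,
    transcript_length = exon_total, genomic_span = span,
    n_exons = n_exons, exon_length_total = exon_total,
    n_introns = n_introns, intron_length_total = intron_total,
    n_cds_chunks = n_cds, cds_length_total = cds_total,
    n_utr5 = n_u5, utr5_length_total = u5_total,
    n_utr3 = n_u3, utr3_length_total = u3_total,
    n_kinase_domains = as.integer(nd),
    stringsAsFactors = FALSE
  )
}

#' Structural features for every gene of an annotation
#'
#' @inheritParams computeGeneFeatures
#' @param gene_ids genes to process (default: all annotated genes).
#' @return data.frame, one row per gene (see [computeGeneFeatures()]).
#' @export
geneFeatureTable <- function(annotation, domain_counts = integer(0),
                             gene_ids = NULL) {
  if (is.null(gene_ids))
    gene_ids <- S4Vectors::mcols(annGenes(annotation))$ID
  do.call(rbind, lapply(gene_ids, computeGeneFeatures,
                        annotation = annotation,
                        domain_counts = domain_counts))
}

#' Family-level means of the structural features
#'
#' @param catalog a [KinaseCatalog-class] (or data.frame with `protein_id` and
#'   `family`).
#' @param features data.frame from [geneFeatureTable()] whose `gene_id` (or
#'   `transcript_id`) matches catalog protein ids.
#' @return data.frame of per-family arithmetic means of all feature columns
#'   plus the member count; empty families are skipped with a warning.
#' @export
familyFeatureSummary <- function(catalog, features) {
  tb <- if (is(catalog, "KinaseCatalog")) catalogTable(catalog) else catalog
  key <- if (all(tb$protein_id %in% features$gene_id)) "gene_id" else "transcript_id"
  idx <- match(tb$protein_id, features[[key]])
  if (anyNA(idx))
    stop("catalog member without features: ",
         paste(tb$protein_id[is.na(idx)], collapse = ", "))
  fam <- tb$family
  if (anyNA(fam)) {
    warning(sum(is.na(fam)), " unassigned member(s) skipped")
    keep <- !is.na(fam)
    fam <- fam[keep]; idx <- idx[keep]
  }
  num_cols <- c("transcript_length", "genomic_span", "n_exons",
                "exon_length_total", "n_introns", "intron_length_total",
                "n_cds_chunks", "cds_length_total", "n_utr5",
                "utr5_length_total", "n_utr3", "utr3_length_total",
                "n_kinase_domains")
  sub <- features[idx, num_cols, drop = FALSE]
  agg <- stats::aggregate(sub, by = list(family = fam), FUN = mean)
  agg$n_members <- as.integer(table(fam)[agg$family])
  agg[order(agg$family), , drop = FALSE]
}
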