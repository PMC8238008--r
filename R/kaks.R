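#' Jukes-Cantor multiple-hit correction
#'
#' Corrects an observed proportion of differences per site for multiple
#' substitutions: `d = -(3/4) * log(1 - (4/3) * p)`.
#'
#' @param p proportion of differing sites, `0 <= p < 3/4`.
#' @return corrected distance (substitutions per site).
#' @examples
#' jukesCantor(0)     # 0
#' jukesCantor(0.3)   # 0.38312
#' @export
jukesCantor <- function(p) {
  if (any(is.na(p)) || any(p < 0))
    stop("p must be a non-negative proportion")
  if (any(p >= 0.75))
    stop("Jukes-Cantor correction undefined for p >= 3/4 (saturation)")
  -0.75 * log(1 - (4 / 3) * p)
}

#' Build a pairwise codon alignment from a protein alignment
#'
#' Maps the columns of a pairwise protein alignment back onto the two coding
#' sequences. Columns gapped in either protein, and codons containing
#' ambiguous nucleotides or stop codons, are dropped pairwise; the number of
#' excluded codon columns is reported.
#'
#' @param prot_aln character vector of length 2 (aligned protein sequences,
#'   gaps as `-`), or an `AAStringSet` of length 2.
#' @param cds character vector of length 2 with the corresponding coding
#'   sequences (a trailing stop codon is tolerated and trimmed).
#' @return list with `codons1`, `codons2` (retained codon vectors), and
#'   `n_excluded` (codon columns dropped).
#' @export
codonAlign <- function(prot_aln, cds) {
  prot_aln <- as.character(prot_aln)
  cds <- toupper(as.character(cds))
  if (length(prot_aln) != 2L || length(cds) != 2L)
    stop("codonAlign expects exactly two sequences")
  ids <- names(cds)
  if (is.null(ids)) ids <- c("seq1", "seq2")
  cod <- vector("list", 2L)
  for (k in 1:2) {
    codons <- .splitCodons(cds[k])
    aa <- .translateCodons(ifelse(grepl("^[ACGT]{3}$", codons), codons, "NNN"))
    if (length(codons) > 1 && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    ungapped <- gsub("-", "", prot_aln[k])
    if (nchar(ungapped) != length(codons))
      stop("CDS/protein length mismatch for ", ids[k], ": ",
           length(codons), " codons vs ", nchar(ungapped), " residues")
    cod[[k]] <- codons
  }
  a1 <- strsplit(prot_aln[1], "")[[1]]
  a2 <- strsplit(prot_aln[2], "")[[1]]
  if (length(a1) != length(a2))
    stop("aligned proteins differ in length")
  i1 <- 0L; i2 <- 0L
  keep1 <- character(0); keep2 <- character(0)
  excluded <- 0L
  aa_tab <- .codonAA()
  for (col in seq_along(a1)) {
    g1 <- a1[col] == "-"; g2 <- a2[col] == "-"
    if (!g1) i1 <- i1 + 1L
    if (!g2) i2 <- i2 + 1L
    if (g1 || g2) { excluded <- excluded + 1L; next }
    c1 <- cod[[1]][i1]; c2 <- cod[[2]][i2]
    ok <- grepl("^[ACGT]{3}$", c1) && grepl("^[ACGT]{3}$", c2) &&
      aa_tab[c1] != "*" && aa_tab[c2] != "*"
    if (!ok) { excluded <- excluded + 1L; next }
    keep1 <- c(keep1, c1); keep2 <- c(keep2, c2)
  }
  list(codons1 = keep1, codons2 = keep2, n_excluded = excluded)
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence under the
#' standard genetic code (single-nucleotide changes to stop codons counted as
#' nonsynonymous), averages S and N over the two sequences, and counts
#' synonymous/nonsynonymous differences per differing codon by equal-weight
#' averaging over all minimal mutational pathways, excluding pathways through
#' stop codons. Proportions `pS = Sd/S` and `pN = Nd/N` are corrected with the
#' Jukes-Cantor formula to give `Ks` and `Ka`; the selection regime follows
#' the usual interpretation of the ratio `Ka/Ks` (< 1 purifying, = 1 neutral,
#' > 1 positive).
#'
#' @param aln a codon alignment from [codonAlign()], or a list with `codons1`
#'   and `codons2` codon vectors.
#' @return one-row data.frame: `codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ka`, `Ks`, `ratio`, `selection`. `Ka`/`Ks` are `NA` when the correction
#'   is undefined (p >= 3/4); `ratio` is `NA` when `Ks` is 0 or undefined, and
#'   `selection` is then `"undefined"`.
#' @export
neiGojobori <- function(aln) {
  c1 <- aln$codons1; c2 <- aln$codons2
  if (length(c1) != length(c2))
    stop("codon vectors differ in length")
  if (!length(c1))
    stop("empty codon alignment")
  aa <- .codonAA()
  if (any(aa[c1] == "*") || any(aa[c2] == "*"))
    stop("internal stop codon in codon alignment")
  syn_sites <- .synSiteTable()
  L <- length(c1)
  S <- (sum(syn_sites[c1]) + sum(syn_sites[c2])) / 2
  N <- 3 * L - S
  tabs <- .pathwayDiffTable()
  diff <- c1 != c2
  Sd <- sum(tabs$sd[cbind(c1[diff], c2[diff])])
  Nd <- sum(tabs$nd[cbind(c1[diff], c2[diff])])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- if (pS < 0.75) jukesCantor(pS) else NA_real_
  Ka <- if (pN < 0.75) jukesCantor(pN) else NA_real_
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  data.frame(
    codons = L, S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    Ka = Ka, Ks = Ks, ratio = ratio,
    selection = kaksClassify(ratio),
    stringsAsFactors = FALSE
  )
}

#' Classify a Ka/Ks ratio into a selection regime
#'
#' @param ratio Ka/Ks value (may be `NA` for undefined).
#' @param tol tolerance around 1 treated as neutral (exact equality is
#'   measure-zero in floating point).
#' @return `"purifying"`, `"neutral"`, `"positive"` or `"undefined"`.
#' @export
kaksClassify <- function(ratio, tol = 1e-9) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("undefined")
    if (abs(r - 1) <= tol) return("neutral")
    if (r < 1) "purifying" else "positive"
  }, character(1))
}

#' Ka/Ks for a table of gene pairs
#'
#' Convenience wrapper running [codonAlign()] + [neiGojobori()] over a set of
#' CDS pairs whose proteins are identical in length (gap-free alignment) or
#' for which a protein alignment is supplied.
#'
#' @param pairs data.frame with columns `gene1`, `gene2`.
#' @param cds named character vector (or `DNAStringSet`) of coding sequences.
#' @param prot_alns optional list (one entry per pair) of length-2 aligned
#'   protein vectors; when `NULL`, proteins are translated and must be equal
#'   length.
#' @return data.frame with one [neiGojobori()] row per pair plus `gene1`,
#'   `gene2`.
#' @export
kaksTable <- function(pairs, cds, prot_alns = NULL) {
  cds <- stats::setNames(toupper(as.character(cds)), names(cds))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    if (!g1 %in% names(cds) || !g2 %in% names(cds))
      stop("pair references unknown sequence: ", g1, " / ", g2)
    if (is.null(prot_alns)) {
      p1 <- .cdsToProtein(cds[[g1]])
      p2 <- .cdsToProtein(cds[[g2]])
      if (nchar(p1) != nchar(p2))
        stop("proteins of ", g1, " and ", g2,
             " differ in length; supply prot_alns")
      aln <- c(p1, p2)
    } else aln <- prot_alns[[i]]
    ca <- codonAlign(aln, stats::setNames(c(cds[[g1]], cds[[g2]]), c(g1, g2)))
    res <- neiGojobori(ca)
    out[[i]] <- cbind(data.frame(gene1 = g1, gene2 = g2,
                                 stringsAsFactors = FALSE), res)
  }
  do.call(rbind, out)
}

# translate a CDS (trailing stop trimmed) to its protein string
.cdsToProtein <- function(cds) {
  codons <- .splitCodons(cds)
  aa <- .translateCodons(codons)
  if (length(aa) > 1 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}
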