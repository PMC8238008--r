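# Codon bookkeeping shared by the Ka/Ks engine and the CDS evolver.
# All tables derive from the standard genetic code (Biostrings::GENETIC_CODE)
# and are built once per session, cached in a package environment.

.pk_cache <- new.env(parent = emptyenv())

.codonUniverse <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

#' @importFrom Biostrings GENETIC_CODE
.codonAA <- function() {
  if (is.null(.pk_cache$aa)) {
    codons <- .codonUniverse()
    gc <- Biostrings::GENETIC_CODE
    # GENETIC_CODE is keyed by RNA-free DNA codons (T not U)
    .pk_cache$aa <- stats::setNames(unname(gc[codons]), codons)
  }
  .pk_cache$aa
}

.isStopCodon <- function(codon) .codonAA()[codon] == "*"

# Per-codon synonymous site count: at each of the 3 positions, the fraction of
# the 3 possible single-nucleotide changes that preserve the amino acid.
# Changes creating a stop codon count as nonsynonymous (NG86 convention).
.synSiteTable <- function() {
  if (!is.null(.pk_cache$syn_sites)) return(.pk_cache$syn_sites)
  aa <- .codonAA()
  codons <- names(aa)
  nt <- c("A", "C", "G", "T")
  s <- stats::setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (aa[cod] == "*") { s[cod] <- NA_real_; next }
    bases <- strsplit(cod, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(nt, bases[pos])) {
        mut <- bases
        mut[pos] <- b
        mcod <- paste(mut, collapse = "")
        if (aa[mcod] != "*" && aa[mcod] == aa[cod]) syn <- syn + 1
      }
    }
    s[cod] <- syn / 3
  }
  .pk_cache$syn_sites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between every
# ordered pair of non-stop codons. Minimal mutational pathways (orderings of
# the differing positions) that pass through a stop codon are excluded and the
# weights renormalized; if every pathway is blocked, all pathways are used
# unweighted (rare fallback, keeps Sd + Nd equal to the number of differing
# positions).
.pathwayDiffTable <- function() {
  if (!is.null(.pk_cache$diffs)) return(.pk_cache$diffs)
  aa <- .codonAA()
  codons <- names(aa)[aa != "*"]
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in seq_len(n)) {
    bi <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      bj <- strsplit(codons[j], "")[[1]]
      dpos <- which(bi != bj)
      k <- length(dpos)
      if (k == 0) next
      path_syn <- numeric(0)
      path_ok <- logical(0)
      for (ord in perms[[as.character(k)]]) {
        cur <- bi
        syn <- 0
        valid <- TRUE
        for (p in dpos[ord]) {
          prev_aa <- aa[paste(cur, collapse = "")]
          cur[p] <- bj[p]
          cod <- paste(cur, collapse = "")
          if (aa[cod] == "*") { valid <- FALSE; break }
          if (aa[cod] == prev_aa) syn <- syn + 1
        }
        path_syn <- c(path_syn, if (valid) syn else NA_real_)
        path_ok <- c(path_ok, valid)
      }
      if (any(path_ok)) {
        msyn <- mean(path_syn[path_ok])
      } else {
        # recompute ignoring the stop exclusion
        msyn <- mean(vapply(perms[[as.character(k)]], function(ord) {
          cur <- bi
          syn <- 0
          for (p in dpos[ord]) {
            prev_aa <- aa[paste(cur, collapse = "")]
            cur[p] <- bj[p]
            if (aa[paste(cur, collapse = "")] == prev_aa) syn <- syn + 1
          }
          syn
        }, numeric(1)))
      }
      sd[i, j] <- msyn
      nd[i, j] <- k - msyn
    }
  }
  .pk_cache$diffs <- list(sd = sd, nd = nd)
  .pk_cache$diffs
}

.splitCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0)
    stop("sequence length not divisible by 3: ", nchar(x))
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

.translateCodons <- function(codons) unname(.codonAA()[codons])
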