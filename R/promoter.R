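#' Extract promoter regions
#'
#' Returns, for each gene, up to `length` bp immediately upstream of the gene:
#' 5' of the gene start on the plus strand, 3' of the gene end
#' reverse-complemented on the minus strand, so the sequence always reads
#' 5' to 3' towards the gene. Promoters are clipped at chromosome ends and
#' flagged when shorter than requested.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param genome named `DNAStringSet` (or character vector) of chromosome
#'   sequences.
#' @param length promoter length in bp (default 1000, the usual 1-kb window).
#' @param gene_ids genes to process (default all).
#' @return data.frame `gene_id`, `chromosome`, `start`, `end` (1-based
#'   inclusive genomic coordinates of the extracted window), `strand`,
#'   `clipped`, `seq`.
#' @export
extractPromoters <- function(annotation, genome, length = 1000,
                             gene_ids = NULL) {
  genome_chr <- stats::setNames(as.character(genome), names(genome))
  g <- annGenes(annotation)
  md <- S4Vectors::mcols(g)
  if (!is.null(gene_ids)) g <- g[md$ID %in% gene_ids]
  md <- S4Vectors::mcols(g)
  out <- vector("list", length(g))
  for (i in seq_along(g)) {
    chr <- as.character(GenomeInfoDb::seqnames(g[i]))
    if (!chr %in% names(genome_chr))
      stop("chromosome ", chr, " absent from genome")
    chr_len <- nchar(genome_chr[[chr]])
    strand <- as.character(BiocGenerics::strand(g[i]))
    if (strand == "+") {
      to <- BiocGenerics::start(g[i]) - 1L
      from <- max(1L, to - length + 1L)
    } else {
      from <- BiocGenerics::end(g[i]) + 1L
      to <- min(chr_len, from + length - 1L)
    }
    if (to < from) {
      seq <- ""
      from <- NA_integer_; to <- NA_integer_
      clipped <- TRUE
    } else {
      seq <- substr(genome_chr[[chr]], from, to)
      if (strand == "-") seq <- .revComp(seq)
      clipped <- nchar(seq) < length
    }
    out[[i]] <- data.frame(
      gene_id = md$ID[i], chromosome = chr, start = from, end = to,
      strand = strand, clipped = clipped, seq = seq,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# ---- JASPAR PFM I/O --------------------------------------------------------

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the JASPAR 2018 flavor: a `>ID name` header followed by four rows
#' `A [ 1 2 3 ]` ... `T [ ... ]` (brackets and row letters optional).
#'
#' @param path file path.
#' @param width_bounds allowed motif widths (default 6 to 50 positions).
#' @return list of PWM records: `motif_id`, `name`, `counts` (4 x width
#'   matrix, rows A/C/G/T).
#' @export
readJasparPfm <- function(path, width_bounds = c(6L, 50L)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records in ", path)
  out <- list()
  for (s in seq_along(starts)) {
    i <- starts[s]
    hdr <- sub("^>\\s*", "", lines[i])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else motif_id
    rows <- matrix(NA_real_, 4, 0)
    got <- list()
    for (k in 1:4) {
      ln <- i + k
      if (ln > length(lines) || grepl("^>", lines[ln]))
        stop("malformed matrix for ", motif_id, " at line ", ln,
             ": expected 4 count rows")
      row <- lines[ln]
      letter <- sub("^\\s*([ACGTacgt])\\b.*$", "\\1", row)
      if (!toupper(letter) %in% c("A", "C", "G", "T"))
        letter <- c("A", "C", "G", "T")[k]
      nums <- regmatches(row, gregexpr("-?[0-9]+\\.?[0-9]*", row))[[1]]
      vals <- suppressWarnings(as.numeric(nums))
      if (!length(vals) || anyNA(vals) || any(vals < 0))
        stop("malformed count row at line ", ln, " of ", path)
      got[[toupper(letter)]] <- vals
    }
    widths <- unique(vapply(got, base::length, integer(1)))
    if (length(widths) != 1)
      stop("rows of ", motif_id, " differ in width")
    counts <- rbind(A = got$A, C = got$C, G = got$G, T = got$T)
    if (widths < width_bounds[1] || widths > width_bounds[2])
      stop("motif ", motif_id, " width ", widths, " outside [",
           width_bounds[1], ", ", width_bounds[2], "]")
    out[[motif_id]] <- list(motif_id = motif_id, name = name, counts = counts)
  }
  out
}

#' Write PFMs in JASPAR text format
#'
#' @param pwms list of PWM records (as from [readJasparPfm()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeJasparPfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$name), con)
    for (r in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", r,
                         paste(format(p$counts[r, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Convert a PFM to a log-odds scoring matrix
#'
#' Counts are converted to per-position probabilities with a pseudocount and
#' scored against a background distribution (default uniform):
#' `log2((count + pseudocount) / (column_total + 4 * pseudocount) / bg)`.
#'
#' @param pwm a PWM record (list with `counts`) or a bare 4 x width matrix.
#' @param background nucleotide background probabilities (A, C, G, T).
#' @param pseudocount added to every cell (default 0.5).
#' @return 4 x width numeric matrix of log2 odds (rows A/C/G/T).
#' @export
pfmToLogOdds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.5) {
  counts <- if (is.list(pwm)) pwm$counts else pwm
  if (!is.matrix(counts) || nrow(counts) != 4)
    stop("counts must be a 4-row matrix")
  if (abs(sum(background) - 1) > 1e-8 || any(background <= 0))
    stop("background must be positive probabilities summing to 1")
  tot <- colSums(counts) + 4 * pseudocount
  prob <- sweep(counts + pseudocount, 2, tot, "/")
  lo <- log2(prob / background)
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

.NT_INDEX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# score every window of seq against a 4 x w log-odds matrix; windows with
# non-ACGT characters score -Inf
.scanStrand <- function(mat, seq) {
  w <- ncol(mat)
  L <- nchar(seq)
  if (L < w) return(numeric(0))
  idx <- .NT_INDEX[strsplit(toupper(seq), "")[[1]]]
  nwin <- L - w + 1L
  scores <- numeric(nwin)
  ok <- rep(TRUE, nwin)
  for (j in seq_len(w)) {
    v <- idx[j:(j + nwin - 1L)]
    miss <- is.na(v)
    ok <- ok & !miss
    v[miss] <- 1L
    scores <- scores + mat[cbind(v, j)]
  }
  scores[!ok] <- -Inf
  scores
}

#' Scan a promoter with a PWM
#'
#' Scores every window on both strands of the promoter; a window is a hit when
#' its score reaches `threshold_fraction` of the maximum attainable score of
#' the matrix. Offsets are 0-based on the supplied promoter sequence.
#'
#' @param scoring_matrix 4 x width log-odds matrix from [pfmToLogOdds()].
#' @param promoter promoter sequence (character).
#' @param threshold_fraction fraction of the maximal score required (default
#'   0.8).
#' @return data.frame `offset`, `strand`, `score`; zero rows (with a warning)
#'   when the promoter is shorter than the motif.
#' @export
scanPromoter <- function(scoring_matrix, promoter, threshold_fraction = 0.8) {
  w <- ncol(scoring_matrix)
  promoter <- as.character(promoter)
  if (nchar(promoter) < w) {
    warning("promoter shorter than motif: no windows scanned")
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  max_score <- sum(apply(scoring_matrix, 2, max))
  thr <- threshold_fraction * max_score
  fwd <- .scanStrand(scoring_matrix, promoter)
  rev <- .scanStrand(scoring_matrix, .revComp(promoter))
  L <- nchar(promoter)
  fi <- which(fwd >= thr); ri <- which(rev >= thr)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(offset = L - w + 1L - ri, strand = rep("-", length(ri)),
               score = rev[ri])
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more annotated/hit members in a foreground
#' draw of size `n` from a background of `N` with `K` positives.
#'
#' @param k foreground positives observed.
#' @param N background size.
#' @param K background positives.
#' @param n foreground size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
hypergeomTail <- function(k, N, K, n) {
  stopifnot(k >= 0, N >= 0, K >= 0, n >= 0, K <= N, n <= N,
            all(k <= pmin(n, K)))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-family motif enrichment in promoters
#'
#' For each PWM, counts promoters with at least one hit in the family
#' foreground (`k` of `n`) and in the background (`K` of `N`, foreground
#' included), computes the upper-tail hypergeometric p-value and
#' Benjamini-Hochberg q across motifs, and flags motifs passing both cutoffs.
#'
#' @param foreground character vector (or single-column of
#'   [extractPromoters()] output) of foreground promoter sequences.
#' @param background promoter sequences of the background; must contain the
#'   foreground (checked by name when both are named).
#' @param pwms list of PWM records (see [readJasparPfm()]).
#' @param threshold_fraction PWM hit threshold, see [scanPromoter()].
#' @param p_cutoff,q_cutoff strict cutoffs for enrichment (default 1e-2 each).
#' @param pseudocount,background_freq passed to [pfmToLogOdds()].
#' @return data.frame `motif_id`, `k`, `n`, `K`, `N`, `p`, `q`, `enriched`.
#' @export
familyMotifEnrichment <- function(foreground, background, pwms,
                                  threshold_fraction = 0.8,
                                  p_cutoff = 1e-2, q_cutoff = 1e-2,
                                  pseudocount = 0.5,
                                  background_freq = rep(0.25, 4)) {
  fg <- stats::setNames(as.character(foreground), names(foreground))
  bg <- stats::setNames(as.character(background), names(background))
  if (!length(fg)) stop("empty foreground")
  if (!is.null(names(fg)) && !is.null(names(bg)) &&
      !all(names(fg) %in% names(bg)))
    stop("foreground must be a subset of the background")
  res <- lapply(pwms, function(p) {
    mat <- pfmToLogOdds(p, background = background_freq,
                        pseudocount = pseudocount)
    hit <- function(seqs) vapply(seqs, function(s)
      nrow(suppressWarnings(scanPromoter(mat, s, threshold_fraction))) > 0,
      logical(1))
    bg_hit <- hit(bg)
    fg_hit <- if (!is.null(names(fg)) && !is.null(names(bg)))
      bg_hit[names(fg)] else hit(fg)
    k <- sum(fg_hit); K <- sum(bg_hit)
    data.frame(motif_id = p$motif_id, k = k, n = length(fg), K = K,
               N = length(bg),
               p = hypergeomTail(k, length(bg), K, length(fg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- bhFdr(out$p)
  out$enriched <- out$p < p_cutoff & out$q < q_cutoff
  out
}
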