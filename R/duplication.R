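#' Gene ranks along chromosomes
#'
#' Assigns every annotated gene its 1-based index among all genes of its
#' chromosome ordered by ascending start coordinate (ties broken by end
#' coordinate, then id). Ranks are computed over all genes, not only kinases:
#' rank gaps define tandem and proximal duplicates.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return data.frame `gene_id`, `chromosome`, `start`, `rank`.
#' @export
geneRanks <- function(annotation) {
  g <- annGenes(annotation)
  ids <- S4Vectors::mcols(g)$ID
  if (anyDuplicated(ids)) stop("duplicate gene id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- data.frame(
    gene_id = ids,
    chromosome = as.character(GenomeInfoDb::seqnames(g)),
    start = BiocGenerics::start(g),
    end = BiocGenerics::end(g),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chromosome, df$start, df$end, df$gene_id), , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$chromosome,
                        FUN = seq_along)
  rownames(df) <- NULL
  df[, c("gene_id", "chromosome", "start", "rank")]
}

.duplicationPriority <- c(singleton = 0, dispersed = 1, proximal = 2,
                          tandem = 3, wgd_segmental = 4)

#' Classify gene duplication origin
#'
#' MCScanX-style classifier. All genes start as singletons; genes with any
#' retained similarity hit become dispersed; pairs on the same chromosome with
#' rank gap between 2 and `proximal_max_gap` upgrade to proximal; rank gap
#' exactly 1 upgrades to tandem; anchor genes of collinear blocks upgrade to
#' WGD/segmental. Each gene receives the highest-priority label it attains
#' (wgd_segmental > tandem > proximal > dispersed > singleton). Tandem and
#' proximal upgrades require the same chromosome; cross-chromosome hits can
#' only yield dispersed. Hits are symmetrized, self-hits dropped, and each
#' gene's similarity partners restricted to its `top_n_hits` best by bit score
#' (a hit is retained if it survives the cut at either end), mirroring common
#' MCScanX pre-filtering.
#'
#' @param ranks data.frame from [geneRanks()].
#' @param hits data.frame of similarity hits with columns `query`, `subject`
#'   and optionally `bit_score`.
#' @param blocks result of [findCollinearBlocks()] (or `NULL` for none): its
#'   `anchors` gene ids mark WGD/segmental genes.
#' @param proximal_max_gap largest rank gap still called proximal (default 19,
#'   i.e. a rank difference below 20).
#' @param top_n_hits per-gene hit cap by descending bit score (default 5);
#'   `Inf` disables the cap.
#' @return data.frame `gene_id`, `class`, one row per ranked gene.
#' @export
classifyDuplicates <- function(ranks, hits, blocks = NULL,
                               proximal_max_gap = 19, top_n_hits = 5) {
  cls <- stats::setNames(rep("singleton", nrow(ranks)), ranks$gene_id)
  chrom <- stats::setNames(ranks$chromosome, ranks$gene_id)
  rnk <- stats::setNames(ranks$rank, ranks$gene_id)

  if (nrow(hits)) {
    unknown <- setdiff(unique(c(hits$query, hits$subject)), ranks$gene_id)
    if (length(unknown))
      stop("hit references unranked gene: ", paste(unknown, collapse = ", "))
    h <- hits[hits$query != hits$subject, , drop = FALSE]
    if (is.null(h$bit_score)) h$bit_score <- 0
    # canonical unordered pairs, best score per pair
    a <- pmin(h$query, h$subject); b <- pmax(h$query, h$subject)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -h$bit_score)
    h <- data.frame(a = a[ord], b = b[ord], bit_score = h$bit_score[ord],
                    stringsAsFactors = FALSE)[!duplicated(key[ord]), , drop = FALSE]
    # per-gene partner lists: each gene is classified by its own top-N hits
    long <- rbind(data.frame(gene = h$a, partner = h$b, bit_score = h$bit_score,
                             stringsAsFactors = FALSE),
                  data.frame(gene = h$b, partner = h$a, bit_score = h$bit_score,
                             stringsAsFactors = FALSE))
    if (is.finite(top_n_hits) && nrow(long)) {
      long <- long[order(long$gene, -long$bit_score, long$partner), ,
                   drop = FALSE]
      long$rank_in_gene <- stats::ave(seq_len(nrow(long)), long$gene,
                                      FUN = seq_along)
      long <- long[long$rank_in_gene <= top_n_hits, , drop = FALSE]
    }
    upgrade <- function(gene, to) {
      if (.duplicationPriority[to] > .duplicationPriority[cls[gene]])
        cls[gene] <<- to
    }
    for (i in seq_len(nrow(long))) {
      g <- long$gene[i]; p <- long$partner[i]
      upgrade(g, "dispersed")
      if (chrom[g] == chrom[p]) {
        gap <- abs(rnk[g] - rnk[p])
        if (gap == 1) upgrade(g, "tandem")
        else if (gap >= 2 && gap <= proximal_max_gap) upgrade(g, "proximal")
      }
    }
  }
  if (!is.null(blocks) && !is.null(blocks$anchors) && nrow(blocks$anchors)) {
    anchor_genes <- intersect(
      unique(c(blocks$anchors$geneA, blocks$anchors$geneB)), names(cls))
    cls[anchor_genes] <- "wgd_segmental"
  }
  data.frame(gene_id = ranks$gene_id, class = unname(cls[ranks$gene_id]),
             stringsAsFactors = FALSE)
}

# longest strictly-monotone chain (DP) among matches sorted by rankA;
# direction +1: rankB increasing, -1: decreasing; gaps capped on both sides
.longestChain <- function(ra, rb, direction, max_rank_gap) {
  n <- length(ra)
  best_len <- integer(n)
  prev <- integer(n)
  ord <- order(ra, rb * direction)
  best_len[ord] <- 1L
  prev[ord] <- 0L
  for (ii in seq_len(n)) {
    i <- ord[ii]
    for (jj in seq_len(ii - 1L)) {
      j <- ord[jj]
      if (ra[j] >= ra[i]) next
      if (ra[i] - ra[j] > max_rank_gap) next
      db <- (rb[i] - rb[j]) * direction
      if (db <= 0 || db > max_rank_gap) next
      if (best_len[j] + 1L > best_len[i]) {
        best_len[i] <- best_len[j] + 1L
        prev[i] <- j
      }
    }
  }
  if (!n) return(integer(0))
  end <- which(best_len == max(best_len))
  end <- end[order(ra[end], rb[end])][1]
  chain <- integer(0)
  while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
  chain
}

#' Find collinear (syntenic) blocks
#'
#' Within each chromosome pair, chains matches whose gene ranks are strictly
#' monotone on both sides (B-side increasing or decreasing) with a per-step
#' rank gap of at most `max_rank_gap` on each side. Maximal chains are
#' extracted greedily by descending size (each match used once) and reported
#' when they contain at least `min_block_size` anchor pairs.
#'
#' @param pairs data.frame with columns `geneA`, `chromA`, `rankA`, `geneB`,
#'   `chromB`, `rankB`.
#' @param min_block_size smallest reported block (default 5 anchor pairs).
#' @param max_rank_gap largest allowed per-step rank gap (default 25).
#' @return list with `blocks` (data.frame: `block_id`, `chromA`, `chromB`,
#'   `size`, `orientation`) and `anchors` (data.frame: `block_id`, `position`,
#'   `geneA`, `rankA`, `geneB`, `rankB`).
#' @export
findCollinearBlocks <- function(pairs, min_block_size = 5, max_rank_gap = 25) {
  empty <- list(
    blocks = data.frame(block_id = integer(0), chromA = character(0),
                        chromB = character(0), size = integer(0),
                        orientation = character(0), stringsAsFactors = FALSE),
    anchors = data.frame(block_id = integer(0), position = integer(0),
                         geneA = character(0), rankA = integer(0),
                         geneB = character(0), rankB = integer(0),
                         stringsAsFactors = FALSE))
  if (!nrow(pairs)) return(empty)
  pairs <- pairs[order(pairs$chromA, pairs$chromB, pairs$rankA, pairs$rankB), ,
                 drop = FALSE]
  blocks <- list(); anchors <- list(); bid <- 0L
  for (grp in split(seq_len(nrow(pairs)),
                    paste(pairs$chromA, pairs$chromB, sep = "\r"))) {
    avail <- rep(TRUE, length(grp))
    sub <- pairs[grp, , drop = FALSE]
    repeat {
      idx <- which(avail)
      if (!length(idx)) break
      ch_up <- .longestChain(sub$rankA[idx], sub$rankB[idx], 1L, max_rank_gap)
      ch_dn <- .longestChain(sub$rankA[idx], sub$rankB[idx], -1L, max_rank_gap)
      if (length(ch_up) >= length(ch_dn)) {
        chain <- idx[ch_up]; orientation <- "same"
      } else {
        chain <- idx[ch_dn]; orientation <- "inverted"
      }
      if (length(chain) < min_block_size) break
      bid <- bid + 1L
      blocks[[bid]] <- data.frame(
        block_id = bid, chromA = sub$chromA[1], chromB = sub$chromB[1],
        size = length(chain), orientation = orientation,
        stringsAsFactors = FALSE)
      anchors[[bid]] <- data.frame(
        block_id = bid, position = seq_along(chain),
        geneA = sub$geneA[chain], rankA = sub$rankA[chain],
        geneB = sub$geneB[chain], rankB = sub$rankB[chain],
        stringsAsFactors = FALSE)
      avail[chain] <- FALSE
    }
  }
  if (!length(blocks)) return(empty)
  blocks <- do.call(rbind, blocks)
  anchors <- do.call(rbind, anchors)
  # deterministic block numbering: by size desc, then chromosomes, then genes
  ord <- order(-blocks$size, blocks$chromA, blocks$chromB,
               vapply(split(anchors$geneA, anchors$block_id), `[`, "", 1)[
                 as.character(blocks$block_id)])
  renum <- stats::setNames(seq_along(ord), blocks$block_id[ord])
  blocks <- blocks[ord, , drop = FALSE]
  blocks$block_id <- seq_len(nrow(blocks))
  anchors$block_id <- as.integer(renum[as.character(anchors$block_id)])
  anchors <- anchors[order(anchors$block_id, anchors$position), , drop = FALSE]
  rownames(blocks) <- rownames(anchors) <- NULL
  list(blocks = blocks, anchors = anchors)
}

#' Dual-genome synteny
#'
#' Computes gene ranks for two annotations, chains the inter-genome similarity
#' hits into collinear blocks, and reports a dot-plot table of anchor
#' coordinates plus the number of blocks anchored by at least one kinase
#' locus.
#'
#' @param annotA,annotB [GenomeAnnotation-class] objects for the two genomes.
#' @param hits data.frame with columns `query` (genome A gene), `subject`
#'   (genome B gene) and optionally `bit_score`.
#' @param kinase_ids character vector of kinase locus ids (either genome).
#' @param min_block_size,max_rank_gap passed to [findCollinearBlocks()].
#' @return list with `blocks`, `anchors`, `dotplot` (data.frame `block_id`,
#'   `geneA`, `chrA`, `startA`, `geneB`, `chrB`, `startB`) and
#'   `n_kinase_blocks`.
#' @export
dualSynteny <- function(annotA, annotB, hits, kinase_ids = character(0),
                        min_block_size = 5, max_rank_gap = 25) {
  if (!nrow(hits)) {
    warning("empty hit table: no syntenic blocks")
    res <- findCollinearBlocks(data.frame(geneA = character(0),
                                          chromA = character(0),
                                          rankA = integer(0),
                                          geneB = character(0),
                                          chromB = character(0),
                                          rankB = integer(0)))
    return(c(res, list(dotplot = data.frame(), n_kinase_blocks = 0L)))
  }
  rA <- geneRanks(annotA)
  rB <- geneRanks(annotB)
  ia <- match(hits$query, rA$gene_id)
  ib <- match(hits$subject, rB$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("hit references gene absent from an annotation")
  pairs <- data.frame(
    geneA = hits$query, chromA = rA$chromosome[ia], rankA = rA$rank[ia],
    geneB = hits$subject, chromB = rB$chromosome[ib], rankB = rB$rank[ib],
    stringsAsFactors = FALSE)
  res <- findCollinearBlocks(pairs, min_block_size, max_rank_gap)
  an <- res$anchors
  dot <- data.frame(
    block_id = an$block_id,
    geneA = an$geneA, chrA = rA$chromosome[match(an$geneA, rA$gene_id)],
    startA = rA$start[match(an$geneA, rA$gene_id)],
    geneB = an$geneB, chrB = rB$chromosome[match(an$geneB, rB$gene_id)],
    startB = rB$start[match(an$geneB, rB$gene_id)],
    stringsAsFactors = FALSE)
  kin <- vapply(split(an$geneA %in% kinase_ids | an$geneB %in% kinase_ids,
                      an$block_id), any, logical(1))
  c(res, list(dotplot = dot, n_kinase_blocks = sum(kin)))
}
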