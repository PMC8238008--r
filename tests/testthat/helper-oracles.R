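# Independent brute-force oracles used across test files. These deliberately
# avoid the package's cached lookup tables and dynamic programming: everything
# is recomputed per call by direct enumeration.

NT <- c("A", "C", "G", "T")
GC_TABLE <- Biostrings::GENETIC_CODE

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# per-codon synonymous site fraction by explicit enumeration
oracle_syn_sites <- function(cod) {
  s <- 0
  for (pos in 1:3) {
    for (b in NT) {
      if (b == substr(cod, pos, pos)) next
      m <- cod
      substr(m, pos, pos) <- b
      if (GC_TABLE[[m]] != "*" && GC_TABLE[[m]] == GC_TABLE[[cod]])
        s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (syn, nonsyn) differences between two codons
oracle_codon_diffs <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  dpos <- which(av != bv)
  if (!length(dpos)) return(c(0, 0))
  syn_per_path <- c(); valid <- c()
  for (ord in perms_of(dpos)) {
    cur <- av; syn <- 0; ok <- TRUE
    for (p in ord) {
      before <- GC_TABLE[[paste(cur, collapse = "")]]
      cur[p] <- bv[p]
      after <- GC_TABLE[[paste(cur, collapse = "")]]
      if (after == "*") { ok <- FALSE; break }
      if (after == before) syn <- syn + 1
    }
    valid <- c(valid, ok)
    syn_per_path <- c(syn_per_path, if (ok) syn else NA)
  }
  msyn <- if (any(valid)) mean(syn_per_path[valid]) else {
    # all pathways blocked: unweighted average ignoring stops
    mean(vapply(perms_of(dpos), function(ord) {
      cur <- av; syn <- 0
      for (p in ord) {
        before <- GC_TABLE[[paste(cur, collapse = "")]]
        cur[p] <- bv[p]
        if (GC_TABLE[[paste(cur, collapse = "")]] == before) syn <- syn + 1
      }
      syn
    }, numeric(1)))
  }
  c(msyn, length(dpos) - msyn)
}

oracle_ng_counts <- function(codons1, codons2) {
  S <- (sum(vapply(codons1, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons2, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons1) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(codons1)) {
    d <- oracle_codon_diffs(codons1[i], codons2[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  c(S = S, N = N, Sd = Sd, Nd = Nd)
}

random_codons <- function(n) {
  pool <- names(GC_TABLE)[GC_TABLE != "*"]
  sample(pool, n, replace = TRUE)
}

# upper-tail hypergeometric by direct enumeration
oracle_hyper_tail <- function(k, N, K, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# exhaustive duplication-rule evaluator (no hit-count cap)
oracle_classify <- function(ranks, hits, block_genes = character(0),
                            proximal_max_gap = 19) {
  pri <- c(singleton = 0, dispersed = 1, proximal = 2, tandem = 3,
           wgd_segmental = 4)
  chrom <- setNames(ranks$chromosome, ranks$gene_id)
  rnk <- setNames(ranks$rank, ranks$gene_id)
  best <- setNames(rep("singleton", nrow(ranks)), ranks$gene_id)
  raise <- function(g, cls) {
    if (pri[cls] > pri[best[g]]) best[g] <<- cls
  }
  for (i in seq_len(nrow(hits))) {
    g1 <- hits$query[i]; g2 <- hits$subject[i]
    if (g1 == g2) next
    for (g in c(g1, g2)) raise(g, "dispersed")
    if (chrom[g1] == chrom[g2]) {
      gap <- abs(rnk[g1] - rnk[g2])
      if (gap == 1) for (g in c(g1, g2)) raise(g, "tandem")
      if (gap >= 2 && gap <= proximal_max_gap)
        for (g in c(g1, g2)) raise(g, "proximal")
    }
  }
  for (g in intersect(block_genes, names(best))) raise(g, "wgd_segmental")
  best
}

# longest strictly monotone chain by exhaustive recursion (small inputs only)
oracle_longest_chain <- function(ra, rb, direction, max_rank_gap) {
  n <- length(ra)
  if (!n) return(0L)
  memo <- new.env()
  ext <- function(i) { # longest chain starting at i
    key <- as.character(i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 1L
    for (j in seq_len(n)) {
      if (ra[j] <= ra[i] || ra[j] - ra[i] > max_rank_gap) next
      db <- (rb[j] - rb[i]) * direction
      if (db <= 0 || db > max_rank_gap) next
      best <- max(best, 1L + ext(j))
    }
    memo[[key]] <- best
    best
  }
  max(vapply(seq_len(n), ext, integer(1)))
}

# naive PWM window scorer
oracle_scan <- function(mat, seq, threshold_fraction = 0.8) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  w <- ncol(mat)
  max_score <- sum(apply(mat, 2, max))
  out <- data.frame(offset = integer(0), strand = character(0),
                    score = numeric(0))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    L <- nchar(s)
    for (i in seq_len(L - w + 1)) {
      sc <- 0
      for (j in seq_len(w)) {
        b <- substr(s, i + j - 1, i + j - 1)
        sc <- sc + if (b %in% rownames(mat)) mat[b, j] else -Inf
      }
      if (sc >= threshold_fraction * max_score) {
        off <- if (strand == "+") i - 1L else L - w + 1L - i
        out <- rbind(out, data.frame(offset = off, strand = strand,
                                     score = sc))
      }
    }
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

# shared simulated-genome bank: generating a genome is the expensive step, so
# tests that only read different aspects of the same seeds share them
.sim_bank <- new.env()
bank_sim <- function(seed, config = NULL) {
  key <- as.character(seed)
  if (is.null(.sim_bank[[key]])) {
    cfg <- if (is.null(config)) simConfig(seed = seed) else config
    .sim_bank[[key]] <- genGenome(cfg)
  }
  .sim_bank[[key]]
}

# catalog + similarity-derived collinearity pairs for a simulated genome
sim_pairs_table <- function(sim) {
  ranks <- geneRanks(sim$annotation)
  ia <- match(sim$similarity$query, ranks$gene_id)
  ib <- match(sim$similarity$subject, ranks$gene_id)
  data.frame(geneA = sim$similarity$query, chromA = ranks$chromosome[ia],
             rankA = ranks$rank[ia],
             geneB = sim$similarity$subject, chromB = ranks$chromosome[ib],
             rankB = ranks$rank[ib], stringsAsFactors = FALSE)
}

sim_catalog <- function(sim) {
  cand <- identifyKinases(sim$domain_hits)
  fams <- assignFamilies(
    sim$domain_hits[!sim$domain_hits$model_id %in% KINASE_MODELS, ])
  buildCatalog(cand, fams)
}
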