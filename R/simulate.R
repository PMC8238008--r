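#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class]. The defaults describe a compact
#' two-chromosome genome with four planted kinase families, tandem/proximal/
#' dispersed duplicate pairs, one six-pair inter-chromosomal collinear block,
#' a promoter motif planted at 80% foreground vs 5% background frequency, and
#' an expression plan with up-regulated members in two families.
#'
#' @param n_chromosomes,chrom_length,n_genes genome dimensions.
#' @param family_sizes named integer vector of kinase family sizes.
#' @param kinase_cds_codons shared codon length of kinase founder CDS.
#' @param duplication_plan data.frame (`class`, `count`): planted pairs.
#' @param collinear_block_plan data.frame (`chromA`, `chromB`, `n_pairs`).
#' @param promoter_motif_plan data.frame (`family`, `motif_id`, `fg_fraction`,
#'   `bg_fraction`).
#' @param de_plan data.frame (`family`, `n_up`, `mean_log2FC`).
#' @param omega_plan numeric vector of selection intensities for simulated
#'   CDS pairs.
#' @param divergence nucleotide divergence between duplicate copies.
#' @param duplication_omega selection intensity for duplicate/family copies.
#' @param seed integer seed.
#' @return a `SimConfig`.
#' @export
simConfig <- function(n_chromosomes = 2L,
                      chrom_length = 260000L,
                      n_genes = 60L,
                      family_sizes = c("RLK-Pelle_DLSV" = 6L,
                                       "CAMK_CDPK" = 5L,
                                       "CMGC_CDK-CRK7-CDK9" = 4L,
                                       "STE_STE11" = 3L),
                      kinase_cds_codons = 240L,
                      duplication_plan = data.frame(
                        class = c("tandem", "proximal", "dispersed"),
                        count = c(3L, 3L, 3L)),
                      collinear_block_plan = data.frame(
                        chromA = 1L, chromB = 2L, n_pairs = 6L),
                      promoter_motif_plan = data.frame(
                        family = "RLK-Pelle_DLSV", motif_id = "SYNM01",
                        fg_fraction = 0.8, bg_fraction = 0.05),
                      de_plan = data.frame(
                        family = c("RLK-Pelle_DLSV", "CAMK_CDPK"),
                        n_up = c(4L, 3L), mean_log2FC = c(3, 2.5)),
                      omega_plan = c(0.2, 1, 5),
                      divergence = 0.02,
                      duplication_omega = 0.2,
                      seed = 1L) {
  new("SimConfig",
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length),
      n_genes = as.integer(n_genes),
      family_sizes = stats::setNames(as.integer(family_sizes),
                                     names(family_sizes)),
      kinase_cds_codons = as.integer(kinase_cds_codons),
      duplication_plan = duplication_plan,
      collinear_block_plan = collinear_block_plan,
      promoter_motif_plan = promoter_motif_plan,
      de_plan = de_plan,
      omega_plan = as.numeric(omega_plan),
      divergence = divergence,
      duplication_omega = as.numeric(duplication_omega),
      seed = as.integer(seed))
}

# built-in synthetic position frequency matrices (JASPAR-expressible);
# strongly peaked columns so the planted consensus scores near the maximum
.simMotifs <- function() {
  mk <- function(id, name, consensus) {
    w <- nchar(consensus)
    counts <- matrix(5, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- strsplit(consensus, "")[[1]]
    for (j in seq_len(w)) counts[cons[j], j] <- 85
    list(motif_id = id, name = name, counts = counts, consensus = consensus)
  }
  list(SYNM01 = mk("SYNM01", "synthetic-bZIP-like", "TGACGTCAGC"),
       SYNM02 = mk("SYNM02", "synthetic-C2H2-like", "GGCGGCTATA"))
}

.randCodons <- function(n) {
  aa <- .codonAA()
  pool <- names(aa)[aa != "*"]
  sample(pool, n, replace = TRUE)
}

# diverge a CDS by `rate * length` accepted substitutions under a selection
# intensity (defaults mirror retained duplicates: mostly purifying)
.divergeCds <- function(codons, rate, omega) {
  if (rate <= 0) return(codons)
  s <- paste(codons, collapse = "")
  n <- max(1L, round(rate * nchar(s)))
  .splitCodons(evolveCdsPair(s, omega, n)$cds)
}

#' Evolve a coding sequence under a selection intensity
#'
#' Proposes uniform random single-nucleotide substitutions and accepts them
#' with probabilities in the ratio 1 : omega (synonymous : nonsynonymous):
#' for `omega <= 1` synonymous proposals are always accepted and nonsynonymous
#' ones with probability `omega`; for `omega > 1` nonsynonymous proposals are
#' always accepted and synonymous ones with probability `1/omega`, so
#' diversifying regimes are representable. Proposals creating a stop codon are
#' rejected outright. Stops after `n_events` accepted substitutions. The
#' realized substitution log is the ground truth for Ka/Ks parameter-recovery
#' studies.
#'
#' @param cds coding sequence (length divisible by 3, no stop codons).
#' @param omega acceptance probability of nonsynonymous proposals (>= 0).
#' @param n_events number of accepted substitutions.
#' @param seed optional integer seed.
#' @return list with `cds` (derived sequence) and `log` (data.frame `event`,
#'   `position`, `from`, `to`, `type` of each accepted change, where `type`
#'   is `"synonymous"` or `"nonsynonymous"`).
#' @export
evolveCdsPair <- function(cds, omega, n_events, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (omega < 0) stop("omega must be >= 0")
  codons <- .splitCodons(cds)
  aa <- .codonAA()
  if (any(aa[codons] == "*")) stop("CDS contains a stop codon")
  seq <- strsplit(toupper(as.character(cds)), "")[[1]]
  nt <- c("A", "C", "G", "T")
  if (!all(seq %in% nt)) stop("CDS contains non-ACGT characters")
  log <- data.frame(event = integer(0), position = integer(0),
                    from = character(0), to = character(0),
                    type = character(0), stringsAsFactors = FALSE)
  accepted <- 0L
  proposals <- 0L
  max_proposals <- 1000L * max(1L, n_events)
  while (accepted < n_events) {
    proposals <- proposals + 1L
    if (proposals > max_proposals)
      stop("proposal budget exhausted; omega may be too small for the ",
           "requested number of events")
    p <- sample.int(length(seq), 1)
    b <- sample(setdiff(nt, seq[p]), 1)
    ci <- (p - 1) %/% 3
    cod <- seq[(ci * 3 + 1):(ci * 3 + 3)]
    old_aa <- aa[paste(cod, collapse = "")]
    cod[(p - 1) %% 3 + 1] <- b
    new_aa <- aa[paste(cod, collapse = "")]
    if (new_aa == "*") next
    syn <- new_aa == old_aa
    p_accept <- if (syn) min(1, 1 / max(omega, .Machine$double.eps))
                else min(1, omega)
    if (p_accept < 1 && stats::runif(1) >= p_accept) next
    accepted <- accepted + 1L
    log <- rbind(log, data.frame(
      event = accepted, position = p, from = seq[p], to = b,
      type = if (syn) "synonymous" else "nonsynonymous",
      stringsAsFactors = FALSE))
    seq[p] <- b
  }
  list(cds = paste(seq, collapse = ""), log = log)
}

# single gene model on its coding strand; returns feature rows (gene-local
# pre-mRNA coordinates), the locus sequence, and the truth feature row
.buildGeneModel <- function(cds_body, u5, u3, n_exons, intron_lens) {
  cds <- paste0(cds_body, "TAA")
  L <- nchar(cds)
  k <- n_exons
  if (k > 1) {
    cuts <- round(seq_len(k - 1) * L / k +
                    stats::runif(k - 1, -min(15, L / (4 * k)),
                                 min(15, L / (4 * k))))
    cuts <- pmin(pmax(cuts, seq_len(k - 1) * 3), L - 3 * (k - seq_len(k - 1)))
    chunks <- diff(c(0L, sort(cuts), L))
  } else chunks <- L
  stopifnot(all(chunks >= 1))
  mature_exons <- chunks
  mature_exons[1] <- mature_exons[1] + u5
  mature_exons[k] <- mature_exons[k] + u3
  # pre-mRNA coordinates (coding strand)
  es <- integer(k); ee <- integer(k)
  pos <- 1L
  for (j in seq_len(k)) {
    es[j] <- pos
    ee[j] <- pos + mature_exons[j] - 1L
    pos <- ee[j] + 1L + if (j < k) intron_lens[j] else 0L
  }
  M <- ee[k]
  cds_s <- integer(k); cds_e <- integer(k)
  for (j in seq_len(k)) {
    cds_s[j] <- if (j == 1) es[1] + u5 else es[j]
    cds_e[j] <- cds_s[j] + chunks[j] - 1L
  }
  introns <- if (k > 1) vapply(intron_lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1)) else character(0)
  u5seq <- paste(sample(c("A", "C", "G", "T"), u5, replace = TRUE),
                 collapse = "")
  u3seq <- paste(sample(c("A", "C", "G", "T"), u3, replace = TRUE),
                 collapse = "")
  mature <- paste0(u5seq, cds, u3seq)
  # interleave mature exon pieces with introns
  pieces <- character(0)
  off <- 0L
  for (j in seq_len(k)) {
    pieces <- c(pieces, substr(mature, off + 1L, off + mature_exons[j]))
    off <- off + mature_exons[j]
    if (j < k) pieces <- c(pieces, introns[j])
  }
  locus_seq <- paste(pieces, collapse = "")
  stopifnot(nchar(locus_seq) == M)
  list(es = es, ee = ee, cds_s = cds_s, cds_e = cds_e,
       u5 = u5, u3 = u3, M = M, locus_seq = locus_seq,
       mature_len = sum(mature_exons), cds_len = L,
       intron_total = M - sum(mature_exons), n_exons = k)
}

#' Generate a synthetic annotated genome with planted ground truth
#'
#' Builds a multi-chromosome genome of strand-aware intron/exon/UTR gene
#' models with: planted kinase families (low within-family divergence and
#' matching domain/family-HMM hit rows), planted duplicate pairs of each
#' requested class (tandem: adjacent gene ranks; proximal: rank gap 2-19;
#' dispersed: different chromosomes; WGD/segmental: members of planted
#' collinear chains), a similarity hit for every planted pair, planted
#' promoter motif occurrences, and CDS pairs evolved under the configured
#' selection intensities. Gene models never overlap and leave at least 1 kb of
#' intergenic space, so 1-kb promoters are unambiguous. All outputs are
#' deterministic under the config seed.
#'
#' @param config a [SimConfig-class].
#' @return list with `annotation` ([GenomeAnnotation-class]), `genome`
#'   (`DNAStringSet`), `proteins` (`AAStringSet`, named by gene), `cds`
#'   (`DNAStringSet`, named by gene, trailing stop included), `domain_hits`,
#'   `similarity` (data.frames), `pwms` (planted motif PFMs), `kaks_pairs`
#'   (list of evolved CDS pairs with their true omega), `truth` (list of truth
#'   tables) and `config`.
#' @export
genGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n_chr <- config@n_chromosomes
  n_genes <- config@n_genes
  per_chr <- diff(round(seq(0, n_genes, length.out = n_chr + 1)))
  chrom_names <- paste0("chr", seq_len(n_chr))

  slot_chr <- rep(seq_len(n_chr), per_chr)
  slot_idx <- unlist(lapply(per_chr, seq_len))
  n_slots <- length(slot_chr)
  gene_ids <- sprintf("sim%02dg%03d", slot_chr, slot_idx)
  free <- rep(TRUE, n_slots)
  slot_of <- function(chr, idx) which(slot_chr == chr & slot_idx == idx)

  # ---- planted collinear blocks (WGD/segmental anchors) --------------------
  block_plan <- config@collinear_block_plan
  dp <- config@duplication_plan
  extra_wgd <- dp[dp$class == "wgd_segmental", , drop = FALSE]
  if (nrow(extra_wgd)) {
    for (i in seq_len(nrow(extra_wgd))) {
      ab <- if (n_chr >= 2) c(1L, 2L) else c(1L, 1L)
      block_plan <- rbind(block_plan,
                          data.frame(chromA = ab[1], chromB = ab[2],
                                     n_pairs = extra_wgd$count[i]))
    }
  }
  shuffle <- function(x) x[sample.int(length(x))]
  pick_run <- function(chr, k) {
    idxs <- slot_idx[slot_chr == chr & free]
    if (length(idxs) < k) return(NULL)
    runs <- idxs[vapply(idxs, function(s)
      all((s:(s + k - 1)) %in% idxs), logical(1))]
    if (!length(runs)) return(NULL)
    start <- sample(runs, 1)
    start:(start + k - 1)
  }
  blocks_truth <- list()
  pair_units <- list() # each: list(a = slot, b = slot, class = ...)
  if (nrow(block_plan)) {
    for (i in seq_len(nrow(block_plan))) {
      k <- block_plan$n_pairs[i]
      ra <- pick_run(block_plan$chromA[i], k)
      if (!is.null(ra)) free[vapply(ra, slot_of, 1L, chr = block_plan$chromA[i])] <- FALSE
      rb <- pick_run(block_plan$chromB[i], k)
      if (is.null(ra) || is.null(rb))
        stop("plan infeasible: no free run of ", k, " consecutive gene slots ",
             "for collinear block ", i)
      free[vapply(rb, slot_of, 1L, chr = block_plan$chromB[i])] <- FALSE
      sa <- vapply(ra, slot_of, 1L, chr = block_plan$chromA[i])
      sb <- vapply(rb, slot_of, 1L, chr = block_plan$chromB[i])
      blocks_truth[[i]] <- data.frame(
        block_id = i, position = seq_len(k),
        geneA = gene_ids[sa], geneB = gene_ids[sb],
        chromA = block_plan$chromA[i], chromB = block_plan$chromB[i],
        rankA = ra, rankB = rb,
        stringsAsFactors = FALSE)
      for (j in seq_len(k))
        pair_units[[length(pair_units) + 1]] <-
          list(a = sa[j], b = sb[j], class = "wgd_segmental")
    }
  }

  # ---- tandem / proximal / dispersed pairs ---------------------------------
  place_pair <- function(class) {
    if (class == "tandem" || class == "proximal") {
      for (chr in sample(seq_len(n_chr))) {
        idxs <- sort(slot_idx[slot_chr == chr & free])
        gaps <- if (class == "tandem") 1L else shuffle(2:19)
        for (gap in gaps) {
          cand <- idxs[(idxs + gap) %in% idxs]
          if (length(cand)) {
            s <- sample(rep(cand, 2), 1) # rep() guards length-1 sample()
            return(c(slot_of(chr, s), slot_of(chr, s + gap)))
          }
        }
      }
      return(NULL)
    }
    # dispersed: different chromosomes when possible, else rank gap >= 20;
    # the pair must not be able to extend any planted collinear chain
    # (prepend/append with monotone ranks), or the block finder would
    # legitimately absorb it as an anchor
    extends_block <- function(c1, i1, c2, i2) {
      for (bt in blocks_truth) {
        ba <- bt$chromA[1]; bb <- bt$chromB[1]
        ra <- bt$rankA; rb <- bt$rankB
        cand <- if (c1 == ba && c2 == bb) c(i1, i2)
        else if (c2 == ba && c1 == bb) c(i2, i1)
        else next
        if ((cand[1] < min(ra) && cand[2] < min(rb)) ||
            (cand[1] > max(ra) && cand[2] > max(rb)))
          return(TRUE)
      }
      FALSE
    }
    if (n_chr >= 2) {
      for (attempt in 1:50) {
        chrs <- sample(seq_len(n_chr), 2)
        i1 <- slot_idx[slot_chr == chrs[1] & free]
        i2 <- slot_idx[slot_chr == chrs[2] & free]
        if (!length(i1) || !length(i2)) next
        s1 <- sample(rep(i1, 2), 1)
        s2 <- sample(rep(i2, 2), 1)
        if (extends_block(chrs[1], s1, chrs[2], s2)) next
        return(c(slot_of(chrs[1], s1), slot_of(chrs[2], s2)))
      }
      return(NULL)
    }
    idxs <- sort(slot_idx[slot_chr == 1 & free])
    cand <- idxs[(idxs + 20L) %in% idxs]
    if (!length(cand)) return(NULL)
    s <- sample(rep(cand, 2), 1)
    c(slot_of(1L, s), slot_of(1L, s + 20L))
  }
  for (i in seq_len(nrow(dp))) {
    cls <- dp$class[i]
    if (cls == "wgd_segmental") next
    for (j in seq_len(dp$count[i])) {
      pr <- place_pair(cls)
      if (is.null(pr))
        stop("plan infeasible: cannot place ", cls, " pair ", j,
             " (not enough free gene slots)")
      free[pr] <- FALSE
      pair_units[[length(pair_units) + 1]] <-
        list(a = pr[1], b = pr[2], class = cls)
    }
  }

  # ---- kinase family assignment over units ---------------------------------
  # families consume tandem/proximal pairs first (so tandem kinase pairs exist
  # for Ka/Ks work), then unplanted single slots
  fam_of <- rep(NA_character_, n_slots)
  fam_pairs <- which(vapply(pair_units, function(u)
    u$class %in% c("tandem", "proximal"), logical(1)))
  block_pairs <- which(vapply(pair_units, function(u)
    u$class == "wgd_segmental", logical(1)))
  fam_pairs <- c(shuffle(fam_pairs), utils::head(shuffle(block_pairs), 1))
  singles <- shuffle(which(free))
  pi_pair <- 1L; pi_single <- 1L
  for (f in names(config@family_sizes)) {
    need <- config@family_sizes[[f]]
    members <- integer(0)
    while (need >= 2 && pi_pair <= length(fam_pairs)) {
      u <- pair_units[[fam_pairs[pi_pair]]]
      members <- c(members, u$a, u$b)
      pi_pair <- pi_pair + 1L
      need <- need - 2L
    }
    while (need >= 1) {
      if (pi_single > length(singles))
        stop("plan infeasible: not enough gene slots for kinase family ", f)
      members <- c(members, singles[pi_single])
      pi_single <- pi_single + 1L
      need <- need - 1L
    }
    fam_of[members] <- f
  }

  # ---- sequences -----------------------------------------------------------
  cds_body <- vector("character", n_slots)
  div <- config@divergence
  for (f in names(config@family_sizes)) {
    founder <- .randCodons(config@kinase_cds_codons)
    founder[1] <- "ATG"
    members <- which(fam_of == f)
    for (m in members)
      cds_body[m] <- paste(.divergeCds(founder, div, config@duplication_omega),
                           collapse = "")
  }
  # pair partners copy each other; family founders already did family slots
  for (u in pair_units) {
    if (!nzchar(cds_body[u$a])) {
      founder <- .randCodons(sample(150:300, 1))
      founder[1] <- "ATG"
      cds_body[u$a] <- paste(founder, collapse = "")
    }
    if (!nzchar(cds_body[u$b]))
      cds_body[u$b] <- paste(
        .divergeCds(.splitCodons(cds_body[u$a]), div,
                    config@duplication_omega), collapse = "")
  }
  for (s in which(!nzchar(cds_body))) {
    cod <- .randCodons(sample(150:300, 1))
    cod[1] <- "ATG"
    cds_body[s] <- paste(cod, collapse = "")
  }

  # ---- gene models and chromosome layout -----------------------------------
  feat <- list()
  truth_feat <- list()
  chrom_seq <- stats::setNames(vector("character", n_chr), chrom_names)
  gene_start <- integer(n_slots); gene_end <- integer(n_slots)
  gene_strand <- character(n_slots)
  for (chr in seq_len(n_chr)) {
    slots <- which(slot_chr == chr)
    pos <- 0L
    parts <- character(0)
    for (s in slots) {
      g <- gene_ids[s]
      tx <- paste0(g, ".1")
      strand <- sample(c("+", "-"), 1)
      model <- .buildGeneModel(
        cds_body[s],
        u5 = sample(50:150, 1), u3 = sample(80:200, 1),
        n_exons = sample(seq_len(min(4L, nchar(cds_body[s]) %/% 90)), 1),
        intron_lens = sample(80:250, 3, replace = TRUE))
      gap <- sample(2300:3300, 1)
      gstart <- pos + gap + 1L
      gend <- gstart + model$M - 1L
      parts <- c(parts,
                 paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                       collapse = ""),
                 if (strand == "+") model$locus_seq else
                   .revComp(model$locus_seq))
      pos <- gend
      gene_start[s] <- gstart; gene_end[s] <- gend; gene_strand[s] <- strand
      to_genomic <- function(a, b) {
        if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
        else c(gstart + model$M - b, gstart + model$M - a)
      }
      rows <- list(data.frame(seqid = chrom_names[chr],
                              start = gstart, end = gend, strand = strand,
                              type = "gene", ID = g, Parent = NA_character_,
                              stringsAsFactors = FALSE),
                   data.frame(seqid = chrom_names[chr],
                              start = gstart, end = gend, strand = strand,
                              type = "mRNA", ID = tx, Parent = g,
                              stringsAsFactors = FALSE))
      add <- function(a, b, type, id = NA_character_) {
        gc <- to_genomic(a, b)
        rows[[length(rows) + 1]] <<- data.frame(
          seqid = chrom_names[chr], start = gc[1], end = gc[2],
          strand = strand, type = type, ID = id, Parent = tx,
          stringsAsFactors = FALSE)
      }
      k <- model$n_exons
      for (j in seq_len(k)) {
        add(model$es[j], model$ee[j], "exon", sprintf("%s.exon%d", tx, j))
        add(model$cds_s[j], model$cds_e[j], "CDS", sprintf("%s.cds%d", tx, j))
      }
      add(model$es[1], model$es[1] + model$u5 - 1L, "five_prime_UTR",
          paste0(tx, ".utr5"))
      add(model$ee[k] - model$u3 + 1L, model$ee[k], "three_prime_UTR",
          paste0(tx, ".utr3"))
      feat[[length(feat) + 1]] <- do.call(rbind, rows)
      truth_feat[[length(truth_feat) + 1]] <- data.frame(
        gene_id = g, transcript_length = model$mature_len,
        genomic_span = model$M, n_exons = k,
        exon_length_total = model$mature_len, n_introns = k - 1L,
        intron_length_total = model$intron_total,
        n_cds_chunks = k, cds_length_total = model$cds_len,
        n_utr5 = 1L, utr5_length_total = model$u5,
        n_utr3 = 1L, utr3_length_total = model$u3,
        stringsAsFactors = FALSE)
    }
    tail_len <- config@chrom_length - pos
    if (tail_len < 1200L)
      stop("plan infeasible: genes exceed chromosome length on ",
           chrom_names[chr], " (need ", pos + 1200L, " bp, have ",
           config@chrom_length, ")")
    parts <- c(parts, paste(sample(c("A", "C", "G", "T"), tail_len,
                                   replace = TRUE), collapse = ""))
    chrom_seq[chr] <- paste(parts, collapse = "")
  }

  features <- do.call(rbind, feat)
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$ID
  S4Vectors::mcols(gr)$Parent <- features$Parent
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(rep(config@chrom_length, n_chr), chrom_names)
  annotation <- new("GenomeAnnotation", features = gr)

  # ---- planted promoter motifs ---------------------------------------------
  motifs <- .simMotifs()
  pm <- config@promoter_motif_plan
  truth_motifs <- list()
  if (nrow(pm)) {
    for (i in seq_len(nrow(pm))) {
      mid <- pm$motif_id[i]
      if (!mid %in% names(motifs))
        stop("unknown motif id in promoter plan: ", mid)
      cons <- motifs[[mid]]$consensus
      w <- nchar(cons)
      fg_slots <- which(fam_of == pm$family[i])
      if (!length(fg_slots))
        stop("promoter motif plan references unknown family ", pm$family[i])
      bg_slots <- setdiff(seq_len(n_slots), fg_slots)
      n_fg <- round(pm$fg_fraction[i] * length(fg_slots))
      n_bg <- round(pm$bg_fraction[i] * length(bg_slots))
      chosen_fg <- fg_slots[sample.int(length(fg_slots))][seq_len(n_fg)]
      chosen_bg <- bg_slots[sample.int(length(bg_slots))][seq_len(n_bg)]
      for (s in c(chosen_fg, chosen_bg)) {
        off <- sample(50:(950 - w), 1) # bp upstream of the planted site start
        chr <- slot_chr[s]
        if (gene_strand[s] == "+") {
          at <- gene_start[s] - off - w
          insert <- cons
        } else {
          at <- gene_end[s] + off
          insert <- .revComp(cons)
        }
        substr(chrom_seq[chr], at + 1L, at + w) <- insert
      }
      truth_motifs[[i]] <- data.frame(
        motif_id = mid, family = pm$family[i],
        gene_id = gene_ids[c(chosen_fg, chosen_bg)],
        planted_in = rep(c("foreground", "background"),
                         c(length(chosen_fg), length(chosen_bg))),
        stringsAsFactors = FALSE)
    }
  }

  # ---- sequence sets -------------------------------------------------------
  genome <- Biostrings::DNAStringSet(chrom_seq)
  cds_full <- stats::setNames(paste0(cds_body, "TAA"), gene_ids)
  prot <- vapply(cds_full, .cdsToProtein, character(1))
  proteins <- Biostrings::AAStringSet(prot)
  cds_set <- Biostrings::DNAStringSet(cds_full)

  # ---- hit tables ----------------------------------------------------------
  kin_slots <- which(!is.na(fam_of))
  dom <- list()
  for (s in kin_slots) {
    cov <- stats::runif(1, 0.55, 0.95)
    to <- 5L + ceiling(cov * 264) - 1L
    dom[[length(dom) + 1]] <- data.frame(
      protein_id = gene_ids[s], model_id = "PF00069",
      model_from = 5L, model_to = min(to, 264L), model_length = 264L,
      evalue = 10^stats::runif(1, -60, -20),
      bit_score = round(stats::runif(1, 150, 400), 1),
      stringsAsFactors = FALSE)
    dom[[length(dom) + 1]] <- data.frame(
      protein_id = gene_ids[s], model_id = fam_of[s],
      model_from = 1L, model_to = 280L, model_length = 300L,
      evalue = 10^stats::runif(1, -40, -10),
      bit_score = round(stats::runif(1, 200, 500), 1),
      stringsAsFactors = FALSE)
  }
  # decoys: sub-threshold kinase-domain coverage on two non-kinase genes
  decoys <- utils::head(setdiff(seq_len(n_slots), kin_slots), 2)
  for (s in decoys)
    dom[[length(dom) + 1]] <- data.frame(
      protein_id = gene_ids[s], model_id = "PF00069",
      model_from = 10L, model_to = 10L + ceiling(stats::runif(1, 0.2, 0.45) * 264) - 1L,
      model_length = 264L, evalue = 1e-8,
      bit_score = 80, stringsAsFactors = FALSE)
  domain_hits <- do.call(rbind, dom)

  sim_rows <- lapply(pair_units, function(u) data.frame(
    query = gene_ids[u$a], subject = gene_ids[u$b],
    identity = round(100 * (1 - div) - stats::runif(1, 0, 0.5), 2),
    bit_score = round(stats::runif(1, 400, 900), 1),
    stringsAsFactors = FALSE))
  similarity <- if (length(sim_rows)) do.call(rbind, sim_rows) else
    data.frame(query = character(0), subject = character(0),
               identity = numeric(0), bit_score = numeric(0))

  # ---- evolved CDS pairs for selection analysis ----------------------------
  kaks_pairs <- lapply(seq_along(config@omega_plan), function(i) {
    omega <- config@omega_plan[i]
    anc <- paste(.randCodons(config@kinase_cds_codons), collapse = "")
    ev <- evolveCdsPair(anc, omega,
                        n_events = max(10L, round(config@kinase_cds_codons / 10)))
    list(pair_id = sprintf("pair%02d", i), omega = omega,
         cds1 = anc, cds2 = ev$cds, log = ev$log)
  })

  # ---- truth tables --------------------------------------------------------
  dup_class <- stats::setNames(rep("singleton", n_slots), gene_ids)
  for (u in pair_units) {
    for (s in c(u$a, u$b))
      if (.duplicationPriority[u$class] >
          .duplicationPriority[dup_class[gene_ids[s]]])
        dup_class[gene_ids[s]] <- u$class
  }
  truth <- list(
    family = data.frame(gene_id = gene_ids[kin_slots],
                        family = fam_of[kin_slots],
                        stringsAsFactors = FALSE),
    duplication = data.frame(gene_id = gene_ids,
                             class = unname(dup_class),
                             stringsAsFactors = FALSE),
    blocks = if (length(blocks_truth)) do.call(rbind, blocks_truth) else
      data.frame(block_id = integer(0), position = integer(0),
                 geneA = character(0), geneB = character(0)),
    gene_features = do.call(rbind, truth_feat),
    motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs) else
      data.frame(motif_id = character(0), family = character(0),
                 gene_id = character(0), planted_in = character(0)),
    omega = data.frame(
      pair_id = vapply(kaks_pairs, `[[`, "", "pair_id"),
      omega = vapply(kaks_pairs, `[[`, 0, "omega"),
      stringsAsFactors = FALSE)
  )

  list(annotation = annotation, genome = genome, proteins = proteins,
       cds = cds_set, domain_hits = domain_hits, similarity = similarity,
       pwms = lapply(motifs, function(m) m[c("motif_id", "name", "counts")]),
       kaks_pairs = kaks_pairs, truth = truth, config = config)
}

#' Generate synthetic expression, GO and qPCR tables
#'
#' Plants up-regulated transcripts per the DE plan (log2FC drawn from a normal
#' truncated above the fold-change threshold, p-values well below the filter
#' cutoffs), gives null transcripts `log2FC ~ N(0, noise_sd)` and
#' `p ~ U(0, 1)`, annotates a GO term enriched in the planted set, and writes
#' Ct tables where the treated Ct drops by `log_E(ratio)` cycles plus
#' replicate noise.
#'
#' @param transcripts character vector of transcript ids.
#' @param families named vector transcript -> family (NA/absent = non-kinase).
#' @param de_plan data.frame `family`, `n_up`, `mean_log2FC`.
#' @param assays names of independent assays/treatments.
#' @param noise_sd sd of the null log2FC (0 = noise-free nulls).
#' @param ct_noise sd of per-replicate Ct noise (0 = closed-form Ct).
#' @param n_ct_targets planted-up transcripts carried into the Ct table.
#' @param replicates qPCR replicates per condition.
#' @param efficiency amplification efficiency used to synthesize Ct values.
#' @param go_fg_fraction,go_bg_fraction annotation frequency of the planted
#'   enriched term among assay-1 planted genes vs the rest.
#' @param seed integer seed.
#' @return list with `de` (named list of data.frames `transcript_id`,
#'   `log2FC`, `p`, `fdr`), `go` (data.frame `gene`, `term`, `name`), `ct`
#'   (data.frame `gene`, `role`, `condition`, `replicate`, `Ct`), and `truth`
#'   (`de` per assay, `enriched_term`, `ratios`).
#' @export
genExpressionTables <- function(transcripts, families, de_plan,
                                assays = c("dehydration", "cabmv", "cpsmv"),
                                noise_sd = 0.3, ct_noise = 0.15,
                                n_ct_targets = 3, replicates = 3,
                                efficiency = 2,
                                go_fg_fraction = 0.5, go_bg_fraction = 0.1,
                                seed = 1L) {
  set.seed(seed)
  m <- length(transcripts)
  de <- list(); truth_de <- list()
  for (a in assays) {
    lfc <- if (noise_sd > 0) stats::rnorm(m, 0, noise_sd) else numeric(m)
    p <- stats::runif(m)
    planted <- character(0)
    for (i in seq_len(nrow(de_plan))) {
      fam <- de_plan$family[i]
      members <- names(families)[!is.na(families) & families == fam]
      members <- intersect(members, transcripts)
      if (length(members) < de_plan$n_up[i])
        stop("de_plan asks for ", de_plan$n_up[i], " up-regulated members of ",
             fam, " but only ", length(members), " exist")
      up <- members[sample.int(length(members))][seq_len(de_plan$n_up[i])]
      for (tx in up) {
        j <- match(tx, transcripts)
        val <- stats::rnorm(1, de_plan$mean_log2FC[i], 0.5)
        while (val <= 1) val <- stats::rnorm(1, de_plan$mean_log2FC[i], 0.5)
        lfc[j] <- val
        p[j] <- stats::runif(1, 0, 1e-4)
      }
      planted <- c(planted, up)
    }
    tab <- data.frame(transcript_id = transcripts, log2FC = lfc, p = p,
                      fdr = bhFdr(p), stringsAsFactors = FALSE)
    de[[a]] <- tab
    truth_de[[a]] <- data.frame(
      transcript_id = planted, direction = "up",
      log2FC = tab$log2FC[match(planted, transcripts)],
      stringsAsFactors = FALSE)
  }

  # GO annotations: a planted term enriched among assay-1 up genes
  enriched_term <- "GO:9900001"
  other_terms <- sprintf("GO:%07d", 1:12)
  fg_genes <- truth_de[[1]]$transcript_id
  bg_genes <- setdiff(transcripts, fg_genes)
  ann <- list()
  take <- function(pool, frac)
    pool[sample.int(length(pool))][seq_len(round(frac * length(pool)))]
  for (g in take(fg_genes, go_fg_fraction))
    ann[[length(ann) + 1]] <- data.frame(gene = g, term = enriched_term,
                                         name = "planted process")
  for (g in take(bg_genes, go_bg_fraction))
    ann[[length(ann) + 1]] <- data.frame(gene = g, term = enriched_term,
                                         name = "planted process")
  for (tx in transcripts) {
    for (tm in sample(other_terms, sample(1:3, 1)))
      ann[[length(ann) + 1]] <- data.frame(gene = tx, term = tm,
                                           name = paste("process", tm))
  }
  go <- unique(do.call(rbind, ann))

  # qPCR Ct tables for the first planted-up transcripts of assay 1
  targets <- utils::head(truth_de[[1]]$transcript_id, n_ct_targets)
  ratios <- 2^truth_de[[1]]$log2FC[match(targets, truth_de[[1]]$transcript_id)]
  base_ct <- 22
  ct <- list()
  emit <- function(gene, role, condition, ctv) {
    noise <- if (ct_noise > 0) stats::rnorm(replicates, 0, ct_noise) else
      numeric(replicates)
    data.frame(gene = gene, role = role, condition = condition,
               replicate = seq_len(replicates), Ct = ctv + noise,
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(targets)) {
    ct[[length(ct) + 1]] <- emit(targets[i], "target", "control", base_ct)
    ct[[length(ct) + 1]] <- emit(targets[i], "target", "treated",
                                 base_ct - log(ratios[i], efficiency))
  }
  for (ref in c("REF_ACT", "REF_UBC")) {
    ct[[length(ct) + 1]] <- emit(ref, "reference", "control", base_ct - 2)
    ct[[length(ct) + 1]] <- emit(ref, "reference", "treated", base_ct - 2)
  }
  ct <- do.call(rbind, ct)

  list(de = de, go = go, ct = ct,
       truth = list(de = truth_de, enriched_term = enriched_term,
                    ratios = stats::setNames(ratios, targets)))
}
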