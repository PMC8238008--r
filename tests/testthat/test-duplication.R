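mk_ranks_ann <- function(starts_by_chr) {
  rows <- list()
  for (chr in names(starts_by_chr)) {
    for (i in seq_along(starts_by_chr[[chr]])) {
      s <- starts_by_chr[[chr]][i]
      g <- sprintf("%s_g%02d", chr, i)
      rows[[length(rows) + 1]] <- data.frame(
        seqid = chr, start = s, end = s + 99L, strand = "+", type = "gene",
        ID = g, Parent = NA_character_, stringsAsFactors = FALSE)
    }
  }
  makeGenomeAnnotation(do.call(rbind, rows))
}

test_that("gene ranks follow coordinates, per chromosome, input-order-free", {
  ann <- mk_ann_shuffled <- mk_ranks_ann(list(chr1 = c(100, 500, 900),
                                              chr2 = c(300, 50)))
  r <- geneRanks(ann)
  expect_equal(r$rank[r$chromosome == "chr1"], 1:3)
  expect_equal(r$gene_id[r$chromosome == "chr2"], c("chr2_g02", "chr2_g01"))
  expect_equal(r$rank[r$chromosome == "chr2"], 1:2)
  # shuffled feature order gives identical ranks
  gr <- annFeatures(ann)
  set.seed(4)
  ann2 <- new("GenomeAnnotation", features = gr[sample(length(gr))])
  expect_equal(geneRanks(ann2), r)
})

test_that("rank-gap rules map to tandem, proximal, dispersed and singleton", {
  ann <- mk_ranks_ann(list(chr1 = seq(100, 2000, by = 150),
                           chr2 = seq(100, 500, by = 150)))
  ranks <- geneRanks(ann)
  hit <- function(a, b) data.frame(query = a, subject = b, bit_score = 100)
  # ranks 7 and 8 on chr1: tandem
  calls <- classifyDuplicates(ranks, hit("chr1_g07", "chr1_g08"))
  cls <- setNames(calls$class, calls$gene_id)
  expect_equal(unname(cls[c("chr1_g07", "chr1_g08")]), c("tandem", "tandem"))
  # ranks 3 and 9: gap 6 -> proximal
  calls <- classifyDuplicates(ranks, hit("chr1_g03", "chr1_g09"))
  cls <- setNames(calls$class, calls$gene_id)
  expect_equal(unname(cls[c("chr1_g03", "chr1_g09")]),
               c("proximal", "proximal"))
  # cross-chromosome -> dispersed; no hits -> singleton
  calls <- classifyDuplicates(ranks, hit("chr1_g01", "chr2_g02"))
  cls <- setNames(calls$class, calls$gene_id)
  expect_equal(unname(cls["chr1_g01"]), "dispersed")
  expect_equal(unname(cls["chr1_g05"]), "singleton")
  expect_error(classifyDuplicates(ranks, hit("chr1_g01", "nope")),
               "unranked")
})

test_that("boundary gaps: 19 is proximal, 20 is only dispersed", {
  ann <- mk_ranks_ann(list(chr1 = seq(100, 100 + 24 * 150, by = 150)))
  ranks <- geneRanks(ann)
  h19 <- data.frame(query = "chr1_g01", subject = "chr1_g20", bit_score = 1)
  cls <- setNames(classifyDuplicates(ranks, h19)$class, ranks$gene_id)
  expect_equal(unname(cls["chr1_g01"]), "proximal")
  h20 <- data.frame(query = "chr1_g01", subject = "chr1_g21", bit_score = 1)
  cls <- setNames(classifyDuplicates(ranks, h20)$class, ranks$gene_id)
  expect_equal(unname(cls["chr1_g01"]), "dispersed")
})

test_that("random instances match the exhaustive rule oracle and partition", {
  set.seed(55)
  for (rep in 1:50) {
    n1 <- sample(15:25, 1); n2 <- 40 - n1
    ann <- mk_ranks_ann(list(chr1 = seq(100, by = 150, length.out = n1),
                             chr2 = seq(100, by = 150, length.out = n2)))
    ranks <- geneRanks(ann)
    genes <- ranks$gene_id
    hits <- data.frame(query = sample(genes, 25, replace = TRUE),
                       subject = sample(genes, 25, replace = TRUE),
                       bit_score = round(runif(25, 50, 500), 1))
    hits <- hits[hits$query != hits$subject, ]
    block_genes <- sample(genes, 6)
    blocks <- list(anchors = data.frame(geneA = block_genes[1:3],
                                        geneB = block_genes[4:6]))
    got <- classifyDuplicates(ranks, hits, blocks, top_n_hits = Inf)
    ora <- oracle_classify(ranks, hits, block_genes)
    expect_equal(setNames(got$class, got$gene_id)[genes], ora[genes])
    # partition invariant
    expect_equal(nrow(got), length(genes))
    # tandem always has a same-chromosome rank-gap-1 partner
    cls <- setNames(got$class, got$gene_id)
    ch <- setNames(ranks$chromosome, ranks$gene_id)
    rk <- setNames(ranks$rank, ranks$gene_id)
    for (g in names(cls)[cls == "tandem"]) {
      partners <- unique(c(hits$subject[hits$query == g],
                           hits$query[hits$subject == g]))
      expect_true(any(ch[partners] == ch[g] &
                        abs(rk[partners] - rk[g]) == 1))
    }
  }
})

test_that("adding a hit can only raise the class in priority order", {
  ann <- mk_ranks_ann(list(chr1 = seq(100, by = 150, length.out = 30)))
  ranks <- geneRanks(ann)
  pri <- c(singleton = 0, dispersed = 1, proximal = 2, tandem = 3,
           wgd_segmental = 4)
  h1 <- data.frame(query = "chr1_g01", subject = "chr1_g25", bit_score = 5)
  h2 <- rbind(h1, data.frame(query = "chr1_g01", subject = "chr1_g02",
                             bit_score = 5))
  c1 <- setNames(classifyDuplicates(ranks, h1)$class, ranks$gene_id)
  c2 <- setNames(classifyDuplicates(ranks, h2)$class, ranks$gene_id)
  expect_true(all(pri[c2] >= pri[c1]))
})

test_that("the per-gene top-hit cap drops weak hub links", {
  ann <- mk_ranks_ann(list(chr1 = seq(100, by = 150, length.out = 30)))
  ranks <- geneRanks(ann)
  hub <- "chr1_g15"
  strong <- data.frame(query = hub,
                       subject = sprintf("chr1_g%02d", c(1:5)),
                       bit_score = 900:896)
  weak <- data.frame(query = hub, subject = "chr1_g16", bit_score = 10)
  cls1 <- setNames(classifyDuplicates(ranks, rbind(strong, weak),
                                      top_n_hits = 1)$class, ranks$gene_id)
  # g16's only (hence top) hit is the hub, rank gap 1: tandem for g16; the
  # hub's own top hit is g01 (gap 14), so the hub stays proximal
  expect_equal(unname(cls1["chr1_g16"]), "tandem")
  expect_equal(unname(cls1["chr1_g15"]), "proximal")
  cls5 <- setNames(classifyDuplicates(ranks, rbind(strong, weak),
                                      top_n_hits = 5)$class, ranks$gene_id)
  # with five slots the hub still keeps only the strong hits: no tandem
  expect_equal(unname(cls5["chr1_g15"]), "proximal")
  expect_equal(unname(cls5["chr1_g16"]), "tandem")
})

test_that("five collinear matches form a block; four never do", {
  mk_pairs <- function(k) data.frame(
    geneA = sprintf("a%d", 1:k), chromA = "chr1", rankA = 1:k,
    geneB = sprintf("b%d", 1:k), chromB = "chr2", rankB = 1:k)
  five <- findCollinearBlocks(mk_pairs(5))
  expect_equal(nrow(five$blocks), 1)
  expect_equal(five$blocks$size, 5)
  four <- findCollinearBlocks(mk_pairs(4))
  expect_equal(nrow(four$blocks), 0)
})

test_that("inverted chains are found and oriented", {
  pr <- data.frame(geneA = sprintf("a%d", 1:6), chromA = "chr1", rankA = 1:6,
                   geneB = sprintf("b%d", 1:6), chromB = "chr2", rankB = 12:7)
  res <- findCollinearBlocks(pr)
  expect_equal(res$blocks$size, 6)
  expect_equal(res$blocks$orientation, "inverted")
})

test_that("reported chains are valid, maximal and match the brute force", {
  set.seed(66)
  for (rep in 1:10) {
    n <- 30
    pr <- data.frame(geneA = sprintf("a%02d", 1:n), chromA = "chr1",
                     rankA = sample(1:60, n),
                     geneB = sprintf("b%02d", 1:n), chromB = "chr2",
                     rankB = sample(1:60, n))
    res <- findCollinearBlocks(pr, min_block_size = 4, max_rank_gap = 25)
    best <- max(oracle_longest_chain(pr$rankA, pr$rankB, 1L, 25),
                oracle_longest_chain(pr$rankA, pr$rankB, -1L, 25))
    if (best < 4) {
      expect_equal(nrow(res$blocks), 0)
    } else {
      expect_equal(res$blocks$size[1], best)
    }
    # every reported chain is strictly monotone with bounded gaps,
    # and no match is used twice
    if (nrow(res$anchors)) {
      expect_false(any(duplicated(res$anchors$geneA)))
      for (b in unique(res$anchors$block_id)) {
        an <- res$anchors[res$anchors$block_id == b, ]
        da <- diff(an$rankA); db <- diff(an$rankB)
        expect_true(all(da > 0) && all(da <= 25))
        expect_true(all(db > 0) || all(db < 0))
        expect_true(all(abs(db) <= 25))
      }
    }
  }
})

test_that("planted duplication classes are recovered perfectly", {
  for (seed in c(401, 402, 403)) {
    sim <- bank_sim(seed)
    ranks <- geneRanks(sim$annotation)
    blocks <- findCollinearBlocks(sim_pairs_table(sim))
    calls <- classifyDuplicates(ranks, sim$similarity, blocks)
    truth <- sim$truth$duplication
    got <- setNames(calls$class, calls$gene_id)
    expect_equal(unname(got[truth$gene_id]), truth$class)
  }
})

test_that("dual synteny on identical genomes finds whole-chromosome blocks", {
  sim <- bank_sim(301)
  ranks <- geneRanks(sim$annotation)
  hits <- data.frame(query = ranks$gene_id, subject = ranks$gene_id,
                     bit_score = 100)
  ds <- dualSynteny(sim$annotation, sim$annotation, hits,
                    kinase_ids = sim$truth$family$gene_id)
  per_chr <- table(ranks$chromosome)
  expect_equal(nrow(ds$blocks), length(per_chr))
  expect_equal(sort(ds$blocks$size), sort(as.integer(per_chr)))
  expect_equal(ds$n_kinase_blocks,
               sum(tapply(ranks$gene_id %in% sim$truth$family$gene_id,
                          ranks$chromosome, any)))
  expect_equal(nrow(ds$dotplot), sum(ds$blocks$size))
  expect_warning(
    dualSynteny(sim$annotation, sim$annotation,
                data.frame(query = character(0), subject = character(0))),
    "empty")
})
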