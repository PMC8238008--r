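test_that("config validation names the violated constraint", {
  expect_error(simConfig(n_genes = 0), "positive")
  expect_error(simConfig(duplication_plan = data.frame(
    class = "sideways", count = 2L)), "unknown duplication class")
  expect_error(simConfig(collinear_block_plan = data.frame(
    chromA = 1L, chromB = 2L, n_pairs = 4L)), "at least 5")
  expect_error(simConfig(promoter_motif_plan = data.frame(
    family = "f", motif_id = "SYNM01", fg_fraction = 1.2,
    bg_fraction = 0)), "\\[0, 1\\]")
  expect_error(simConfig(divergence = 0.5), "divergence")
})

test_that("infeasible layouts fail loudly rather than emit broken genomes", {
  tiny <- simConfig(chrom_length = 20000L, n_genes = 30L)
  expect_error(genGenome(tiny), "infeasible")
  crowded <- simConfig(duplication_plan = data.frame(
    class = "tandem", count = 40L))
  expect_error(genGenome(crowded), "infeasible")
})

test_that("planted tandem pairs occupy adjacent ranks", {
  cfg <- simConfig(duplication_plan = data.frame(class = "tandem", count = 4L),
                   collinear_block_plan = data.frame(chromA = integer(0),
                                                     chromB = integer(0),
                                                     n_pairs = integer(0)),
                   seed = 7L)
  sim <- genGenome(cfg)
  tand <- sim$truth$duplication$gene_id[sim$truth$duplication$class == "tandem"]
  expect_equal(length(tand), 8)
  ranks <- geneRanks(sim$annotation)
  rk <- setNames(ranks$rank, ranks$gene_id)
  ch <- setNames(ranks$chromosome, ranks$gene_id)
  for (i in seq_len(nrow(sim$similarity))) {
    a <- sim$similarity$query[i]; b <- sim$similarity$subject[i]
    expect_equal(ch[[a]], ch[[b]])
    expect_equal(abs(rk[[a]] - rk[[b]]), 1)
  }
})

test_that("fixed seeds give byte-identical files", {
  cfg <- simConfig(seed = 99L)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  p1 <- writeSimulation(genGenome(cfg), d1)
  p2 <- writeSimulation(genGenome(cfg), d2)
  expect_equal(names(p1), names(p2))
  for (nm in names(p1))
    expect_equal(unname(tools::md5sum(p1[[nm]])),
                 unname(tools::md5sum(p2[[nm]])), label = nm)
})

test_that("planted collinear chains are ordered in genome coordinates", {
  cfg <- simConfig(collinear_block_plan = data.frame(chromA = 1L, chromB = 2L,
                                                     n_pairs = 6L),
                   seed = 13L)
  sim <- genGenome(cfg)
  bl <- sim$truth$blocks
  expect_equal(nrow(bl), 6)
  g <- annGenes(sim$annotation)
  starts <- setNames(BiocGenerics::start(g), S4Vectors::mcols(g)$ID)
  chroms <- setNames(as.character(GenomeInfoDb::seqnames(g)),
                     S4Vectors::mcols(g)$ID)
  # brute-force scan of emitted coordinates: each side of the chain is
  # strictly increasing along its own chromosome, and sides are consecutive
  expect_true(all(chroms[bl$geneA] == "chr1"))
  expect_true(all(chroms[bl$geneB] == "chr2"))
  expect_true(all(diff(starts[bl$geneA]) > 0))
  expect_true(all(diff(starts[bl$geneB]) > 0))
  ranks <- geneRanks(sim$annotation)
  rk <- setNames(ranks$rank, ranks$gene_id)
  expect_equal(diff(rk[bl$geneA]), rep(1, 5), ignore_attr = TRUE)
  expect_equal(diff(rk[bl$geneB]), rep(1, 5), ignore_attr = TRUE)
  # and the similarity table carries a hit for every planted pair
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(bl$geneA, bl$geneB) %in%
                    key(sim$similarity$query, sim$similarity$subject)))
})

test_that("the annotation GFF3 round-trips through the reader without loss", {
  sim <- bank_sim(301)
  path <- tempfile(fileext = ".gff3")
  writeGenomeAnnotation(sim$annotation, path)
  back <- readGenomeAnnotation(path)
  a <- as.data.frame(annFeatures(sim$annotation))
  b <- as.data.frame(annFeatures(back))
  key <- function(d) sort(paste(d$seqnames, d$start, d$end, d$strand, d$type,
                                d$ID, d$Parent))
  expect_equal(key(a), key(b))
  # seqlengths preserved via the GFF3 sequence-region pragma
  expect_equal(GenomeInfoDb::seqlengths(annFeatures(back)),
               GenomeInfoDb::seqlengths(annFeatures(sim$annotation)))
})

test_that("CDS sequences extracted from the genome match the emitted CDS", {
  sim <- bank_sim(301)
  gr <- annFeatures(sim$annotation)
  md <- S4Vectors::mcols(gr)
  for (gid in sample(names(sim$cds), 6)) {
    tx <- paste0(gid, ".1")
    cds <- gr[md$type == "CDS" & md$Parent == tx]
    cds <- cds[order(BiocGenerics::start(cds))]
    chrom <- as.character(sim$genome[[as.character(
      GenomeInfoDb::seqnames(cds[1]))]])
    pieces <- vapply(seq_along(cds), function(i)
      substr(chrom, BiocGenerics::start(cds[i]), BiocGenerics::end(cds[i])),
      character(1))
    joined <- paste(pieces, collapse = "")
    if (as.character(BiocGenerics::strand(cds[1])) == "-")
      joined <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(joined)))
    expect_equal(joined, as.character(sim$cds[[gid]]))
  }
})

test_that("emitted proteins translate from the emitted CDS", {
  sim <- bank_sim(301)
  for (gid in sample(names(sim$cds), 6)) {
    prot <- Biostrings::translate(sim$cds[[gid]])
    expect_equal(sub("\\*$", "", as.character(prot)),
                 as.character(sim$proteins[[gid]]))
  }
})

test_that("omega zero evolution never changes the protein", {
  set.seed(6)
  anc <- paste(random_codons(120), collapse = "")
  ev <- evolveCdsPair(anc, omega = 0, n_events = 40, seed = 2)
  expect_equal(nrow(ev$log), 40)
  expect_true(all(ev$log$type == "synonymous"))
  tr <- function(x) paste(GC_TABLE[substring(
    x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))], collapse = "")
  expect_equal(tr(ev$cds), tr(anc))
  expect_false(ev$cds == anc)
})

test_that("zero events leave the sequence untouched; stops are rejected", {
  anc <- paste(random_codons(30), collapse = "")
  ev <- evolveCdsPair(anc, omega = 1, n_events = 0)
  expect_identical(ev$cds, anc)
  expect_equal(nrow(ev$log), 0)
  expect_error(evolveCdsPair(paste0(anc, "TAA"), 1, 5), "stop")
  expect_error(evolveCdsPair("ATGA", 1, 1), "divisible")
})

test_that("neutral evolution mirrors the availability of mutation classes", {
  # omega = 1: accepted syn:nonsyn ratio ~ availability ratio among all
  # single-nt non-stop mutations of the sequence, by exhaustive enumeration
  set.seed(15)
  anc <- paste(random_codons(200), collapse = "")
  avail_syn <- 0; avail_non <- 0
  codons <- substring(anc, seq(1, nchar(anc), 3), seq(3, nchar(anc), 3))
  for (cod in codons) {
    for (pos in 1:3) for (b in NT) {
      if (b == substr(cod, pos, pos)) next
      m <- cod
      substr(m, pos, pos) <- b
      if (GC_TABLE[[m]] == "*") next
      if (GC_TABLE[[m]] == GC_TABLE[[cod]]) avail_syn <- avail_syn + 1
      else avail_non <- avail_non + 1
    }
  }
  expected_frac <- avail_syn / (avail_syn + avail_non)
  logs <- do.call(rbind, lapply(1:20, function(s)
    evolveCdsPair(anc, 1, 50, seed = s)$log))
  got_frac <- mean(logs$type == "synonymous")
  # binomial noise on 1000 events: three sigma
  expect_lt(abs(got_frac - expected_frac),
            3 * sqrt(expected_frac * (1 - expected_frac) / nrow(logs)) + 0.01)
})

test_that("simulated codon pairs keep their bookkeeping through codonAlign", {
  sim <- bank_sim(301)
  kp <- sim$kaks_pairs[[1]]
  p1 <- plantKinome:::.cdsToProtein(kp$cds1)
  p2 <- plantKinome:::.cdsToProtein(kp$cds2)
  # substitution-only evolution: proteins align without gaps
  aln <- codonAlign(c(p1, p2), c(a = kp$cds1, b = kp$cds2))
  expect_equal(length(aln$codons1), nchar(kp$cds1) / 3)
  expect_equal(aln$n_excluded, 0)
})
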