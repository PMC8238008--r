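test_that("the DE filter is strict at every threshold", {
  tab <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    log2FC = c(1.0, 2.0, -2.0, 3.0, 2.0),
    p = c(0.01, 0.01, 0.01, 0.05, 0.01),
    fdr = c(0.01, 0.01, 0.01, 0.01, 0.05))
  out <- deFilter(tab)
  expect_equal(out$call, c("ns", "up", "down", "ns", "ns"))
  cnt <- attr(out, "counts")
  expect_equal(unname(cnt["up"] + cnt["down"] + cnt["ns"]), nrow(tab))
  expect_error(deFilter(tab[, -2]), "log2FC")
})

test_that("DE counts partition the table for random inputs", {
  set.seed(3)
  for (rep in 1:10) {
    tab <- data.frame(log2FC = rnorm(200, 0, 2), p = runif(200),
                      fdr = runif(200))
    out <- deFilter(tab)
    cnt <- attr(out, "counts")
    expect_equal(unname(sum(cnt)), 200)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFdr(0.03), 0.03)
  set.seed(9)
  p <- runif(50)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  idx <- sample(50)
  expect_equal(bhFdr(p[idx]), q[idx])
  expect_error(bhFdr(c(0.1, 1.2)), "0, 1")
})

test_that("family tallies count distinct transcripts per treatment", {
  cat_df <- data.frame(protein_id = c("t1", "t2", "t3", "t4"),
                       family = c("FamA", "FamA", "FamA", "FamB"),
                       group = "Fam", n_domains = 1, status = "bona_fide")
  de <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t1", "t1", "t4", "tX"),
    treatment = c("A", "A", "A", "A", "B", "B", "A"),
    call = c("up", "up", "up", "up", "up", "up", "up"))
  tl <- familyTally(cat_df, de)
  expect_equal(tl$n[tl$family == "FamA" & tl$treatment == "A"], 3)
  expect_equal(tl$n[tl$family == "FamA" & tl$treatment == "B"], 1)
  expect_equal(tl$n[tl$family == "FamB" & tl$treatment == "B"], 1)
  expect_equal(attr(tl, "unmapped"), "tX")
})

test_that("crosstalk is plain set intersection", {
  sets <- list(a = c("x", "y", "z"), b = c("y", "z", "w"), c = c("z", "q"))
  ct <- crosstalk(sets)
  expect_equal(ct$shared, "z")
  expect_equal(ct$pairwise$n[ct$pairwise$assayA == "a" &
                               ct$pairwise$assayB == "b"], 2)
  expect_equal(crosstalk(list(a = "x", b = "y"))$shared, character(0))
  expect_equal(crosstalk(list(a = c("x", "y"), b = c("x", "y")))$shared,
               c("x", "y"))
  expect_error(crosstalk(list(a = "x")), "two")
  set.seed(2)
  rnd <- lapply(1:3, function(i) sample(letters, 10))
  names(rnd) <- c("a", "b", "c")
  expect_equal(crosstalk(rnd)$shared,
               sort(intersect(intersect(rnd$a, rnd$b), rnd$c)))
})

test_that("GO enrichment matches the shared hypergeometric oracle", {
  ann <- rbind(
    data.frame(gene = sprintf("g%02d", 1:5), term = "GO:1", name = "T1"),
    data.frame(gene = sprintf("g%02d", 1:20), term = "GO:2", name = "T2"))
  fg <- sprintf("g%02d", 1:5)
  bg <- sprintf("g%02d", 1:20)
  res <- goEnrichment(fg[1:5][c(1, 2, 3, 4)] |> c("g20"), bg, ann)
  row1 <- res[res$term == "GO:1", ]
  expect_equal(row1$p, 76 / 15504, tolerance = 1e-12)
  # a term annotating every gene has tail probability 1
  row2 <- res[res$term == "GO:2", ]
  expect_equal(row2$p, 1)
  expect_false(row2$enriched)
  expect_error(goEnrichment(c("g01", "nope"), bg, ann), "absent")
})

test_that("the planted GO term is recovered across 100 seeded generations", {
  fams <- setNames(rep(c("FamA", "FamB"), c(10, 10)), sprintf("t%02d", 1:20))
  txs <- c(names(fams), sprintf("n%02d", 1:40))
  plan <- data.frame(family = "FamA", n_up = 6, mean_log2FC = 3)
  hit <- logical(100)
  for (s in 1:100) {
    ex <- genExpressionTables(txs, fams, plan, assays = "a1", seed = s)
    fg <- ex$truth$de$a1$transcript_id
    res <- goEnrichment(fg, txs, ex$go)
    p <- res$p[res$term == ex$truth$enriched_term]
    hit[s] <- length(p) == 1 && p < 0.05
  }
  expect_gte(sum(hit), 95)
})

test_that("qPCR ratios follow the closed form and the null is flat", {
  # E = 2, target dCt = 1, reference dCt = 0 -> ratio 2
  r <- restRatio(c(25, 25, 25), c(24, 24, 24),
                 list(c(20, 20, 20)), list(c(20, 20, 20)))
  expect_equal(r$ratio, 2)
  expect_equal(r$delta_ct_target, 1)
  # treated identical to control: ratio 1, p ~ 1
  r0 <- restRatio(c(25, 25, 25), c(25, 25, 25),
                  list(c(20, 20, 20)), list(c(20, 20, 20)))
  expect_equal(r0$ratio, 1)
  expect_equal(r0$p_random, 1)
  expect_error(restRatio(c(25, 25), c(24, 24), list(c(20, 20)),
                         list(c(20, 20)), E_target = 0.9), "exceed")
  expect_error(restRatio(25, c(24, 24), list(c(20, 20)), list(c(20, 20))),
               "replicates")
})

test_that("efficiency percentages convert to fold-per-cycle sensibly", {
  # 90.4% efficiency -> E = 1.904; one cycle of dCt multiplies by E
  r <- restRatio(c(25, 25, 25), c(24, 24, 24),
                 list(c(20, 20, 20)), list(c(20, 20, 20)),
                 E_target = 1 + 90.4 / 100)
  expect_equal(r$ratio, 1.904)
})

test_that("a global Ct offset across both genes leaves the ratio unchanged", {
  set.seed(44)
  ctc <- rnorm(3, 25); ctt <- rnorm(3, 24)
  rfc <- rnorm(3, 20); rft <- rnorm(3, 20)
  r1 <- restRatio(ctc, ctt, list(rfc), list(rft))
  r2 <- restRatio(ctc + 3, ctt + 3, list(rfc + 3), list(rft + 3))
  expect_equal(r1$ratio, r2$ratio)
})

test_that("3v3 randomization p equals full enumeration", {
  set.seed(10)
  for (rep in 1:5) {
    ctc <- rnorm(3, 25, 0.3); ctt <- rnorm(3, 24, 0.3)
    rfc <- rnorm(3, 20, 0.3); rft <- rnorm(3, 20, 0.3)
    r <- restRatio(ctc, ctt, list(rfc), list(rft))
    expect_true(r$exhaustive)
    expect_equal(r$n_reallocations, choose(6, 3))
    # oracle: enumerate control index sets explicitly
    ct_t <- c(ctc, ctt); ct_r <- c(rfc, rft)
    obs <- abs(log(2^(mean(ctc) - mean(ctt)) / 2^(mean(rfc) - mean(rft))))
    stats <- apply(utils::combn(6, 3), 2, function(ix) {
      m <- seq_len(6) %in% ix
      abs(log(2^(mean(ct_t[m]) - mean(ct_t[!m])) /
                2^(mean(ct_r[m]) - mean(ct_r[!m]))))
    })
    expect_equal(r$p_random, mean(stats >= obs - 1e-12))
  }
})

test_that("zero-noise generation recovers exactly the planted DE set", {
  fams <- setNames(rep(c("FamA", "FamB"), c(10, 10)), sprintf("t%02d", 1:20))
  txs <- c(names(fams), sprintf("n%02d", 1:40))
  plan <- data.frame(family = c("FamA", "FamB"), n_up = c(6, 4),
                     mean_log2FC = c(3, 2.5))
  ex <- genExpressionTables(txs, fams, plan, assays = "a1",
                            noise_sd = 0, ct_noise = 0, seed = 21)
  out <- deFilter(ex$de$a1)
  expect_setequal(out$transcript_id[out$call == "up"],
                  ex$truth$de$a1$transcript_id)
  expect_equal(sum(out$call == "down"), 0)
  # zero-noise Ct closed form: treated Ct = control - log2(ratio)
  ct <- ex$ct
  tgt <- names(ex$truth$ratios)[1]
  ctl <- ct$Ct[ct$gene == tgt & ct$condition == "control"]
  trt <- ct$Ct[ct$gene == tgt & ct$condition == "treated"]
  expect_equal(unique(ctl) - unique(trt), log2(ex$truth$ratios[[tgt]]))
  # and restRatio recovers the planted ratio exactly
  g <- function(gene, cond) ct$Ct[ct$gene == gene & ct$condition == cond]
  rr <- restRatio(g(tgt, "control"), g(tgt, "treated"),
                  list(g("REF_ACT", "control"), g("REF_UBC", "control")),
                  list(g("REF_ACT", "treated"), g("REF_UBC", "treated")))
  expect_equal(rr$ratio, ex$truth$ratios[[tgt]])
})
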