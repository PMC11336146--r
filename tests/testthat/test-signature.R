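## small cohort with two strongly directional genes and one null gene
mkScreenFixture <- function(n = 120, seed = 41) {
  set.seed(seed)
  risk <- rnorm(n)                 # higher -> shorter survival
  prot <- rnorm(n)                 # higher -> longer survival
  null <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(0.9 * risk - 0.9 * prot))
  ev <- rbinom(n, 1, 0.85)
  expr <- rbind(gRisk = 500 + 100 * risk, gProt = 500 + 100 * prot,
                gNull = 500 + 100 * null, gConst = rep(300, n))
  expr <- pmax(expr, 0)
  colnames(expr) <- paste0("s", seq_len(n))
  list(expr = expr, time = tt, event = ev)
}

test_that("the screen weights genes by hazard-ratio direction", {
  f <- mkScreenFixture()
  w <- suppressMessages(screenGenes(f$expr, time = f$time, event = f$event))
  tb <- weightTable(w)
  expect_identical(tb$weight[tb$gene_id == "gRisk"], 1L)   # HR > 1
  expect_identical(tb$weight[tb$gene_id == "gProt"], -1L)  # HR in (0,1)
  expect_identical(tb$weight[tb$gene_id == "gConst"], 0L)
  expect_identical(tb$reason[tb$gene_id == "gConst"], "constant")
  expect_true(all(tb$hr[tb$weight == 1] > 1, na.rm = TRUE))
  expect_true(all(tb$hr[tb$weight == -1] < 1, na.rm = TRUE))
})

test_that("screen weights are invariant under positive affine transforms", {
  f <- mkScreenFixture(seed = 42)
  w1 <- suppressMessages(screenGenes(f$expr, time = f$time, event = f$event))
  expr2 <- f$expr
  expr2["gRisk", ] <- 7 * expr2["gRisk", ] + 250   # same gene, new scale
  w2 <- suppressMessages(screenGenes(expr2, time = f$time, event = f$event))
  expect_identical(weightTable(w1)$weight, weightTable(w2)$weight)
})

test_that("screen errors on misaligned inputs and works on a SurvCohort", {
  f <- mkScreenFixture()
  expect_error(screenGenes(f$expr, time = f$time[-1], event = f$event[-1]),
               "align")
  clin <- data.frame(sample_id = colnames(f$expr), time = f$time,
                     event = f$event, dataset_id = "d1")
  co <- SurvCohort(f$expr, clin)
  w <- suppressMessages(screenGenes(co))
  expect_s4_class(w, "GeneWeights")
})

test_that("scoring is the sign-weighted mean of the stated formula", {
  expr <- matrix(c(800, 200, 100, 100), nrow = 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  w <- fixedSignature(data.frame(gene_id = c("gA", "gB"),
                                 fixed_weight = c(1, -1)))
  sc <- scoreSamples(expr, w)
  expect_equal(unname(sc["s1"]), (800 - 200) / 2)  # direct arithmetic
  expect_equal(unname(sc["s2"]), 0)                # cancellation at equal expr
  ## all weights +1 reduces to the per-sample mean over signature genes
  wp <- fixedSignature(data.frame(gene_id = c("gA", "gB"),
                                  fixed_weight = c(1, 1)))
  expect_equal(unname(scoreSamples(expr, wp)), unname(colMeans(expr)))
})

test_that("scoring is permutation-invariant and linear in expression", {
  set.seed(43)
  expr <- matrix(rexp(50, 1 / 300), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  w <- fixedSignature(data.frame(gene_id = paste0("g", 1:5),
                                 fixed_weight = c(1, -1, 1, 1, -1)))
  sc <- scoreSamples(expr, w)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(scoreSamples(expr[perm, ], w), sc)
  expect_equal(scoreSamples(3 * expr, w), 3 * sc)
})

test_that("scoring skips absent genes and refuses an empty signature", {
  expr <- matrix(1:4, nrow = 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  w <- fixedSignature(data.frame(gene_id = c("gA", "gB", "gX"),
                                 fixed_weight = c(1, -1, 1)))
  expect_message(sc <- scoreSamples(expr, w), "genes_skipped_absent=1")
  expect_length(sc, 2)
  wx <- fixedSignature(data.frame(gene_id = "gZ", fixed_weight = 1))
  expect_error(scoreSamples(expr, wx), "no signature gene")
})

test_that("fixed signatures validate their entries", {
  ok <- fixedSignature(data.frame(gene_id = c("a", "b", "c"),
                                  fixed_weight = c(1, 1, -1)))
  tb <- weightTable(ok)
  expect_identical(nrow(tb), 3L)
  expect_true(all(tb$source == "fixed"))
  expect_true(all(is.na(tb$hr)))
  expect_error(fixedSignature(data.frame(gene_id = "a", fixed_weight = 0)),
               "-1 or \\+1")
  expect_error(fixedSignature(data.frame(gene_id = c("a", "a"),
                                         fixed_weight = c(1, 1))),
               "duplicated")
  expect_error(fixedSignature(data.frame(gene_id = "a",
                                         fixed_weight = NA_real_)),
               "missing")
})

test_that("gene weights serialize to TSV in the supplementary-table shape", {
  f <- mkScreenFixture()
  w <- suppressMessages(screenGenes(f$expr, time = f$time, event = f$event))
  tf <- tempfile(fileext = ".tsv")
  writeGeneWeights(w, tf)
  back <- read.delim(tf)
  expect_identical(colnames(back)[1:7],
                   c("gene_id", "hr", "ci_low", "ci_high", "p", "weight",
                     "source"))
  expect_identical(back$weight, weightTable(w)$weight)
})
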