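smallSim <- function(n_per = 150, n_ds = 3, seed = 61, ...) {
  simulateCohort(simConfig(n_samples = rep(n_per, n_ds), seed = seed, ...))
}

test_that("whole-cohort analysis finds a simulated effect end to end", {
  sim <- smallSim()
  res <- suppressMessages(analyzeCohort(sim$cohort))
  sel <- selectedCutoff(res$scan)
  expect_lt(sel$p_adj, 0.01)
  expect_gt(res$cox$hr, 1)      # high score -> worse outcome by construction
  ## the KM curves separate: high group ends lower than the low group
  expect_lt(min(res$km$high$survival), min(res$km$low$survival))
})

test_that("a tiny cohort fails the scan precondition", {
  expr <- matrix(rexp(9, 1 / 300), nrow = 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  clin <- data.frame(sample_id = paste0("s", 1:3), time = c(1, 2, 3),
                     event = c(1, 1, 0), dataset_id = "d")
  co <- SurvCohort(expr, clin)
  expect_error(suppressMessages(analyzeCohort(co)))
})

test_that("per-dataset replication uses shared weights and re-scans", {
  sim <- smallSim(seed = 62)
  w <- suppressMessages(screenGenes(sim$cohort))
  pd <- suppressMessages(perDataset(sim$cohort, w))
  expect_identical(nrow(pd), 3L)
  expect_true(all(pd$direction_consistent))
  ## restriction property: single-dataset analyzeCohort equals the
  ## per-dataset row computed with the same shared weights
  d1 <- sim$cohort[, colData(sim$cohort)$dataset_id == "dataset01"]
  res1 <- suppressMessages(analyzeCohort(d1, weights = w))
  sel1 <- selectedCutoff(res1$scan)
  row1 <- pd[pd$dataset_id == "dataset01", ]
  expect_equal(row1$cutoff, sel1$cutoff)
  expect_equal(row1$hr, res1$cox$hr)
  expect_equal(row1$p, res1$cox$p)
})

test_that("insufficient datasets are excluded and named", {
  sim <- smallSim(seed = 63)
  w <- suppressMessages(screenGenes(sim$cohort))
  cd <- clinicalData(sim$cohort)
  ## shrink dataset03 to 8 samples
  keep <- cd$dataset_id != "dataset03" |
    cd$sample_id %in% head(cd$sample_id[cd$dataset_id == "dataset03"], 8)
  sub <- sim$cohort[, keep]
  pd <- suppressMessages(perDataset(sub, w))
  excl <- attr(pd, "excluded")
  expect_identical(excl$dataset_id, "dataset03")
  expect_identical(excl$reason, "too_few_samples")
  ## a dataset with zero events is excluded too
  cd2 <- clinicalData(sim$cohort)
  cd2$event[cd2$dataset_id == "dataset02"] <- 0
  co2 <- SurvCohort(SummarizedExperiment::assay(sim$cohort, "exprs"), cd2)
  pd2 <- suppressMessages(perDataset(co2, w))
  expect_true("dataset02" %in% attr(pd2, "excluded")$dataset_id)
})

test_that("covariate encodings follow the declared scheme", {
  clin <- data.frame(sex = c("female", "male", NA),
                     msi = c("stable", "stable_or_low", "high"),
                     stage = c("1", "4", NA),
                     t_stage = c("2", "3", "4"))
  expect_equal(encodeCovariate(clin, "sex"), c(0, 1, NA))
  expect_equal(encodeCovariate(clin, "msi"), c(0, 0.5, 2))
  expect_equal(encodeCovariate(clin, "stage"), c(1, 4, NA))
  expect_equal(encodeCovariate(clin, "t_stage"), c(2, 3, 4))
  expect_error(encodeCovariate(clin, "grade"), "not present")
})

pairedFixture <- function(n = 400, beta_score = 0.7, seed = 64) {
  set.seed(seed)
  scores <- rnorm(n)
  cutoff <- median(scores)
  hi <- as.numeric(scores > cutoff)
  sex <- sample(c("female", "male"), n, replace = TRUE)  # independent of hazard
  tt <- rexp(n, 0.02 * exp(beta_score * hi))
  cmax <- quantile(tt, 0.6)
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     time = pmin(tt, cmax), event = as.numeric(tt <= cmax),
                     dataset_id = "d", sex = sex)
  list(scores = setNames(scores, clin$sample_id), clin = clin,
       cutoff = cutoff)
}

test_that("the paired model keeps the signature and ignores a null covariate", {
  sig_hits <- 0; cov_hits <- 0
  for (seed in 1:10) {
    f <- pairedFixture(seed = 64 + seed)
    res <- pairedMultivariate(f$scores, f$clin, "sex", f$cutoff)
    expect_identical(res$n_complete, nrow(f$clin))
    sig_hits <- sig_hits + (res$signature$p < 0.05)
    cov_hits <- cov_hits + (res$covariate$p < 0.05)
  }
  expect_gte(sig_hits, 8)    # power >= 80% at n = 400, beta = 0.7
  expect_lte(cov_hits, 3)    # null covariate stays null
})

test_that("paired-model degeneracies are flagged, not silently fit", {
  f <- pairedFixture()
  f$clin$sex <- NA_character_
  expect_error(pairedMultivariate(f$scores, f$clin, "sex", f$cutoff),
               "missing for every sample")
  f2 <- pairedFixture()
  f2$clin$sex <- ifelse(f2$scores > f2$cutoff, "male", "female")
  expect_error(pairedMultivariate(f2$scores, f2$clin, "sex", f2$cutoff),
               "collinear")
  f3 <- pairedFixture()
  f3$clin$sex <- "male"
  expect_error(pairedMultivariate(f3$scores, f3$clin, "sex", f3$cutoff),
               "constant")
})

test_that("paired signature HR is consistent with the univariate HR", {
  f <- pairedFixture(n = 2000, seed = 66)
  hi <- as.numeric(f$scores > f$cutoff)
  uni <- coxFit(hi, f$clin$time, f$clin$event)
  res <- pairedMultivariate(f$scores, f$clin, "sex", f$cutoff)
  expect_lt(abs(res$signature$hr - uni$hr) / uni$hr, 0.15)
})

test_that("the pairing loop reports one row per usable covariate", {
  sim <- smallSim(seed = 67)
  cd <- simulateClinicalCovariates(clinicalData(sim$cohort), seed = 68)
  co <- SurvCohort(SummarizedExperiment::assay(sim$cohort, "exprs"), cd)
  w <- suppressMessages(screenGenes(co))
  sc <- scoreSamples(co, w)
  scan <- scanCutoffs(sc, cd$time, cd$event)
  paired <- suppressMessages(
    pairedMultivariateAll(sc, clinicalData(co), selectedCutoff(scan)$cutoff))
  expect_true(all(paired$covariate %in% names(clinicalVocabulary())))
  expect_gte(nrow(paired), 6)
  expect_true(all(paired$hr_signature > 0))
})
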