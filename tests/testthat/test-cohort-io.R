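writeTSV <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("expression reader round-trips and canonicalizes orientation", {
  tf <- writeTSV(c("sample_id\tMKI67\tCDKN1A",
                   "s1\t100.5\t200", "s2\t150\t250", "s3\t120\t0"))
  m <- readExpression(tf)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(rownames(m), c("MKI67", "CDKN1A"))
  expect_identical(m["MKI67", "s1"], 100.5)
  expect_identical(m["CDKN1A", "s3"], 0)

  ## transpose oracle: the same data laid out genes-in-rows reads equal
  tg <- writeTSV(c("gene_id\ts1\ts2\ts3",
                   "MKI67\t100.5\t150\t120", "CDKN1A\t200\t250\t0"))
  expect_identical(readExpression(tg, orientation = "genes_by_samples"), m)

  ## write-then-read reproduces values bit-identically
  out <- tempfile(fileext = ".tsv")
  writeExpression(m, out)
  expect_identical(readExpression(out), m)
})

test_that("expression reader rejects malformed input with locations", {
  dup <- writeTSV(c("sample_id\tMKI67\tMKI67", "s1\t1\t2", "s2\t3\t4"))
  expect_error(readExpression(dup), "MKI67")
  neg <- writeTSV(c("sample_id\tA\tB", "s1\t1\t-2", "s2\t3\t4"))
  expect_error(readExpression(neg), "negative.*'s1'.*'B'")
  txt <- writeTSV(c("sample_id\tA\tB", "s1\t1\tx", "s2\t3\t4"))
  expect_error(readExpression(txt), "non-numeric.*'s1'.*'B'")
})

test_that("expression reader accepts CSV and gzip variants", {
  cf <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,A,B", "s1,1,2", "s2,3,4"), cf)
  m <- readExpression(cf)
  expect_equal(unname(m["A", ]), c(1, 3))
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w")
  writeLines(c("sample_id\tA\tB", "s1\t1\t2", "s2\t3\t4"), con)
  close(con)
  expect_identical(unname(readExpression(gz)["B", "s2"]), 4)
})

test_that("clinical reader keeps missing covariates as NA, never drops rows", {
  tf <- writeTSV(c("sample_id\ttime\tevent\tdataset_id\tmsi",
                   "s1\t12.5\t1\td1\thigh",
                   "s2\t30\t0\td1\t",
                   "s3\t8\t0\td2\tNA",
                   "s4\t40\t0\td2\tnan"))
  clin <- readClinical(tf)
  expect_identical(nrow(clin), 4L)        # accepted = input row count
  expect_identical(clin$msi, c("high", NA, NA, NA))
  expect_identical(clin$time[1], 12.5)
})

test_that("clinical reader enforces invariants and vocabulary", {
  t0 <- writeTSV(c("sample_id\ttime\tevent", "s1\t0\t1"))
  expect_error(readClinical(t0), "non-positive.*'s1'")
  bad_ev <- writeTSV(c("sample_id\ttime\tevent", "s1\t5\t2"))
  expect_error(readClinical(bad_ev), "event")
  drift <- writeTSV(c("sample_id\ttime\tevent\tmsi", "s1\t5\t1\tMSS"))
  expect_error(readClinical(drift), "unknown level 'MSS'")
  ## a fully censored cohort is legal
  cens <- writeTSV(c("sample_id\ttime\tevent", "s1\t5\t0", "s2\t7\t0"))
  expect_identical(sum(readClinical(cens)$event), 0)
})

test_that("clinical summary computes percentages over non-missing records", {
  clin <- data.frame(
    sex = c(rep("male", 492), rep("female", 435)),
    n_stage = c(rep("0", 257), rep("1", 138), rep("2", 87), rep("3", 4),
                rep(NA, 441)))
  s <- clinicalSummary(clin)
  expect_equal(s$percent[s$feature == "sex" & s$level == "male"], 53.07)
  expect_equal(s$percent[s$feature == "n_stage" & s$level == "0"], 52.88)
  expect_equal(sum(s$count[s$feature == "n_stage"]), 486)
  ## per-feature percentages sum to 100 within rounding slack
  for (f in unique(s$feature))
    expect_lt(abs(sum(s$percent[s$feature == f]) - 100), 0.05)
  ## single category normalizes to 100.00
  one <- clinicalSummary(data.frame(location = rep("distal", 7)))
  expect_identical(one$percent, 100)
})

test_that("clinical table round-trips through TSV", {
  clin <- data.frame(sample_id = c("a", "b"), time = c(1.25, 33.333333),
                     event = c(1, 0), dataset_id = "d1",
                     msi = c(NA, "high"), stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  writeClinical(clin, tf)
  back <- readClinical(tf)
  expect_identical(back$time, clin$time)
  expect_identical(back$msi, clin$msi)
})

test_that("gene list reader parses ids, probes and fixed weights", {
  tf <- writeTSV(c("gene\tprobe\tweight", "CDKN1A\t202284_s_at\t1",
                   "MKI67\t212021_s_at\t-1"))
  gl <- readGeneList(tf)
  expect_identical(gl$gene_id, c("CDKN1A", "MKI67"))
  expect_identical(gl$fixed_weight, c(1, -1))
  dup <- writeTSV(c("gene", "A", "A"))
  expect_error(readGeneList(dup), "duplicated")
  bad <- writeTSV(c("gene\tweight", "A\t0"))
  expect_error(readGeneList(bad), "-1 or \\+1")
})
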