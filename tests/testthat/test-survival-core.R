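test_that("Kaplan-Meier matches the hand product-limit on small fixtures", {
  ## single event: the curve drops to zero at its time
  km1 <- kmEstimate(5, 1)
  expect_equal(km1$survival, 0)
  ## [1,2,3] with the middle subject censored: S(1)=2/3, S(3)=(2/3)*0=0
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  ## fully censored cohort: no drops, S stays at 1
  expect_identical(nrow(kmEstimate(c(2, 4, 6), c(0, 0, 0))), 0L)
})

test_that("Kaplan-Meier equals the hand oracle under random censoring", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1   # provoke ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) next
    got <- kmEstimate(time, event)
    want <- handKM(time, event)
    expect_equal(got$time, want$time)
    expect_equal(got$survival, want$survival)
  }
})

test_that("Kaplan-Meier is 1 - ECDF when there is no censoring", {
  set.seed(32)
  time <- rexp(60, 0.05)
  km <- kmEstimate(time, rep(1, 60))
  expect_equal(km$survival, 1 - ecdf(time)(km$time))
})

test_that("log-rank matches the brute-force O-E/V accumulation", {
  ## two identical groups: statistic 0, p 1
  lr0 <- logrankTest(rep(0:1, each = 3), rep(c(1, 2, 3), 2),
                     rep(c(1, 0, 1), 2))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p, 1)
  ## the 4-subject all-event fixture against the hand table
  g <- c(0, 0, 1, 1); tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1)
  got <- logrankTest(g, tt, ev)
  want <- bruteLogrank(g, tt, ev)
  expect_equal(got$chi_square, want$chi_square, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  ## random small fixtures (distinct times)
  set.seed(33)
  for (rep in 1:20) {
    n <- 2 * sample(3:15, 1)
    g <- rep(0:1, n / 2)
    tt <- sample(seq_len(1000), n) / 10
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    want <- bruteLogrank(g, tt, ev)
    if (!is.finite(want$chi_square)) next   # degenerate O-E/V table
    got <- logrankTest(g, tt, ev)
    expect_equal(got$chi_square, want$chi_square, tolerance = 1e-9)
  }
  expect_error(logrankTest(g, tt, rep(0, n)), "event")
})

test_that("Cox beta equals the grid-search partial-likelihood argmax", {
  fixtures <- list(
    list(x = c(0, 0, 0, 1, 1, 1), time = c(2, 5, 9, 1, 3, 7),
         event = c(1, 1, 0, 1, 1, 1)),
    list(x = c(0.2, -1.3, 0.8, 2.1, -0.4), time = c(1, 8, 2, 4, 6),
         event = c(1, 0, 1, 1, 1)),
    list(x = c(1, 2, 3, 4), time = c(2, 4, 1, 3), event = c(1, 1, 1, 1)))
  for (f in fixtures) {
    fit <- coxFit(f$x, f$time, f$event)
    oracle <- gridCoxBeta(f$x, f$time, f$event)
    expect_equal(fit$beta, oracle, tolerance = 1e-3)
    expect_equal(fit$hr, exp(fit$beta))
    expect_equal(fit$ci_low, exp(fit$beta - 1.959964 * fit$se))
    expect_equal(fit$ci_high, exp(fit$beta + 1.959964 * fit$se))
  }
})

test_that("Cox fit recovers a known rate ratio from simulation", {
  set.seed(35)
  d <- simTwoGroup(5000, hr = 2)
  fit <- coxFit(d$group, d$time, d$event)
  expect_gt(fit$hr, 1.85)
  expect_lt(fit$hr, 2.15)
})

test_that("Cox HR is invariant under positive affine covariate rescaling", {
  set.seed(36)
  x <- rnorm(120)
  tt <- rexp(120, 0.05 * exp(0.6 * x))
  ev <- rbinom(120, 1, 0.8)
  f1 <- coxFit(x, tt, ev)
  f2 <- coxFit(10 * x + 3, tt, ev)
  expect_equal(f2$beta, f1$beta / 10, tolerance = 1e-6)
  expect_equal(sign(log(f2$hr)), sign(log(f1$hr)))
  expect_equal(f2$p, f1$p, tolerance = 1e-6)
})

test_that("degenerate Cox inputs error or are flagged, never silent", {
  expect_error(coxFit(rep(1, 10), rexp(10) + 0.1, rep(1, 10)), "constant")
  ## perfect separation: monotone likelihood is flagged, not a crash
  x <- c(0, 0, 0, 1, 1, 1)
  tt <- c(1, 2, 3, 10, 11, 12)
  fit <- coxFit(x, tt, rep(1, 6))
  expect_false(fit$converged)
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(37)
  ps <- replicate(1000, {
    d <- simTwoGroup(60, hr = 1, censor_at = 30)
    logrankTest(d$group, d$time, d$event)$p
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) / length(ps))))
  expect_lt(ks, 0.05)
})

test_that("two-group Cox and log-rank agree on non-degenerate data", {
  set.seed(38)
  for (rep in 1:10) {
    d <- simTwoGroup(200, hr = 1.8, censor_at = 25)
    fit <- coxFit(d$group, d$time, d$event)
    lr <- logrankTest(d$group, d$time, d$event)
    expect_lt(abs(log10(fit$p) - log10(lr$p)), 0.5)
    expect_equal(fit$hr > 1, TRUE)
  }
})
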