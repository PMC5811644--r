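test_that("expected relative yields are the planted fractions", {
  d <- build_default_design()
  expect_equal(unname(expected_relative_yields(d$treatments[12, ])),
               rep(0.25, 4))
  expect_equal(unname(expected_relative_yields(d$treatments[6, ])),
               rep(0.5, 2))
  expect_equal(unname(expected_relative_yields(d$treatments[2, ])), 1)
  expect_error(expected_relative_yields(d$treatments[1, ]), "bare")
})

test_that("partition reproduces the hand-worked example and algebraic identities", {
  # dRY = (+0.25, -0.25): mean 0 so CE = 0; SE carries the whole effect
  pr <- partition(c(A = 4, B = 2), c(A = 3, B = 0.5))
  expect_equal(pr$delta_Y, 0.5)
  expect_equal(pr$CE, 0)
  expect_equal(pr$SE, 0.5)

  # proportional replacement is exactly (0, 0, 0)
  M <- c(M = 3.54, P = 3.54, C = 0.48, U = 0.48)
  pr0 <- partition(M, M / 4)
  expect_identical(c(pr0$delta_Y, pr0$CE, pr0$SE), c(0, 0, 0))

  # uniform inflation with equal M: CE = f * Y_E, SE = 0
  f <- 0.292
  Me <- c(a = 2, b = 2, c = 2)
  pre <- partition(Me, (1 + f) * Me / 3)
  expect_equal(pre$CE, f * pre$Y_E, tolerance = 1e-12)
  expect_equal(pre$SE, 0, tolerance = 1e-12)

  expect_error(partition(c(A = 0, B = 1), c(A = 1, B = 1)), "A")
  expect_error(partition(c(A = 1, B = 1), c(A = 1, X = 1)), "match")
})

test_that("partition properties: additivity, scale equivariance, SE sign", {
  set.seed(31)
  for (i in 1:300) {
    N <- sample(2:6, 1)
    sp <- paste0("s", seq_len(N))
    M <- setNames(runif(N, 0.1, 5), sp)
    Yo <- setNames(runif(N, 0, 3), sp)
    pr <- partition(M, Yo)
    expect_equal(pr$CE + pr$SE, pr$delta_Y,
                 tolerance = 1e-10 * max(1, abs(pr$delta_Y)))
    # scale equivariance
    a <- runif(1, 0.1, 10)
    pra <- partition(a * M, a * Yo)
    expect_equal(c(pra$delta_Y, pra$CE, pra$SE),
                 a * c(pr$delta_Y, pr$CE, pr$SE), tolerance = 1e-9)
    # SE sign matches a direct population-covariance oracle
    dRY <- Yo / M - 1 / N
    cov_pop <- mean((dRY - mean(dRY)) * (M - mean(M)))
    expect_equal(sign(pr$SE), sign(N * cov_pop))
  }
})

test_that("partition_experiment handles defaults, per-block pairing and edge cases", {
  recs <- simulate_experiment(calibrated_scenario(13))
  d <- build_default_design()
  p <- partition_experiment(recs, d)
  expect_equal(nrow(p$units), 7 * 6)  # 7 mixture treatments x 6 blocks
  expect_equal(p$units$delta_Y, p$units$CE + p$units$SE, tolerance = 1e-10)
  expect_equal(sort(unique(p$summary$treatment_id)), 6:12)

  pb <- partition_experiment(recs, d, per_block = TRUE)
  expect_equal(nrow(pb$units), 42)
  expect_false(isTRUE(all.equal(p$units$CE, pb$units$CE)))

  # no mixtures -> empty result
  mono_only <- recs[recs$treatment_id <= 5, ]
  d_mono <- d
  d_mono$treatments <- d$treatments[1:5, ]
  expect_equal(nrow(partition_experiment(mono_only, d_mono)$units), 0)

  # missing monoculture -> error
  no_M <- recs[recs$treatment_id != 2, ]
  expect_error(partition_experiment(no_M, d), "monoculture")
})

test_that("selection-dominated generator yields positive SE and small CE", {
  # redistributive rooted dominance 1.6 / non-rooted 0.4, no boost: the
  # generator's ground truth has mean(dRY) = 0 (CE = 0) and cov(dRY, M) > 0
  sc <- calibrated_scenario(77)
  sc$mixture_dominance <- c(M = 1.6, P = 1.6, C = 0.4, U = 0.4)
  ses <- ces <- numeric(30)
  for (i in 1:30) {
    sc$seed <- 600 + i
    p <- partition_experiment(simulate_experiment(sc))
    u <- p$units[p$units$treatment_id == 12, ]
    ses[i] <- mean(u$SE); ces[i] <- mean(u$CE)
  }
  expect_gt(mean(ses), 0)
  expect_lt(abs(mean(ces)), mean(ses))
})

test_that("percent overyield is the relative excess over the mean monoculture", {
  M <- c(3.54, 3.54, 0.48, 0.48)
  expect_equal(percent_overyield(mean(M), M), 0)
  expect_equal(percent_overyield(2 * mean(M), M), 100)
  expect_equal(round(percent_overyield(2.597, M), 1), 29.2)
  expect_error(percent_overyield(1, numeric(0)))
  expect_error(percent_overyield(1, c(0, 0)), "positive")
})
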