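test_that("zero block signal collapses to OLS with a boundary flag", {
  # balanced layout with all block means forced equal
  d <- toy_lmm_data(seed = 3, blocks = 4, k = 2, reps = 3,
                    effects = c(0, 1), block_sd = 0, resid_sd = 0.5)
  d$y <- d$y - ave(d$y, d$block) + mean(d$y)  # remove block means exactly
  fit <- fit_lmm(model_spec("y", "g", reference = "a"), d)
  expect_true(fit$boundary)
  expect_equal(fit$sigma2_block, 0)
  ols <- lm(y ~ relevel(factor(g), "a"), d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-9)
})

test_that("REML on balanced one-way layouts equals ANOVA closed forms", {
  for (s in c(2, 5, 9)) {
    set.seed(s)
    blocks <- 6; per <- 12
    bl <- rep(seq_len(blocks), each = per)
    y <- 3 + rnorm(blocks, 0, 0.5)[bl] + rnorm(blocks * per, 0, 0.8)
    fit <- lmm_profile_fit(y, intercept_only(length(y)), factor(bl), "REML")
    msb <- per * var(tapply(y, bl, mean))
    msw <- mean(tapply(y, bl, var))
    expect_equal(fit$sigma2_block, max(0, (msb - msw) / per),
                 tolerance = 1e-8)
    expect_equal(fit$sigma2_resid, if (fit$boundary) var(y) else msw,
                 tolerance = 1e-8)
  }
})

test_that("profile fit matches a direct dense-likelihood oracle", {
  for (s in 1:3) {
    d <- toy_lmm_data(seed = s)
    X <- model.matrix(~ relevel(factor(d$g), "a"))
    fit <- lmm_profile_fit(d$y, X, factor(d$block), "ML")
    orc <- oracle_lmm_ml(d$y, X, d$block)
    expect_equal(fit$loglik_ML, orc$loglik, tolerance = 1e-6)
    expect_gte(fit$loglik_ML, orc$loglik - 1e-6)
  }
})

test_that("lrt guards its preconditions and degenerates correctly", {
  d <- toy_lmm_data(seed = 4)
  spec <- model_spec("y", "g", reference = "a")
  full_ml <- fit_lmm(spec, d, "ML")
  null_ml <- lmm_profile_fit(d$y, intercept_only(nrow(d)), factor(d$block),
                             "ML")
  res <- lrt(full_ml, null_ml)
  expect_equal(res$df, 2)
  expect_true(res$p < 1 && res$statistic > 0)

  same <- lrt(full_ml, full_ml)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_error(lrt(fit_lmm(spec, d, "REML"), null_ml), "ML")
})

test_that("contrasts against the reference recover simulated effects", {
  d <- toy_lmm_data(seed = 6, blocks = 6, k = 3, reps = 6,
                    effects = c(0, -0.8, 0))
  fit <- fit_lmm(model_spec("y", "g", reference = "a"), d)
  ct <- contrasts_vs_reference(fit)
  expect_equal(ct$level, c("b", "c"))
  expect_equal(ct$t, ct$estimate / ct$se)
  expect_lt(ct$estimate[ct$level == "b"], 0)
  expect_lt(ct$p[ct$level == "b"], 0.05)
  expect_gt(ct$p[ct$level == "c"], 0.05)
})

test_that("tukey_pairwise matches the studentized-range distribution on balanced data", {
  d <- toy_lmm_data(seed = 8, blocks = 5, k = 3, reps = 4,
                    effects = c(0, 0.9, -0.2), block_sd = 0)
  fit <- fit_lmm(model_spec("y", "g", reference = "a"), d)
  tk <- tukey_pairwise(fit)
  expect_equal(nrow(tk), 3)
  # direct oracle: balanced boundary fit equals OLS, so q has its classic form
  expect_true(fit$boundary || fit$sigma2_block < 1e-6)
  mse <- fit$sigma2_resid
  nper <- nrow(d) / 3
  means <- tapply(d$y, d$g, mean)
  df <- fit$df_containment
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(tk$pair[i], " - ")[[1]]
    lab <- ifelse(pair == "(ref)", "a", pair)
    q_direct <- abs(diff(means[lab])) / sqrt(mse / nper)
    expect_equal(tk$statistic[i], unname(q_direct), tolerance = 1e-8)
    expect_equal(tk$p_tukey[i],
                 ptukey(unname(q_direct), 3, df, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  # k = 4 levels -> 6 comparisons, threshold 0.05/6
  d4 <- toy_lmm_data(seed = 9, blocks = 5, k = 4, reps = 3,
                     effects = c(0, 0.3, -0.3, 0.6))
  tk4 <- tukey_pairwise(fit_lmm(model_spec("y", "g", reference = "a"), d4))
  expect_equal(nrow(tk4), 6)
  expect_equal(attr(tk4, "n_comparisons"), 6)
  expect_equal(round(attr(tk4, "bonferroni_threshold"), 3), 0.008)

  # two identical groups: near-1 tukey p
  did <- data.frame(block = rep(1:5, 4), g = rep(c("a", "b"), each = 10))
  set.seed(10); did$y <- rnorm(20)
  did$y[did$g == "b"] <- did$y[did$g == "a"]
  tid <- tukey_pairwise(fit_lmm(model_spec("y", "g", reference = "a"), did))
  expect_gt(tid$p_tukey[1], 0.99)
})

test_that("logistic GLMM reduces to plain logistic regression without block signal", {
  set.seed(12)
  n <- 120
  d <- data.frame(block = rep(1:6, each = 20), x = rnorm(n))
  d$z <- rbinom(n, 1, plogis(-0.3 + 1.2 * d$x))  # no block effect
  fit <- fit_logistic_glmm(model_spec("z", "x", fixed_type = "numeric"), d)
  glmfit <- glm(z ~ x, binomial, d)
  if (fit$boundary) {
    expect_equal(unname(fit$beta), unname(coef(glmfit)), tolerance = 1e-6)
  } else {
    # tiny estimated variance: coefficients still near the glm oracle
    expect_lt(fit$sigma2_block, 0.2)
    expect_equal(unname(fit$beta), unname(coef(glmfit)), tolerance = 0.1)
  }
  expect_equal(fit$loglik, as.numeric(logLik(glmfit)), tolerance = 0.05)

  # constant response -> degenerate flagged, no crash
  d$z1 <- 1L
  degen <- fit_logistic_glmm(model_spec("z1", "x", fixed_type = "numeric"), d)
  expect_true(degen$degenerate)
  expect_true(degen$separation)
})

test_that("logistic GLMM recovers a negative biomass effect on colonization", {
  hits <- vapply(1:40, function(i) {
    recs <- add_design_factors(simulate_experiment(calibrated_scenario(i)))
    fit <- fit_logistic_glmm(
      model_spec("colonized", "total_native", fixed_type = "numeric"), recs)
    unname(fit$beta["total_native"]) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hurdle analysis dispatches its two stages correctly", {
  recs <- add_design_factors(simulate_experiment(calibrated_scenario(2)))
  h <- hurdle_analysis(model_spec("invader_root", "richness",
                                  fixed_type = "numeric"), recs)
  expect_equal(h$n_zero + h$n_positive, 72)
  expect_false(h$stage2_skipped)
  expect_s3_class(h$stage1, "glmm_fit")
  expect_s3_class(h$stage2, "lmm_fit")
  expect_true(is.list(h$lrt_stage1) && is.list(h$lrt_stage2))

  # all-positive response: stage 1 degenerate, stage 2 equals plain LMM on log
  recs$allpos <- recs$invader_shoot
  hp <- hurdle_analysis(model_spec("allpos", "richness",
                                   fixed_type = "numeric"), recs)
  expect_true(hp$stage1$degenerate)
  ref <- fit_lmm(model_spec("allpos", "richness", fixed_type = "numeric",
                            log_transform = TRUE), recs)
  expect_equal(hp$stage2$beta, ref$beta)

  # all-zero response: stage 2 skipped
  recs$zeros <- 0
  hz <- hurdle_analysis(model_spec("zeros", "richness",
                                   fixed_type = "numeric"), recs)
  expect_true(hz$stage2_skipped)
  expect_equal(hz$n_positive, 0)
})
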