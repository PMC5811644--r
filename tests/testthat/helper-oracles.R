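# Independent oracles and small fixture builders used across the suite.

# exhaustive-enumeration oracle for the two-sided exact test, built on
# stats::dhyper (independent of the package's log-factorial path)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# dense grid search oracle for the conditional-MLE odds ratio
oracle_cmle_grid <- function(t2, grid = seq(-10, 10, length.out = 2001)) {
  ll <- vapply(grid, function(lp) conditional_loglik(t2, lp), numeric(1))
  grid[which.max(ll)]
}

random_table2x2 <- function(max_total = 40) {
  repeat {
    n <- sample(4:max_total, 1)
    a <- sample(0:n, 1)
    rest <- n - a
    b <- if (rest > 0) sample(0:rest, 1) else 0
    rest <- rest - b
    cc <- if (rest > 0) sample(0:rest, 1) else 0
    d <- rest - cc
    if ((a + b) > 0 && (cc + d) > 0 && (a + cc) > 0 && (b + d) > 0)
      return(table2x2(a, b, cc, d))
  }
}

# direct full-likelihood LMM oracle: dense covariance, grid + Nelder-Mead
# polish over the two log-variances (GLS for the fixed effects via dense
# solves -- an independent code path from the package's blockwise profile)
oracle_lmm_ml <- function(y, X, block) {
  Z <- stats::model.matrix(~ 0 + factor(block))
  n <- length(y)
  ll <- function(par) {
    s2b <- exp(par[1]); s2e <- exp(par[2])
    V <- s2e * diag(n) + s2b * tcrossprod(Z)
    ch <- chol(V)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - drop(X %*% beta)
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r * Vi_r))
  }
  grid <- expand.grid(lb = seq(-8, 3, length.out = 15),
                      le = seq(-8, 3, length.out = 15))
  vals <- apply(grid, 1, ll)
  start <- as.numeric(grid[which.max(vals), ])
  opt <- stats::optim(start, function(p) -ll(p), method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(loglik = -opt$value, par = opt$par)
}

# toy dataset for mixed-model tests: b blocks x k groups x r reps
toy_lmm_data <- function(seed = 1, blocks = 5, k = 3, reps = 4,
                         effects = c(0, 0.8, -0.5), block_sd = 0.5,
                         resid_sd = 0.7) {
  set.seed(seed)
  d <- expand.grid(block = seq_len(blocks), rep = seq_len(reps),
                   g = letters[seq_len(k)])
  d$y <- 2 + effects[match(d$g, letters)] +
    stats::rnorm(blocks, 0, block_sd)[d$block] +
    stats::rnorm(nrow(d), 0, resid_sd)
  d
}

intercept_only <- function(n) {
  matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
}

fit_lrt_richness <- function(records, response = "invader_shoot",
                             log_transform = TRUE) {
  spec <- model_spec(response, "richness", fixed_type = "factor",
                     reference = "0", log_transform = log_transform)
  full <- fit_lmm(spec, records, criterion = "ML")
  mf <- mesoinvade:::build_model_frame(spec, records)
  null <- lmm_profile_fit(mf$y, intercept_only(nrow(records)), mf$block,
                          criterion = "ML")
  lrt(full, null)
}
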