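#' Specify a mixed model
#'
#' All models share one structure: a response (optionally natural-log
#' transformed), one fixed factor or numeric covariate, and a single random
#' intercept for block.
#'
#' @param response Column name of the response.
#' @param fixed Column name of the fixed effect.
#' @param fixed_type `"factor"` (treatment contrasts against `reference`) or
#'   `"numeric"` (linear trend).
#' @param reference Reference level when `fixed_type = "factor"`; defaults to
#'   the first level in sort order.
#' @param log_transform Natural-log transform the response (requires
#'   positive values).
#' @param random Grouping column for the random intercept (default
#'   `"block"`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, fixed, fixed_type = c("factor", "numeric"),
                       reference = NULL, log_transform = FALSE,
                       random = "block") {
  fixed_type <- match.arg(fixed_type)
  structure(list(response = response, fixed = fixed,
                 fixed_type = fixed_type, reference = reference,
                 log_transform = log_transform, random = random),
            class = "model_spec")
}

build_model_frame <- function(spec, data) {
  for (nm in c(spec$response, spec$fixed, spec$random))
    if (!nm %in% names(data)) stop("column not found: ", nm)
  y <- data[[spec$response]]
  if (spec$log_transform) {
    if (any(y <= 0)) stop("log transform requires a positive response")
    y <- log(y)
  }
  if (any(!is.finite(y))) stop("response not finite after transform")
  block <- factor(data[[spec$random]])
  if (nlevels(block) < 2) stop("need at least 2 blocks")
  if (spec$fixed_type == "factor") {
    f <- factor(data[[spec$fixed]])
    ref <- if (is.null(spec$reference)) levels(f)[1] else
      as.character(spec$reference)
    if (!ref %in% levels(f)) stop("reference level not present: ", ref)
    f <- stats::relevel(f, ref = ref)
    X <- stats::model.matrix(~f)
    colnames(X) <- c("(Intercept)", levels(f)[-1])
  } else {
    X <- cbind(`(Intercept)` = 1, stats::setNames(
      data.frame(as.numeric(data[[spec$fixed]])), spec$fixed))
    X <- as.matrix(X)
    colnames(X) <- c("(Intercept)", spec$fixed)
  }
  list(y = y, X = X, block = block)
}

# GLS pieces for the compound-symmetric random-intercept model at variance
# ratio lambda = sigma2_block / sigma2_resid: W = (I + lambda Z Z')^{-1}
# applied blockwise, (Wv)_j = v_j - lambda/(1 + n_j lambda) * sum(v_j)
lmm_gls <- function(y, X, block_idx, n_per_block, lambda) {
  wmult <- function(v) {
    s <- rowsum(v, block_idx, reorder = TRUE)
    shrink <- lambda / (1 + n_per_block * lambda)
    v - (shrink * s)[block_idx, , drop = FALSE]
  }
  WX <- wmult(X)
  Wy <- wmult(matrix(y, ncol = 1))
  A <- crossprod(X, WX)
  beta <- solve(A, crossprod(X, Wy))
  resid <- y - drop(X %*% beta)
  rssw <- sum(resid * drop(wmult(matrix(resid, ncol = 1))))
  list(beta = drop(beta), A = A, rssw = rssw, resid = resid,
       logdet = sum(log(1 + n_per_block * lambda)))
}

lmm_objective <- function(y, X, block_idx, n_per_block, lambda, criterion) {
  n <- length(y); p <- ncol(X)
  g <- lmm_gls(y, X, block_idx, n_per_block, lambda)
  if (criterion == "ML") {
    s2 <- g$rssw / n
    -0.5 * (n * log(2 * pi * s2) + g$logdet + n)
  } else {
    s2 <- g$rssw / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + g$logdet +
              determinant(g$A, logarithm = TRUE)$modulus + (n - p))
  }
}

# analytic d(loglik)/d(lambda) at the profiled GLS solution; the envelope
# theorem removes the d(beta)/d(lambda) term
lmm_score <- function(y, X, block_idx, n_per_block, lambda, criterion) {
  n <- length(y); p <- ncol(X)
  g <- lmm_gls(y, X, block_idx, n_per_block, lambda)
  S <- rowsum(g$resid, block_idx, reorder = TRUE)  # block residual sums
  shr <- 1 / (1 + n_per_block * lambda)
  drss <- -sum(S^2 * shr^2)
  dlogdet <- sum(n_per_block * shr)
  if (criterion == "ML") {
    -0.5 * (n * drss / g$rssw + dlogdet)
  } else {
    U <- rowsum(X, block_idx, reorder = TRUE)      # block sums of X rows
    Ainv <- solve(g$A)
    dlogdetA <- -sum((U %*% Ainv) * U * shr^2)
    -0.5 * ((n - p) * drss / g$rssw + dlogdet + dlogdetA)
  }
}

#' Fit a random-intercept linear mixed model by profile likelihood
#'
#' For the single-random-intercept model, fixed effects and the residual
#' variance have closed forms given the variance ratio
#' `lambda = sigma2_block / sigma2_resid` (generalized least squares with a
#' compound-symmetric per-block covariance), so the likelihood is profiled
#' down to a 1-D bounded search over `log(lambda)` on \[-20, 20\]. Both ML
#' and REML objectives are maximized; estimates and standard errors are
#' reported at the requested criterion. A ratio at the lower search boundary
#' is flagged and the fit collapses to ordinary least squares.
#'
#' @param spec A [model_spec()].
#' @param data Data.frame with the spec's columns.
#' @param criterion `"REML"` (default) or `"ML"` for reported estimates.
#' @return Object of class `lmm_fit`: `beta`, `se`, `vcov_beta`,
#'   `sigma2_block`, `sigma2_resid`, `loglik_ML`, `loglik_REML`, `loglik`
#'   (at `criterion`), `fitted`, `residuals`, `df_containment`, `boundary`,
#'   `n_params_fixed`, plus the model frame.
#' @export
fit_lmm <- function(spec, data, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  mf <- build_model_frame(spec, data)
  fit <- lmm_profile_fit(mf$y, mf$X, mf$block, criterion)
  fit$spec <- spec
  fit
}

#' @rdname fit_lmm
#' @param y Numeric response vector.
#' @param X Design matrix (with intercept column).
#' @param block Factor of block membership.
#' @export
lmm_profile_fit <- function(y, X, block, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  block <- factor(block)
  q <- nlevels(block)
  if (q < 2) stop("need at least 2 blocks")
  n <- length(y); p <- qr(X)$rank
  if (p < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  block_idx <- as.integer(block)
  n_per_block <- as.vector(table(block_idx))

  solve_one <- function(crit) {
    obj <- function(t) -lmm_objective(y, X, block_idx, n_per_block,
                                      exp(t), crit)
    opt <- stats::optimize(obj, c(-20, 20), tol = 1e-8)
    t_best <- opt$minimum
    # polish on the analytic score: optimize() alone is limited to about
    # sqrt(machine eps) at a quadratic minimum
    score_t <- function(t) lmm_score(y, X, block_idx, n_per_block,
                                     exp(t), crit) * exp(t)
    lo <- t_best - 1e-3; hi <- t_best + 1e-3
    if (lo > -20 && hi < 20 && score_t(lo) > 0 && score_t(hi) < 0) {
      t_best <- stats::uniroot(score_t, c(lo, hi), tol = 1e-14)$root
    }
    ll_best <- -obj(t_best)
    ll_boundary <- lmm_objective(y, X, block_idx, n_per_block, 0, crit)
    if (ll_best <= ll_boundary + 1e-12 || t_best < -15)
      list(lambda = 0, loglik = ll_boundary, boundary = TRUE)
    else
      list(lambda = exp(t_best), loglik = ll_best, boundary = FALSE)
  }
  sol_ml <- solve_one("ML")
  sol_reml <- solve_one("REML")
  sol <- if (criterion == "ML") sol_ml else sol_reml

  g <- lmm_gls(y, X, block_idx, n_per_block, sol$lambda)
  s2 <- if (criterion == "ML") g$rssw / n else g$rssw / (n - ncol(X))
  vcov_beta <- solve(g$A) * s2
  beta <- stats::setNames(g$beta, colnames(X))
  # BLUPs of the block intercepts
  res_mean <- rowsum(g$resid, block_idx, reorder = TRUE)
  blup <- drop(sol$lambda / (1 + n_per_block * sol$lambda) * res_mean)
  structure(list(
    beta = beta, se = stats::setNames(sqrt(diag(vcov_beta)), colnames(X)),
    vcov_beta = vcov_beta,
    sigma2_block = sol$lambda * s2, sigma2_resid = s2,
    lambda = sol$lambda,
    loglik_ML = sol_ml$loglik, loglik_REML = sol_reml$loglik,
    loglik = sol$loglik, criterion = criterion,
    fitted = drop(X %*% g$beta), residuals = g$resid,
    ranef = stats::setNames(blup, levels(block)),
    df_containment = n - ncol(X) - (q - 1),
    boundary = sol$boundary, n = n, n_params_fixed = ncol(X),
    X = X, y = y, block = block), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s), n = %d, blocks = %d%s\n",
              x$criterion, x$n, nlevels(x$block),
              if (x$boundary) " [block variance at boundary 0]" else ""))
  print(data.frame(estimate = x$beta, se = x$se))
  cat(sprintf("  sigma_block = %.4f, sigma_resid = %.4f, logLik = %.4f\n",
              sqrt(x$sigma2_block), sqrt(x$sigma2_resid), x$loglik))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' For linear mixed models both fits must be ML (REML log-likelihoods are not
#' comparable across fixed structures); logistic GLMM fits compare their
#' Laplace log-likelihoods. Degrees of freedom equal the difference in
#' fixed-effect counts; p-value from the chi-squared upper tail.
#'
#' @param fit_full,fit_null Nested fits on identical data.
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt <- function(fit_full, fit_null) {
  get_ll <- function(f) {
    if (inherits(f, "lmm_fit")) {
      if (f$criterion != "ML")
        stop("likelihood-ratio tests require ML fits; refit with criterion = 'ML'")
      f$loglik
    } else if (inherits(f, "glmm_fit")) f$loglik
    else stop("unsupported fit object")
  }
  if (fit_full$n != fit_null$n)
    stop("fits must be on identical data (n differs)")
  ll_f <- get_ll(fit_full); ll_n <- get_ll(fit_null)
  df <- fit_full$n_params_fixed - fit_null$n_params_fixed
  if (df < 0) stop("null model must be nested in the full model")
  stat <- max(0, 2 * (ll_f - ll_n))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Contrasts of each factor level against the reference
#'
#' With treatment contrasts the non-intercept coefficients are exactly the
#' level-vs-reference differences; t statistics use containment degrees of
#' freedom `n - p - (blocks - 1)`.
#'
#' @param fit An `lmm_fit` from a factor-type [model_spec()].
#' @return Data.frame with `level`, `estimate`, `se`, `t`, `p`.
#' @export
contrasts_vs_reference <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  idx <- which(names(fit$beta) != "(Intercept)")
  df <- fit$df_containment
  out <- data.frame(level = names(fit$beta)[idx],
                    estimate = unname(fit$beta[idx]),
                    se = unname(fit$se[idx]), stringsAsFactors = FALSE)
  out$t <- out$estimate / out$se
  out$p <- 2 * stats::pt(-abs(out$t), df)
  rownames(out) <- NULL
  out
}

#' Tukey pairwise comparisons of group means
#'
#' All k(k-1)/2 pairwise differences of the model group means, with p-values
#' from the studentized-range distribution at containment degrees of
#' freedom, and an additional significance flag at the Bonferroni level
#' `alpha / C` where C is the number of comparisons (k = 4 gives
#' 0.05/6 = 0.00833, reported as 0.008).
#'
#' @param fit An `lmm_fit` on a factor fixed effect (k >= 2 levels).
#' @param alpha Familywise level for the Bonferroni threshold (default 0.05).
#' @return Data.frame with `pair`, `estimate`, `se`, `statistic`, `p_tukey`,
#'   `significant_at_bonferroni`; attributes `bonferroni_threshold` and
#'   `n_comparisons`.
#' @export
tukey_pairwise <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  nm <- names(fit$beta)
  if (!"(Intercept)" %in% nm || length(nm) < 2)
    stop("need a fitted factor model with at least 2 levels")
  k <- length(nm)  # intercept level + (k-1) others
  ref <- "(ref)"
  levels_all <- c(ref, nm[-1])
  # group-mean contrast vectors in coefficient space
  cvec <- function(level) {
    v <- numeric(length(nm)); v[1] <- 1
    if (level != ref) v[match(level, nm)] <- 1
    v
  }
  pairs <- utils::combn(levels_all, 2)
  C <- ncol(pairs)
  df <- fit$df_containment
  out <- do.call(rbind, lapply(seq_len(C), function(j) {
    d <- cvec(pairs[1, j]) - cvec(pairs[2, j])
    est <- sum(d * fit$beta)
    se <- sqrt(drop(t(d) %*% fit$vcov_beta %*% d))
    qstat <- abs(est) / (se / sqrt(2))
    data.frame(pair = paste(pairs[1, j], "-", pairs[2, j]),
               estimate = est, se = se, statistic = qstat,
               p_tukey = stats::ptukey(qstat, nmeans = k, df = df,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  thr <- alpha / C
  out$significant_at_bonferroni <- out$p_tukey < thr
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "n_comparisons") <- C
  out
}

# ---- logistic GLMM (Laplace) -------------------------------------------

# per-block 1-D Newton for the conditional mode of the random intercept
glmm_block_mode <- function(eta_fix, y, sigma2) {
  b <- 0
  for (it in 1:50) {
    p <- stats::plogis(eta_fix + b)
    g <- sum(y - p) - b / sigma2
    h <- sum(p * (1 - p)) + 1 / sigma2
    step <- g / h
    b <- b + step
    if (abs(step) < 1e-12) break
  }
  p <- stats::plogis(eta_fix + b)
  list(b = b, ll = sum(stats::dbinom(y, 1, p, log = TRUE)),
       w = sum(p * (1 - p)))
}

glmm_laplace_loglik <- function(beta, sigma2, y, X, block_idx, q) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (j in seq_len(q)) {
    sel <- block_idx == j
    m <- glmm_block_mode(eta[sel], y[sel], sigma2)
    ll <- ll + m$ll - m$b^2 / (2 * sigma2) - 0.5 * log1p(sigma2 * m$w)
  }
  ll
}

#' Fit a logistic mixed model with a block random intercept
#'
#' Laplace approximation: the per-block random-intercept modes are found by
#' 1-D Newton iterations inside an outer quasi-Newton optimization over the
#' fixed effects and log block SD. When the estimated block variance is
#' below 1e-8 the model is refit as a plain logistic regression and flagged
#' as a boundary fit. Complete or quasi-complete separation is flagged (the
#' affected estimates diverge) rather than raised as an error.
#'
#' @param spec A [model_spec()] with a binary (0/1 or logical) response.
#' @param data Data.frame.
#' @return Object of class `glmm_fit`: `beta`, `sigma2_block`, `loglik`
#'   (Laplace, or exact when at the boundary), `fitted` (probabilities at
#'   the fixed effects), `converged`, `boundary`, `separation`,
#'   `n_params_fixed`, `n`.
#' @export
fit_logistic_glmm <- function(spec, data) {
  mf <- build_model_frame(spec, data)
  y <- mf$y
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  glmm_laplace_fit(y, mf$X, mf$block)
}

#' @rdname fit_logistic_glmm
#' @param y Binary 0/1 response vector.
#' @param X Design matrix.
#' @param block Factor of block membership.
#' @export
glmm_laplace_fit <- function(y, X, block) {
  block <- factor(block)
  block_idx <- as.integer(block)
  q <- nlevels(block)
  n <- length(y); p <- ncol(X)
  degenerate <- length(unique(y)) < 2

  glm0 <- suppressWarnings(stats::glm.fit(X, y,
                                          family = stats::binomial()))
  beta0 <- ifelse(is.finite(glm0$coefficients), glm0$coefficients, 0)

  make_fit <- function(beta, sigma2, loglik, converged, boundary) {
    eta <- drop(X %*% beta)
    separation <- degenerate || max(abs(eta)) > 15
    structure(list(beta = stats::setNames(beta, colnames(X)),
                   sigma2_block = sigma2, loglik = loglik,
                   fitted = stats::plogis(eta), converged = converged,
                   boundary = boundary, separation = separation,
                   degenerate = degenerate,
                   n = n, n_params_fixed = p, block = block),
              class = "glmm_fit")
  }

  if (degenerate) {
    ll <- sum(stats::dbinom(y, 1, stats::plogis(drop(X %*% beta0)),
                            log = TRUE))
    return(make_fit(beta0, 0, ll, TRUE, TRUE))
  }

  negll <- function(par) {
    beta <- par[seq_len(p)]
    sigma2 <- exp(2 * par[p + 1])
    -glmm_laplace_loglik(beta, sigma2, y, X, block_idx, q)
  }
  opt <- stats::nlminb(c(beta0, log(0.3)), negll,
                       control = list(iter.max = 500, eval.max = 1000))
  sigma2_hat <- exp(2 * opt$par[p + 1])
  if (sigma2_hat < 1e-8) {
    ll <- sum(stats::dbinom(y, 1, stats::plogis(drop(X %*% beta0)),
                            log = TRUE))
    return(make_fit(beta0, 0, ll, opt$convergence == 0, TRUE))
  }
  make_fit(opt$par[seq_len(p)], sigma2_hat, -opt$objective,
           opt$convergence == 0, FALSE)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic GLMM (Laplace), n = %d%s%s\n", x$n,
    if (x$boundary) " [block variance at boundary 0]" else "",
    if (x$separation) " [separation flagged]" else ""))
  print(data.frame(estimate = x$beta))
  cat(sprintf("  sigma_block = %.4f, logLik = %.4f\n",
              sqrt(x$sigma2_block), x$loglik))
  invisible(x)
}

# ---- hurdle ------------------------------------------------------------

#' Two-part hurdle analysis of a zero-inflated positive response
#'
#' Stage 1 models presence/absence (`response > 0`) with a logistic mixed
#' model; stage 2 models the natural log of the response among positive
#' records with a linear mixed model. Both stages test the fixed factor by
#' likelihood-ratio tests against intercept-only fits. Stage 2 is skipped
#' (with a flag) when fewer than 3 records are positive.
#'
#' @param spec A [model_spec()] naming the raw (untransformed) response.
#' @param data Data.frame.
#' @return Object of class `hurdle_result` with `stage1`, `stage2`,
#'   `lrt_stage1`, `lrt_stage2`, `n_zero`, `n_positive`, `stage2_skipped`.
#' @export
hurdle_analysis <- function(spec, data) {
  y <- data[[spec$response]]
  if (is.null(y)) stop("column not found: ", spec$response)
  if (any(y < 0)) stop("hurdle response must be non-negative")
  data$.presence <- as.integer(y > 0)
  spec1 <- model_spec(".presence", spec$fixed, spec$fixed_type,
                      spec$reference, FALSE, spec$random)
  stage1 <- fit_logistic_glmm(spec1, data)
  null1 <- glmm_laplace_fit(data$.presence,
                            matrix(1, nrow(data), 1,
                                   dimnames = list(NULL, "(Intercept)")),
                            factor(data[[spec$random]]))
  lrt1 <- if (stage1$degenerate) NULL else lrt(stage1, null1)

  n_pos <- sum(y > 0)
  pos <- data[y > 0, , drop = FALSE]
  stage2 <- NULL; lrt2 <- NULL; skipped <- FALSE
  if (n_pos < 3) {
    skipped <- TRUE
  } else {
    spec2 <- model_spec(spec$response, spec$fixed, spec$fixed_type,
                        spec$reference, TRUE, spec$random)
    stage2 <- tryCatch(fit_lmm(spec2, pos, criterion = "REML"),
                       error = function(e) e)
    if (inherits(stage2, "error")) {
      skipped <- TRUE
      stage2 <- NULL
    } else {
      full_ml <- fit_lmm(spec2, pos, criterion = "ML")
      spec2n <- model_spec(spec$response, spec$fixed, spec$fixed_type,
                           spec$reference, TRUE, spec$random)
      mf <- build_model_frame(spec2n, pos)
      null_ml <- lmm_profile_fit(mf$y,
                                 matrix(1, nrow(pos), 1,
                                        dimnames = list(NULL, "(Intercept)")),
                                 mf$block, criterion = "ML")
      lrt2 <- lrt(full_ml, null_ml)
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2, lrt_stage1 = lrt1,
                 lrt_stage2 = lrt2, n_zero = sum(y == 0),
                 n_positive = n_pos, stage2_skipped = skipped),
            class = "hurdle_result")
}

#' @export
print.hurdle_result <- function(x, ...) {
  cat(sprintf("Hurdle analysis: %d zero, %d positive\n", x$n_zero,
              x$n_positive))
  cat("Stage 1 (presence/absence):\n"); print(x$stage1)
  if (x$stage2_skipped) cat("Stage 2 skipped (<3 positive records)\n")
  else { cat("Stage 2 (log biomass | presence):\n"); print(x$stage2) }
  invisible(x)
}
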