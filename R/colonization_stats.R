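#' 2x2 contingency table
#'
#' Rows are the two groups, columns success/failure:
#' \preformatted{        success  failure
#'   g1       a        b
#'   g2       c        d}
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A list of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("table has zero total")
  structure(as.list(counts), class = "table2x2")
}

# log hypergeometric point probability of first cell x, from log-factorials;
# margins r1 = a+b, r2 = c+d, c1 = a+c, n total
log_hyper_pmf <- function(x, r1, r2, c1) {
  lfact <- function(k) lgamma(k + 1)
  n <- r1 + r2
  (lfact(r1) - lfact(x) - lfact(r1 - x)) +
    (lfact(r2) - lfact(c1 - x) - lfact(r2 - (c1 - x))) -
    (lfact(n) - lfact(c1) - lfact(n - c1))
}

hyper_support <- function(r1, r2, c1) {
  max(0L, c1 - r2):min(r1, c1)
}

#' Exact two-sided test on a 2x2 table
#'
#' With both margins fixed, the first cell follows the central hypergeometric
#' distribution under the null of equal proportions. The two-sided p-value is
#' the sum of the probabilities of all admissible tables whose point
#' probability does not exceed that of the observed table (relative tolerance
#' 1e-7 on the comparison). Computed in log space via log-factorials.
#'
#' @param t A `table2x2`.
#' @return List with `p_two_sided`, `point_prob` and the support enumerated.
#' @export
fisher_exact_two_sided <- function(t) {
  stopifnot(inherits(t, "table2x2"))
  r1 <- t$a + t$b; r2 <- t$c + t$d; c1 <- t$a + t$c
  if (r1 + r2 == 0) stop("table has zero total")
  supp <- hyper_support(r1, r2, c1)
  logp <- log_hyper_pmf(supp, r1, r2, c1)
  lp_obs <- log_hyper_pmf(t$a, r1, r2, c1)
  keep <- logp <= lp_obs + log(1 + 1e-7)
  # log-sum-exp over the selected tables
  m <- max(logp[keep])
  p <- exp(m) * sum(exp(logp[keep] - m))
  list(p_two_sided = min(1, p), point_prob = exp(lp_obs), support = supp)
}

# conditional mean and log-likelihood of Fisher's noncentral hypergeometric
# distribution at log-odds-ratio t, computed with log-sum-exp
noncentral_logweights <- function(supp, r1, r2, c1, log_psi) {
  lfact <- function(k) lgamma(k + 1)
  lw <- (lfact(r1) - lfact(supp) - lfact(r1 - supp)) +
    (lfact(r2) - lfact(c1 - supp) - lfact(r2 - (c1 - supp))) +
    supp * log_psi
  lw
}

noncentral_mean <- function(supp, r1, r2, c1, log_psi) {
  lw <- noncentral_logweights(supp, r1, r2, c1, log_psi)
  m <- max(lw)
  w <- exp(lw - m)
  sum(supp * w) / sum(w)
}

#' Conditional-likelihood of a table at odds ratio psi
#'
#' Log-probability of the observed first cell under Fisher's noncentral
#' hypergeometric distribution with the table's margins.
#'
#' @param t A `table2x2`.
#' @param log_psi Log odds ratio.
#' @return Log conditional likelihood.
#' @export
conditional_loglik <- function(t, log_psi) {
  r1 <- t$a + t$b; r2 <- t$c + t$d; c1 <- t$a + t$c
  supp <- hyper_support(r1, r2, c1)
  lw <- noncentral_logweights(supp, r1, r2, c1, log_psi)
  m <- max(lw)
  lw_obs <- noncentral_logweights(t$a, r1, r2, c1, log_psi)
  lw_obs - (m + log(sum(exp(lw - m))))
}

#' Conditional-MLE odds ratio of a 2x2 table
#'
#' The odds-ratio parameter psi of Fisher's noncentral hypergeometric
#' distribution that maximizes the likelihood of the observed first cell
#' conditional on both margins. The conditional mean is strictly increasing
#' in psi, so the MLE solves `E_psi[X] = a` by monotone root-finding on
#' log(psi). Tables with the observed cell at the support boundary return 0
#' or Inf with a boundary flag.
#'
#' @param t A `table2x2`.
#' @return List with `odds_ratio` and logical `boundary`.
#' @export
conditional_mle_odds_ratio <- function(t) {
  stopifnot(inherits(t, "table2x2"))
  r1 <- t$a + t$b; r2 <- t$c + t$d; c1 <- t$a + t$c
  supp <- hyper_support(r1, r2, c1)
  if (length(supp) == 1)
    return(list(odds_ratio = NA_real_, boundary = TRUE))
  if (t$a == min(supp)) return(list(odds_ratio = 0, boundary = TRUE))
  if (t$a == max(supp)) return(list(odds_ratio = Inf, boundary = TRUE))
  f <- function(lp) noncentral_mean(supp, r1, r2, c1, lp) - t$a
  lo <- -1; hi <- 1
  while (f(lo) > 0 && lo > -500) lo <- lo * 2
  while (f(hi) < 0 && hi < 500) hi <- hi * 2
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  list(odds_ratio = exp(root), boundary = FALSE)
}

#' Exact test plus conditional-MLE odds ratio
#'
#' @param t A `table2x2`.
#' @return Object of class `fisher_result` with fields `p_two_sided`,
#'   `odds_ratio_cmle`, `point_prob`, `boundary` and the table.
#' @export
fisher_result <- function(t) {
  p <- fisher_exact_two_sided(t)
  or <- conditional_mle_odds_ratio(t)
  structure(list(table = t, p_two_sided = p$p_two_sided,
                 point_prob = p$point_prob,
                 odds_ratio_cmle = or$odds_ratio, boundary = or$boundary),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("2x2 exact test: a=%d b=%d c=%d d=%d\n", x$table$a, x$table$b,
              x$table$c, x$table$d))
  cat(sprintf("  two-sided p = %.4g, conditional-MLE odds ratio = %.3f%s\n",
              x$p_two_sided, x$odds_ratio_cmle,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Colonization rates by group
#'
#' @param records Mesocosm records.
#' @param grouping One of `"vegetated_vs_bare"`, `"treatment"`,
#'   `"functional_group"`.
#' @param design Experiment design supplying treatment metadata.
#' @return Data.frame with `group`, `colonized`, `n`, `percent` (1 dp) and
#'   `percent_raw` (unrounded).
#' @export
colonization_rates <- function(records, grouping = "vegetated_vs_bare",
                               design = build_default_design()) {
  g <- grouping_vector(records, grouping, design)
  groups <- unique(g)
  out <- do.call(rbind, lapply(groups, function(gr) {
    sel <- g == gr
    n <- sum(sel)
    k <- sum(records$colonized[sel])
    data.frame(group = gr, colonized = k, n = n,
               percent = round(100 * k / n, 1),
               percent_raw = 100 * k / n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

grouping_vector <- function(records, grouping, design) {
  tr <- design$treatments
  idx <- match(records$treatment_id, tr$id)
  if (anyNA(idx)) stop("records contain unknown treatment ids")
  switch(grouping,
    vegetated_vs_bare = ifelse(tr$richness[idx] > 0, "vegetated", "bare"),
    treatment = as.character(records$treatment_id),
    functional_group = tr$group_label[idx],
    stop("unknown grouping: ", grouping)
  )
}

#' Compare colonization between two groups by exact test
#'
#' Builds the 2x2 table (group x colonized yes/no) and runs
#' [fisher_exact_two_sided()] and [conditional_mle_odds_ratio()]. With the
#' default grouping, group 1 is vegetated and group 2 bare, so an odds ratio
#' below 1 means colonization is rarer in vegetated mesocosms.
#'
#' @inheritParams colonization_rates
#' @return A `fisher_result`.
#' @export
compare_colonization <- function(records, grouping = "vegetated_vs_bare",
                                 design = build_default_design()) {
  g <- grouping_vector(records, grouping, design)
  lev <- unique(g)
  if (length(lev) != 2)
    stop("grouping yields ", length(lev),
         " groups; exact comparison needs exactly 2 (use pairwise calls)")
  lev <- sort(lev, decreasing = TRUE)  # "vegetated" before "bare"
  a <- sum(records$colonized[g == lev[1]])
  b <- sum(!records$colonized[g == lev[1]])
  cc <- sum(records$colonized[g == lev[2]])
  d <- sum(!records$colonized[g == lev[2]])
  res <- fisher_result(table2x2(a, b, cc, d))
  res$groups <- lev
  res
}

#' Write a fisher_result as JSON
#'
#' @param x A `fisher_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
fisher_to_json <- function(x, path) {
  obj <- list(table = list(a = x$table$a, b = x$table$b, c = x$table$c,
                           d = x$table$d),
              p_two_sided = x$p_two_sided,
              odds_ratio_cmle = x$odds_ratio_cmle,
              boundary = x$boundary,
              method = "exact central hypergeometric, two-sided by point probability; conditional-MLE odds ratio")
  if (!is.null(x$groups)) obj$groups <- x$groups
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
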