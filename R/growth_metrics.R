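#' Relative growth rate
#'
#' RGR = (ln W_f - ln W_i) / duration, in g g^-1 DW day^-1. A final mass of
#' zero (total loss of the fragments) is a domain error, not -Inf: such
#' units should be reported as non-established instead.
#'
#' @param W_i Initial total dry mass (g), > 0.
#' @param W_f Final total dry mass (g), > 0.
#' @param duration_days Duration in days, >= 1.
#' @return Numeric RGR (vectorized).
#' @export
relative_growth_rate <- function(W_i, W_f, duration_days) {
  if (any(!is.finite(W_i)) || any(W_i <= 0))
    stop("initial mass must be positive")
  if (any(!is.finite(W_f)) || any(W_f <= 0))
    stop("final mass must be positive (zero-mass units are non-established)")
  if (any(duration_days < 1)) stop("duration must be >= 1 day")
  (log(W_f) - log(W_i)) / duration_days
}

#' Root:shoot ratio
#'
#' @param root_g Root dry mass (g), >= 0.
#' @param shoot_g Shoot dry mass (g), > 0.
#' @return root_g / shoot_g (vectorized).
#' @export
root_shoot_ratio <- function(root_g, shoot_g) {
  if (any(!is.finite(shoot_g)) || any(shoot_g <= 0))
    stop("shoot mass must be positive")
  if (any(root_g < 0)) stop("root mass must be non-negative")
  root_g / shoot_g
}

#' Per-treatment summaries of the invader responses
#'
#' Mean, sample SD (n - 1 denominator) and n per treatment for root DW,
#' shoot DW, root:shoot ratio and RGR, mirroring a mean +/- SD reporting
#' table. RGR uses final mass = root + shoot.
#'
#' @param records Mesocosm records.
#' @return Data.frame with one row per (treatment, response) with columns
#'   `treatment_id`, `response`, `mean`, `sd`, `n`. Empty groups yield
#'   `n = 0` rows with `NA` mean flagged.
#' @export
summarize_by_treatment <- function(records) {
  wf <- records$invader_root + records$invader_shoot
  resp <- list(
    root_dw = records$invader_root,
    shoot_dw = records$invader_shoot,
    root_shoot = ifelse(records$invader_shoot > 0,
                        records$invader_root / records$invader_shoot, NA),
    rgr = ifelse(wf > 0 & records$invader_initial > 0,
                 (log(wf) - log(records$invader_initial)) /
                   records$duration_days, NA)
  )
  ids <- sort(unique(records$treatment_id))
  out <- do.call(rbind, lapply(names(resp), function(nm) {
    do.call(rbind, lapply(ids, function(id) {
      x <- resp[[nm]][records$treatment_id == id]
      x <- x[!is.na(x)]
      data.frame(treatment_id = id, response = nm,
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
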