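#' Expected relative yields in a substitutive design
#'
#' Planting density constant means each of N species is planted at fraction
#' 1/N, which is its expected relative yield under proportional replacement.
#'
#' @param treatment One row of a design's treatment table (or a list with a
#'   `composition` element).
#' @return Named numeric, 1/N per composition member.
#' @export
expected_relative_yields <- function(treatment) {
  comp <- if (is.data.frame(treatment)) treatment$composition[[1]] else
    treatment$composition
  if (length(comp) == 0)
    stop("bare treatment has no expected relative yields")
  stats::setNames(rep(1 / length(comp), length(comp)), comp)
}

#' Additive partition of the net diversity effect
#'
#' Compares observed mixture yield with the yield expected from monocultures
#' at planted proportions and splits the difference into a complementarity
#' effect, `CE = N * mean(dRY) * mean(M)`, and a selection effect,
#' `SE = N * cov(dRY, M)` with the population covariance (divisor N) so that
#' `CE + SE = dY` holds exactly.
#'
#' @param M Named numeric, monoculture yield per species (g DW), all > 0.
#' @param Y_O_species Named numeric, observed per-species yields in the
#'   mixture (g DW), same species as `M`.
#' @param RY_E Named numeric, expected relative yields (planted proportions)
#'   summing to 1; defaults to 1/N each.
#' @return Object of class `partition_result` with `delta_Y`, `CE`, `SE`,
#'   `Y_O`, `Y_E`, `M_bar`, `RY_O`, `delta_RY`, `N`.
#' @export
partition <- function(M, Y_O_species,
                      RY_E = stats::setNames(rep(1 / length(M), length(M)),
                                             names(M))) {
  if (is.null(names(M)) || is.null(names(Y_O_species)))
    stop("M and Y_O_species must be named by species")
  if (!setequal(names(M), names(Y_O_species)) ||
      !setequal(names(M), names(RY_E)))
    stop("species sets of M, Y_O_species and RY_E must match")
  sp <- names(M)
  M <- M[sp]; Y_O_species <- Y_O_species[sp]; RY_E <- RY_E[sp]
  if (any(M <= 0))
    stop("monoculture yield must be positive for species: ",
         paste(sp[M <= 0], collapse = ", "))
  if (any(Y_O_species < 0)) stop("observed yields must be non-negative")
  if (abs(sum(RY_E) - 1) > 1e-8)
    stop("expected relative yields must sum to 1 (substitutive design)")
  N <- length(sp)
  RY_O <- Y_O_species / M
  dRY <- RY_O - RY_E
  Y_O <- sum(Y_O_species)
  Y_E <- sum(RY_E * M)
  M_bar <- mean(M)
  CE <- N * mean(dRY) * M_bar
  # population covariance (divisor N); sample covariance would break
  # CE + SE = delta_Y additivity
  SE <- N * mean((dRY - mean(dRY)) * (M - M_bar))
  structure(list(delta_Y = Y_O - Y_E, CE = CE, SE = SE, Y_O = Y_O,
                 Y_E = Y_E, M_bar = M_bar, RY_O = RY_O, delta_RY = dRY,
                 N = N),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "Net diversity effect dY = %.4f g (Y_O = %.4f, Y_E = %.4f)\n",
    x$delta_Y, x$Y_O, x$Y_E))
  cat(sprintf("  complementarity CE = %.4f g, selection SE = %.4f g\n",
              x$CE, x$SE))
  invisible(x)
}

#' Partition every mixture mesocosm of an experiment
#'
#' Monoculture yields `M_i` are the across-block means of each species'
#' monoculture treatment (default), or the same-block monoculture value when
#' `per_block = TRUE` (sensitivity analysis; errors if a same-block
#' monoculture yield is zero). The partition is applied to each mixture
#' mesocosm and summarized per treatment.
#'
#' @param records Mesocosm records.
#' @param design Experiment design.
#' @param per_block Pair mixtures with same-block monocultures instead of
#'   across-block means.
#' @return List with `units` (one row per mixture mesocosm: treatment, block,
#'   Y_O, Y_E, delta_Y, CE, SE, M_bar) and `summary` (per-treatment means and
#'   SDs). Both empty if the experiment has no mixtures.
#' @export
partition_experiment <- function(records, design = build_default_design(),
                                 per_block = FALSE) {
  tr <- design$treatments
  mono <- tr[tr$richness == 1, ]
  mono_species <- vapply(mono$composition, `[[`, character(1), 1)
  mixtures <- tr[tr$richness >= 2, ]
  empty <- data.frame(treatment_id = integer(0), block = integer(0),
                      Y_O = numeric(0), Y_E = numeric(0),
                      delta_Y = numeric(0), CE = numeric(0), SE = numeric(0),
                      M_bar = numeric(0))
  if (nrow(mixtures) == 0)
    return(list(units = empty, summary = empty[, 0]))

  mono_yield <- function(sp, block = NULL) {
    tid <- mono$id[mono_species == sp]
    if (length(tid) != 1)
      stop("missing monoculture treatment for species ", sp)
    sel <- records$treatment_id == tid
    if (!is.null(block)) sel <- sel & records$block == block
    y <- records[[paste0("yield_", sp)]][sel]
    if (length(y) == 0) stop("no monoculture records for species ", sp)
    mean(y)
  }

  rows <- list()
  for (ti in seq_len(nrow(mixtures))) {
    trm <- mixtures[ti, ]
    comp <- trm$composition[[1]]
    RY_E <- expected_relative_yields(trm)
    recs <- records[records$treatment_id == trm$id, , drop = FALSE]
    for (r in seq_len(nrow(recs))) {
      blk <- recs$block[r]
      M <- vapply(comp, function(sp)
        mono_yield(sp, block = if (per_block) blk else NULL), numeric(1))
      if (per_block && any(M <= 0))
        stop("per-block monoculture yield is zero for species ",
             paste(comp[M <= 0], collapse = ", "), " in block ", blk,
             "; cannot form relative yields")
      Yo <- vapply(comp, function(sp)
        recs[[paste0("yield_", sp)]][r], numeric(1))
      pr <- partition(M, Yo, RY_E)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment_id = trm$id, block = blk, Y_O = pr$Y_O, Y_E = pr$Y_E,
        delta_Y = pr$delta_Y, CE = pr$CE, SE = pr$SE, M_bar = pr$M_bar)
    }
  }
  units <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  ids <- unique(units$treatment_id)
  summary <- do.call(rbind, lapply(ids, function(id) {
    u <- units[units$treatment_id == id, ]
    data.frame(treatment_id = id, n = nrow(u),
               delta_Y_mean = mean(u$delta_Y), delta_Y_sd = stats::sd(u$delta_Y),
               CE_mean = mean(u$CE), CE_sd = stats::sd(u$CE),
               SE_mean = mean(u$SE), SE_sd = stats::sd(u$SE))
  }))
  list(units = units, summary = summary)
}

#' Percent overyielding relative to the average monoculture
#'
#' @param Y_O Observed mixture yield (g DW).
#' @param M_values Monoculture yields of the component species (g DW).
#' @return 100 * (Y_O - mean(M)) / mean(M).
#' @export
percent_overyield <- function(Y_O, M_values) {
  if (length(M_values) == 0) stop("no monoculture yields supplied")
  mbar <- mean(M_values)
  if (mbar <= 0) stop("mean monoculture yield must be positive")
  100 * (Y_O - mbar) / mbar
}
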