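#' Construct a simulation scenario
#'
#' A scenario states the world the generator draws from: monoculture mean
#' yields, lognormal noise and block variability on the log scale, per-species
#' multiplicative dominance in mixtures (1 = proportional replacement null),
#' an equal-share complementarity boost, and the invader response model.
#'
#' @param monoculture_mean Named numeric, mean monoculture yield (g DW) per
#'   native species.
#' @param monoculture_cv Coefficient of variation of yields (lognormal noise).
#' @param block_sd Between-block SD, additive on log-yield.
#' @param mixture_dominance Named numeric, multiplicative deviation of
#'   per-capita mixture performance from monoculture per-capita performance.
#' @param complementarity_boost Multiplicative factor applied equally to all
#'   species in mixtures.
#' @param invader List as built by [invader_model()].
#' @param seed Integer seed driving all randomness.
#' @return An object of class `scenario`.
#' @export
scenario <- function(monoculture_mean, monoculture_cv, block_sd,
                     mixture_dominance, complementarity_boost, invader,
                     seed = 1L) {
  stopifnot(all(monoculture_mean >= 0), monoculture_cv >= 0, block_sd >= 0,
            all(mixture_dominance > 0), complementarity_boost > 0)
  sc <- list(monoculture_mean = monoculture_mean,
             monoculture_cv = monoculture_cv,
             block_sd = block_sd,
             mixture_dominance = mixture_dominance,
             complementarity_boost = complementarity_boost,
             invader = invader,
             seed = as.integer(seed))
  class(sc) <- "scenario"
  sc
}

#' Invader response model
#'
#' Colonization is Bernoulli with logistic probability declining in total
#' native biomass; root mass given colonization is lognormal with a log-mean
#' declining in native biomass; shoot mass declines linearly in native
#' biomass (floored at a small positive value) with multiplicative lognormal
#' noise.
#'
#' @param colonize_intercept,colonize_slope Logistic coefficients for
#'   P(colonized) against total native biomass (g DW); slope must be <= 0.
#' @param root_mu,root_sigma Lognormal log-mean (at zero native biomass) and
#'   log-SD of root mass given colonization.
#' @param root_slope Decline of log root mass per g native biomass (<= 0).
#' @param shoot_base,shoot_slope Linear model of mean shoot mass (g) against
#'   native biomass; slope must be <= 0.
#' @param shoot_floor Minimum mean shoot mass (g), > 0.
#' @param shoot_cv Coefficient of variation of shoot mass noise.
#' @param initial_mass_mean,initial_mass_sd Total initial fragment mass (g).
#' @param duration_days Invader exposure time in days.
#' @return A list of class `invader_model`.
#' @export
invader_model <- function(colonize_intercept, colonize_slope,
                          root_mu, root_sigma, root_slope = 0,
                          shoot_base, shoot_slope, shoot_floor = 0.05,
                          shoot_cv = 0.12,
                          initial_mass_mean = 0.41, initial_mass_sd = 0.05,
                          duration_days = 56L) {
  stopifnot(colonize_slope <= 0, shoot_slope <= 0, root_slope <= 0,
            shoot_floor > 0, root_sigma >= 0, duration_days >= 1)
  structure(list(colonize_intercept = colonize_intercept,
                 colonize_slope = colonize_slope,
                 root_mu = root_mu, root_sigma = root_sigma,
                 root_slope = root_slope,
                 shoot_base = shoot_base, shoot_slope = shoot_slope,
                 shoot_floor = shoot_floor, shoot_cv = shoot_cv,
                 initial_mass_mean = initial_mass_mean,
                 initial_mass_sd = initial_mass_sd,
                 duration_days = as.integer(duration_days)),
            class = "invader_model")
}

#' Scenario calibrated to the reported experiment
#'
#' Monoculture means 3.54 g (rooted M, P) and 0.48 g (non-rooted C, U);
#' rooted dominance > 1 and non-rooted dominance < 1 so that the expected
#' four-species mixture yield exceeds the average monoculture yield by about
#' 29% while complementarity is slightly negative; bare-sediment colonization
#' probability 2/3 declining with native biomass so that vegetated units
#' colonize at roughly 8%; 56-day invader exposure.
#'
#' @param seed Integer seed.
#' @return A `scenario`.
#' @export
calibrated_scenario <- function(seed = 1L) {
  scenario(
    monoculture_mean = c(M = 3.54, P = 3.54, C = 0.48, U = 0.48),
    monoculture_cv = 0.35,
    block_sd = 0.3,
    mixture_dominance = c(M = 1.4, P = 1.4, C = 0.5, U = 0.5),
    complementarity_boost = 1.0,
    invader = invader_model(
      colonize_intercept = qlogis(2 / 3), colonize_slope = -4,
      root_mu = log(0.055), root_sigma = 0.8, root_slope = -2.5,
      shoot_base = 1.71, shoot_slope = -0.226,
      initial_mass_mean = 0.41, initial_mass_sd = 0.05,
      duration_days = 56L),
    seed = seed
  )
}

#' Analytic null scenario
#'
#' Proportional replacement: all dominance factors 1, no complementarity
#' boost, and an invader whose responses do not depend on native biomass.
#' Expected net diversity effect, complementarity and selection are all zero
#' for every mixture, and treatment has no effect on any invader response.
#'
#' @param seed Integer seed.
#' @return A `scenario`.
#' @export
null_scenario <- function(seed = 1L) {
  scenario(
    monoculture_mean = c(M = 3.54, P = 3.54, C = 0.48, U = 0.48),
    monoculture_cv = 0.35,
    block_sd = 0.3,
    mixture_dominance = c(M = 1, P = 1, C = 1, U = 1),
    complementarity_boost = 1.0,
    invader = invader_model(
      colonize_intercept = qlogis(2 / 3), colonize_slope = 0,
      root_mu = log(0.055), root_sigma = 0.8, root_slope = 0,
      shoot_base = 1.71, shoot_slope = 0,
      initial_mass_mean = 0.41, initial_mass_sd = 0.05,
      duration_days = 56L),
    seed = seed
  )
}

# deterministic per-unit substream so adding mesocosms never shifts earlier
# draws; kept below 2^31 - 1
unit_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

#' Simulate one experiment
#'
#' Draws one mesocosm record per design unit. The yield of species i planted
#' at fraction 1/N in a mixture is
#' `(1/N) * m_i * dominance_i * boost * exp(block_j + eps)` with lognormal
#' noise centred so that the expectation equals the deterministic part;
#' monocultures use dominance 1. Invader responses are drawn conditional on
#' the realized total native biomass. Fully reproducible: the global seed
#' drives per-mesocosm substreams.
#'
#' @param scenario A `scenario`.
#' @param design An `experiment_design` (default [build_default_design()]).
#' @return A data.frame of mesocosm records (one row per unit).
#' @export
simulate_experiment <- function(scenario, design = build_default_design()) {
  stopifnot(inherits(scenario, "scenario"))
  sdl <- sqrt(log(1 + scenario$monoculture_cv^2))  # log-scale noise SD
  sb <- scenario$block_sd
  inv <- scenario$invader
  set.seed(scenario$seed)
  block_eff <- stats::rnorm(design$blocks, 0, sb)
  sh_sdl <- sqrt(log(1 + inv$shoot_cv^2))

  rows <- vector("list", design$blocks * nrow(design$treatments))
  k <- 0L
  for (b in seq_len(design$blocks)) {
    for (ti in seq_len(nrow(design$treatments))) {
      k <- k + 1L
      tr <- design$treatments[ti, ]
      comp <- tr$composition[[1]]
      set.seed(unit_seed(scenario$seed, k))
      yields <- stats::setNames(rep(NA_real_, length(NATIVE_CODES)),
                                NATIVE_CODES)
      if (length(comp)) {
        n <- length(comp)
        for (sp in comp) {
          dom <- if (n > 1) scenario$mixture_dominance[[sp]] else 1
          boost <- if (n > 1) scenario$complementarity_boost else 1
          mu <- (1 / n) * scenario$monoculture_mean[[sp]] * dom * boost
          # centre total log-noise so E[yield] = mu
          yields[sp] <- mu * exp(block_eff[b] + stats::rnorm(1, 0, sdl) -
                                   (sdl^2 + sb^2) / 2)
        }
      }
      btot <- sum(yields, na.rm = TRUE)
      p_col <- stats::plogis(inv$colonize_intercept +
                               inv$colonize_slope * btot)
      colonized <- stats::runif(1) < p_col
      root <- if (colonized)
        exp(inv$root_mu + inv$root_slope * btot +
              stats::rnorm(1, 0, inv$root_sigma)) else 0
      shoot_mean <- max(inv$shoot_floor, inv$shoot_base +
                          inv$shoot_slope * btot)
      shoot <- shoot_mean * exp(block_eff[b] + stats::rnorm(1, 0, sh_sdl) -
                                  (sh_sdl^2 + sb^2) / 2)
      wi <- max(0.05, stats::rnorm(1, inv$initial_mass_mean,
                                   inv$initial_mass_sd))
      row <- data.frame(block = b, treatment_id = tr$id,
                        stringsAsFactors = FALSE)
      for (sp in NATIVE_CODES) row[[paste0("yield_", sp)]] <- yields[[sp]]
      row$invader_root <- root
      row$invader_shoot <- shoot
      row$colonized <- colonized
      row$invader_initial <- wi
      row$duration_days <- inv$duration_days
      rows[[k]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Serialize / read a scenario as YAML
#'
#' @param scenario A `scenario`.
#' @param path File path.
#' @return `scenario_to_yaml()` returns `path` invisibly;
#'   `scenario_from_yaml()` returns a `scenario`.
#' @export
scenario_to_yaml <- function(scenario, path) {
  obj <- list(monoculture_mean = as.list(scenario$monoculture_mean),
              monoculture_cv = scenario$monoculture_cv,
              block_sd = scenario$block_sd,
              mixture_dominance = as.list(scenario$mixture_dominance),
              complementarity_boost = scenario$complementarity_boost,
              invader = unclass(scenario$invader),
              seed = scenario$seed)
  # full precision so a round-tripped scenario simulates identically
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  scenario(monoculture_mean = unlist(obj$monoculture_mean),
           monoculture_cv = obj$monoculture_cv,
           block_sd = obj$block_sd,
           mixture_dominance = unlist(obj$mixture_dominance),
           complementarity_boost = obj$complementarity_boost,
           invader = do.call(invader_model, obj$invader),
           seed = obj$seed)
}
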