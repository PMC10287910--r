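#' Hill binding parameters for EMSA titrations
#'
#' @param kd_nM dissociation constant (nM) of protein-DNA binding.
#' @param n Hill cooperativity coefficient (>= 1).
#' @param plateau saturation plateau of the bound fraction, in (0, 1].
#' @return an object of class \code{hill_params}.
#' @export
hill_params <- function(kd_nM, n = 1, plateau = 1) {
  if (kd_nM <= 0) stop("KD must be positive")
  if (n < 1) stop("Hill coefficient must be >= 1")
  if (plateau <= 0 || plateau > 1) stop("plateau must be in (0, 1]")
  structure(list(kd_nM = kd_nM, n = n, plateau = plateau),
            class = "hill_params")
}

#' Two-state thermal-melt parameters (CD theta-220 readout)
#'
#' @param tm_C melting midpoint (degC).
#' @param slope_C cooperativity width of the transition (degC, > 0).
#' @param theta_folded,theta_unfolded ellipticity baselines (a.u.).
#' @return an object of class \code{melt_params}.
#' @export
melt_params <- function(tm_C, slope_C = 1.8, theta_folded = -10,
                        theta_unfolded = -2) {
  if (slope_C <= 0) stop("slope must be positive")
  structure(list(tm_C = tm_C, slope_C = slope_C,
                 theta_folded = theta_folded,
                 theta_unfolded = theta_unfolded),
            class = "melt_params")
}

#' Double-exponential FRAP recovery parameters
#'
#' @param fraction_fast,fraction_slow,fraction_immobile population fractions,
#'   each in [0, 1], summing to at most 1. The recovery asymptote is
#'   \code{1 - fraction_immobile}.
#' @param tau_fast,tau_slow recovery time constants (s), with
#'   \code{tau_fast < tau_slow}.
#' @return an object of class \code{frap_params}.
#' @export
frap_params <- function(fraction_fast, fraction_slow, fraction_immobile,
                        tau_fast, tau_slow) {
  fr <- c(fraction_fast, fraction_slow, fraction_immobile)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (sum(fr) > 1 + 1e-9) stop("fractions must sum to at most 1")
  if (tau_fast >= tau_slow) stop("tau_fast must be smaller than tau_slow")
  if (tau_fast <= 0) stop("time constants must be positive")
  structure(list(fraction_fast = fraction_fast, fraction_slow = fraction_slow,
                 fraction_immobile = fraction_immobile, tau_fast = tau_fast,
                 tau_slow = tau_slow),
            class = "frap_params")
}

#' Convert a nonspecific-DNA mass concentration to 30 bp binding sites
#'
#' The well-mixed model represents nonspecific DNA as a pool of independent
#' dimer-binding sites of 30 bp (one active ParA2 dimer footprint). Assumes
#' 650 g/mol per bp.
#'
#' @param mg_per_ml DNA mass concentration (mg/ml).
#' @param bp_per_site footprint in bp (default 30).
#' @return site concentration in uM.
#' @export
dna_sites_uM <- function(mg_per_ml, bp_per_site = 30) {
  mg_per_ml / (650 * bp_per_site) * 1e6
}
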