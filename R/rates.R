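#' Rate constants of the ParA2 ATPase cycle
#'
#' Bundles the elementary rate constants of the ParA2 nucleotide cycle into a
#' validated parameter vector. The cycle tracked by the package is:
#' apo dimer D binds ATP to a closed sandwich dimer (\code{k1}, \code{k_minus1});
#' the closed dimer remodels slowly to the DNA-binding-competent open state
#' D*-ATP (\code{k2}, accelerated \code{k2_dna_factor}-fold by DNA); D*-ATP
#' loads cooperatively onto nonspecific DNA sites (\code{k3}, \code{k_minus3},
#' mean-field cooperativity \code{coop_omega}); hydrolysis releases the
#' ADP-bound dimer from DNA (\code{k4}, stimulated by cofactors); ADP
#' dissociates (\code{k5}, \code{k_minus5}); and ADP-loaded dimers can swap
#' nucleotide directly at the slow effective exchange constants \code{k6_*}.
#'
#' Concentration convention: the model tracks dimers internally; user-facing
#' protein concentrations are monomer-based and halved on entry (ParA2 is a
#' constitutive dimer in solution). Second-order constants are per-uM per-s;
#' first-order constants are per-s.
#'
#' Defaults are calibrated once so that the observed rates of the standard
#' assays emerge at the concentrations at which they were measured:
#' MANT-ATP binding kobs ~0.12/s at 25 uM with KD = k_minus1/k1 = 8 uM;
#' tryptophan-switch kobs ~0.017/s (k2 plus the small solution-phase
#' hydrolysis leak \code{k_hyd}); DNA-carpet association 0.05/s at 1 uM
#' protein (k3 * 0.5 uM dimer) and wash decay 0.1/s
#' (k4 * stim_dna + k_minus3); nucleotide-exchange constants as printed.
#'
#' @param k1 ATP association to the apo dimer (per-uM per-s).
#' @param k_minus1 ATP dissociation from the closed dimer (per-s).
#' @param k2 conformational remodeling of the closed dimer to the active
#'   DNA-binding state (per-s).
#' @param k2_dna_factor dimensionless fold-acceleration of \code{k2} by DNA
#'   (>= 1).
#' @param k3 DNA-site association of the active dimer (per-uM(site) per-s).
#' @param k_minus3 dissociation of the DNA-bound dimer without hydrolysis
#'   (per-s).
#' @param coop_omega mean-field nearest-neighbour cooperativity factor
#'   multiplying \code{k3} in proportion to the current bound fraction (>= 1).
#' @param k4 hydrolysis-coupled release of the ADP dimer from DNA (per-s,
#'   basal; multiplied by the condition's stimulation factor).
#' @param stim_dna,stim_parb,stim_both fold-stimulation of hydrolysis by
#'   nonspecific DNA, ParB2, or both (basal = 1; each >= 1).
#' @param k5 ADP association (per-uM per-s).
#' @param k_minus5 ADP dissociation (per-s).
#' @param k6_adp_to_atp,k6_adp_to_adp,k6_atp_to_atp effective second-order
#'   nucleotide-exchange constants (per-uM per-s); each must not exceed
#'   \code{k1} (exchange is slower than direct binding).
#' @param kcat basal catalytic turnover of the cycle (ATP per dimer per s),
#'   used by the bulk ATPase forward model.
#' @param k_hyd solution-phase hydrolysis of the active D*-ATP dimer (per-s,
#'   basal; multiplied by the condition's stimulation factor).
#' @return An object of class \code{para_rates} (a validated named list).
#' @examples
#' r <- rate_set()
#' r$k_minus1 / r$k1   # nucleotide KD in uM
#' @export
rate_set <- function(k1 = 0.0035, k_minus1 = 0.028,
                     k2 = 0.016, k2_dna_factor = 3,
                     k3 = 0.1, k_minus3 = 0.02, coop_omega = 2,
                     k4 = 0.04, stim_dna = 2, stim_parb = 3, stim_both = 8,
                     k5 = 0.0035, k_minus5 = 0.028,
                     k6_adp_to_atp = 6.5e-4, k6_adp_to_adp = 6.1e-4,
                     k6_atp_to_atp = 1.4e-3,
                     kcat = 0.008, k_hyd = 0.0018) {
  r <- list(k1 = k1, k_minus1 = k_minus1, k2 = k2,
            k2_dna_factor = k2_dna_factor, k3 = k3, k_minus3 = k_minus3,
            coop_omega = coop_omega, k4 = k4, stim_dna = stim_dna,
            stim_parb = stim_parb, stim_both = stim_both, k5 = k5,
            k_minus5 = k_minus5, k6_adp_to_atp = k6_adp_to_atp,
            k6_adp_to_adp = k6_adp_to_adp, k6_atp_to_atp = k6_atp_to_atp,
            kcat = kcat, k_hyd = k_hyd)
  class(r) <- "para_rates"
  validate_rate_set(r)
  r
}

#' Validate a ParA2 rate set
#'
#' Checks the invariants of a \code{para_rates} object: all rates
#' non-negative, stimulation and cooperativity factors at least 1, finite
#' positive nucleotide dissociation constants where the binding constants are
#' non-zero, and exchange constants no faster than direct ATP binding.
#'
#' @param r a \code{para_rates} object (or plain named list with the same
#'   fields).
#' @return \code{r}, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_rate_set <- function(r) {
  num <- unlist(r[setdiff(names(r), character(0))])
  if (any(!is.finite(num))) stop("rate set contains non-finite values")
  if (any(num < 0)) stop("all rate constants must be >= 0")
  for (f in c("stim_dna", "stim_parb", "stim_both", "coop_omega",
              "k2_dna_factor")) {
    if (r[[f]] < 1) stop(sprintf("%s must be >= 1", f))
  }
  if (r$k1 > 0) {
    kd <- r$k_minus1 / r$k1
    if (!is.finite(kd) || kd <= 0) stop("ATP KD (k_minus1/k1) must be finite and positive")
  }
  if (r$k5 > 0) {
    kd <- r$k_minus5 / r$k5
    if (!is.finite(kd) || kd <= 0) stop("ADP KD (k_minus5/k5) must be finite and positive")
  }
  if (r$k1 > 0) {
    k6 <- c(r$k6_adp_to_atp, r$k6_adp_to_adp, r$k6_atp_to_atp)
    if (any(k6 > r$k1)) {
      stop("nucleotide-exchange constants k6_* must not exceed k1")
    }
  }
  invisible(r)
}

#' @export
print.para_rates <- function(x, ...) {
  cat("ParA2 cycle rate set\n")
  cat(sprintf("  ATP binding      k1 = %.4g /uM/s, k-1 = %.4g /s (KD = %.3g uM)\n",
              x$k1, x$k_minus1, if (x$k1 > 0) x$k_minus1 / x$k1 else NA))
  cat(sprintf("  remodeling       k2 = %.4g /s (x%.3g with DNA)\n",
              x$k2, x$k2_dna_factor))
  cat(sprintf("  DNA loading      k3 = %.4g /uM/s, k-3 = %.4g /s, omega = %.3g\n",
              x$k3, x$k_minus3, x$coop_omega))
  cat(sprintf("  hydrolysis       k4 = %.4g /s (stim %g/%g/%g), k_hyd = %.4g /s, kcat = %.4g ATP/dimer/s\n",
              x$k4, x$stim_dna, x$stim_parb, x$stim_both, x$k_hyd, x$kcat))
  cat(sprintf("  ADP binding      k5 = %.4g /uM/s, k-5 = %.4g /s (KD = %.3g uM)\n",
              x$k5, x$k_minus5, if (x$k5 > 0) x$k_minus5 / x$k5 else NA))
  cat(sprintf("  exchange         ADP->ATP %.3g, ADP->ADP %.3g, ATP->ATP %.3g /uM/s\n",
              x$k6_adp_to_atp, x$k6_adp_to_adp, x$k6_atp_to_atp))
  invisible(x)
}

#' Hydrolysis stimulation factor for an assay condition
#'
#' Returns the fold-stimulation of ATP hydrolysis implied by which cofactors
#' are present: both DNA and ParB2, DNA alone, ParB2 alone, or neither
#' (basal = 1).
#'
#' @param rates a \code{para_rates} object.
#' @param dna,parb logical; cofactor presence.
#' @return a single numeric factor.
#' @export
stim_factor <- function(rates, dna = FALSE, parb = FALSE) {
  if (dna && parb) rates$stim_both
  else if (dna) rates$stim_dna
  else if (parb) rates$stim_parb
  else 1
}
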