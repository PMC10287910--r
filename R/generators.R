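#' Stopped-flow sampling grid
#'
#' Dense early sampling (10 ms steps for the first 30 s) then 100 ms steps,
#' mimicking a split-timebase stopped-flow acquisition.
#' @param duration total span (s).
#' @return numeric time grid starting at 0.
#' @keywords internal
stopped_flow_grid <- function(duration) {
  if (duration <= 30) return(seq(0, duration, by = 0.01))
  c(seq(0, 30, by = 0.01), seq(30.1, duration, by = 0.1))
}

#' Synthetic stopped-flow MANT-nucleotide kinetics
#'
#' Generates the fluorescence time course of a MANT-nucleotide stopped-flow
#' experiment by integrating the cycle model and projecting the
#' ParA2-bound labelled-nucleotide concentration (MANT fluorescence rises on
#' protein binding). Three protocols:
#' \describe{
#'   \item{binding}{apo ParA2 rapidly mixed with MANT-AXP; fluorescence rise.}
#'   \item{dissociation}{ParA2 pre-incubated with MANT-AXP (180 s), then
#'     chased with excess unlabelled AXP; fluorescence decay.}
#'   \item{exchange}{ParA2 pre-loaded with unlabelled AXP, then mixed with
#'     MANT-AXP; the labelled signal rises at the effective exchange rate.
#'     Exchange is modelled as the effective second-order swap reactions
#'     (direct release-then-rebind is folded into the effective constants, so
#'     the observed slope of kobs vs concentration is the exchange constant
#'     itself).}
#' }
#'
#' @param rates a \code{para_rates} object.
#' @param protocol one of "binding", "dissociation", "exchange".
#' @param parA2_uM ParA2 concentration, monomer basis (uM).
#' @param mant_uM MANT-nucleotide concentration (uM).
#' @param nucleotide "ATP" or "ADP" (selects MANT-ATP or MANT-ADP).
#' @param chase_uM unlabelled chase concentration for the dissociation
#'   protocol (uM).
#' @param preload_ratio unlabelled AXP : ParA2 monomer ratio for the exchange
#'   protocol (paper protocol: 5).
#' @param duration trace span (s); protocol-specific default.
#' @param noise_sigma iid Gaussian noise, as fraction of the dynamic range.
#' @param seed RNG seed (required when noise_sigma > 0).
#' @return a \code{para_trace}; y is the bound-label fraction (relative
#'   fluorescence). Flag \code{"excess assumption violated"} is set when the
#'   nucleotide is not in at least 10-fold excess over ParA2 in the binding
#'   protocol.
#' @export
gen_mant_kinetics <- function(rates, protocol = c("binding", "dissociation",
                                                  "exchange"),
                              parA2_uM = 1.25, mant_uM = 25,
                              nucleotide = c("ATP", "ADP"), chase_uM = 1000,
                              preload_ratio = 5, duration = NULL,
                              noise_sigma = 0, seed = NA_integer_) {
  protocol <- match.arg(protocol)
  nucleotide <- match.arg(nucleotide)
  dimer <- parA2_uM / 2
  m_nt <- if (nucleotide == "ATP") "mATP" else "mADP"
  flags <- character()

  if (protocol == "binding") {
    duration <- duration %||% 30
    if (mant_uM < 10 * parA2_uM) flags <- "excess assumption violated"
    scheme <- assemble_scheme(rates, assay_condition(nucleotide = nucleotide))
    init <- species_state(stats::setNames(c(dimer, mant_uM), c("D", m_nt)))
    traj <- integrate_scheme(scheme, init, stopped_flow_grid(duration))
    y <- bound_label(traj) / mant_uM
  } else if (protocol == "dissociation") {
    duration <- duration %||% 200
    scheme <- assemble_scheme(rates, assay_condition(nucleotide = nucleotide))
    init <- species_state(stats::setNames(c(dimer, mant_uM), c("D", m_nt)))
    pre <- integrate_scheme(scheme, init, seq(0, 180, by = 1))
    start <- pre$state[nrow(pre$state), ]
    start[[nucleotide]] <- start[[nucleotide]] + chase_uM
    # competitive displacement: the excess unlabelled chase makes label
    # release effectively irreversible; the effective exchange constants are
    # measured-range constructs and are not extrapolated to millimolar chase
    ch_rates <- rates
    ch_rates$k6_adp_to_atp <- 0
    ch_rates$k6_adp_to_adp <- 0
    ch_rates$k6_atp_to_atp <- 0
    scheme <- assemble_scheme(ch_rates, assay_condition(nucleotide = nucleotide))
    traj <- integrate_scheme(scheme, start, stopped_flow_grid(duration))
    y <- bound_label(traj)
    y <- y / y[1]
  } else {  # exchange
    duration <- duration %||% 200
    if (mant_uM < 10 * parA2_uM) flags <- "excess assumption violated"
    ex_rates <- rates
    ex_rates$k1 <- 0; ex_rates$k_minus1 <- 0
    ex_rates$k5 <- 0; ex_rates$k_minus5 <- 0
    scheme <- assemble_scheme(ex_rates, assay_condition(nucleotide = "ATP"))
    preload_uM <- preload_ratio * parA2_uM
    free_nt <- max(preload_uM - 2 * dimer, 0)
    loaded <- if (nucleotide == "ATP") "DD" else "DD"
    # preloaded with unlabelled ADP (the ADP -> AXP exchange protocols);
    # incoming nucleotide is labelled
    init <- species_state(stats::setNames(
      c(dimer, free_nt, mant_uM), c(loaded, "ADP", m_nt)))
    traj <- integrate_scheme(scheme, init, stopped_flow_grid(duration))
    y <- bound_label(traj) / (2 * dimer)
  }

  tr <- para_trace(x = traj$time, y = y,
                   assay = paste0("mant_", protocol),
                   condition = list(protocol = protocol,
                                    nucleotide = nucleotide,
                                    parA2_uM = parA2_uM, mant_uM = mant_uM),
                   params = list(rates = unclass(rates)),
                   x_unit = "time_s", y_unit = "rel_fluor", flags = flags)
  add_noise(tr, noise_sigma * diff(range(y)), seed)
}

bound_label <- function(traj) {
  s <- traj$state
  2 * (s[, "mDT"] + s[, "mDS"] + s[, "mB"] + s[, "mDD"])
}

#' Synthetic tryptophan-fluorescence conformational-switch kinetics
#'
#' Intrinsic tryptophan fluorescence reports the ParA2 conformational state:
#' the remodeled D*-ATP dimer raises the signal by 5 percent and the
#' DNA-bound state by 13 percent over the apo baseline. The generator
#' integrates the cycle under the named condition and projects those weights;
#' control conditions with no conformational signal (ADP, ATPgS without DNA,
#' no Mg2+) carry a slow linear photobleaching drift.
#'
#' @param rates a \code{para_rates}.
#' @param condition one of "ATP", "ATP+DNA", "ADP", "ATPgS", "ATPgS+DNA",
#'   "no-Mg", "ATP+ParB2", "ATP+DNA+ParB2".
#' @param parA2_uM ParA2 monomer concentration (uM, final after mixing).
#' @param nucleotide_uM nucleotide concentration (uM, final).
#' @param dna_mg_ml nonspecific DNA (mg/ml, final) when the condition
#'   includes DNA.
#' @param duration span (s).
#' @param bleach_rate linear photobleach drift for control conditions
#'   (relative units per s; default 2e-4 = 0.02 percent/s).
#' @param noise_sigma,seed noise model as in [gen_mant_kinetics()].
#' @return a \code{para_trace} of relative fluorescence vs time.
#' @export
gen_trp_switch <- function(rates, condition = "ATP", parA2_uM = 0.6,
                           nucleotide_uM = 1000, dna_mg_ml = 0.1,
                           duration = 400, bleach_rate = 2e-4,
                           noise_sigma = 0, seed = NA_integer_) {
  known <- c("ATP", "ATP+DNA", "ADP", "ATPgS", "ATPgS+DNA", "no-Mg",
             "ATP+ParB2", "ATP+DNA+ParB2")
  if (!condition %in% known) {
    stop("unknown condition '", condition, "'")
  }
  parts <- strsplit(condition, "+", fixed = TRUE)[[1]]
  nt <- if (parts[1] == "no-Mg") "ATP" else parts[1]
  cond <- assay_condition(nucleotide = nt, dna = "DNA" %in% parts,
                          parb = "ParB2" %in% parts,
                          mg = parts[1] != "no-Mg")
  scheme <- assemble_scheme(rates, cond)
  dimer <- parA2_uM / 2
  init_named <- c(D = dimer)
  # ATPgS shares the ATP pool species; its chemistry is encoded in the scheme
  init_named[if (nt == "ADP") "ADP" else "ATP"] <- nucleotide_uM
  if (cond$dna) init_named["sites"] <- dna_sites_uM(dna_mg_ml)
  if (cond$parb) init_named["ParB"] <- parA2_uM
  init <- species_state(init_named)
  grid <- c(seq(0, 30, by = 0.05), seq(30.2, duration, by = 0.2))
  traj <- integrate_scheme(scheme, init, grid)
  s <- traj$state
  y <- 1 + (0.05 * (s[, "DS"] + s[, "mDS"]) + 0.13 * (s[, "B"] + s[, "mB"])) / dimer
  # photobleaching drift on conditions without a conformational signal
  if (condition %in% c("ADP", "ATPgS", "no-Mg")) {
    y <- y - bleach_rate * traj$time
  }
  tr <- para_trace(x = traj$time, y = y, assay = "trp_switch",
                   condition = list(condition = condition,
                                    parA2_uM = parA2_uM),
                   params = list(rates = unclass(rates)),
                   x_unit = "time_s", y_unit = "rel_fluor")
  rng <- diff(range(y))
  add_noise(tr, noise_sigma * if (rng > 0) rng else 1, seed)
}

#' Synthetic EMSA titration (fraction DNA bound vs protein)
#'
#' Cooperative Hill binding of ParA2 to a short nonspecific DNA probe:
#' \code{f(c) = plateau * c^n / (KD^n + c^n)}, with iid Gaussian noise
#' truncated to [0, 1] (clipping counted, never silent).
#'
#' @param params a \code{hill_params}.
#' @param protein_nM protein concentrations (nM); at least 6, spanning KD.
#' @param noise_sigma sd of the added noise (fraction-bound units).
#' @param seed RNG seed.
#' @return a \code{para_trace} with x = concentration (nM), y = fraction
#'   bound. Flag \code{"titration below KD"} when every concentration is
#'   below KD (downstream fit will be unidentifiable).
#' @export
gen_emsa <- function(params, protein_nM = exp(seq(log(10), log(1200),
                                                  length.out = 8)),
                     noise_sigma = 0, seed = NA_integer_) {
  stopifnot(inherits(params, "hill_params"))
  protein_nM <- sort(protein_nM)
  f <- params$plateau * protein_nM^params$n /
    (params$kd_nM^params$n + protein_nM^params$n)
  flags <- if (max(protein_nM) < params$kd_nM) "titration below KD" else character()
  tr <- para_trace(x = protein_nM, y = f, assay = "emsa",
                   condition = list(kd_nM = params$kd_nM, n = params$n),
                   params = unclass(params),
                   x_unit = "parA2_nM", y_unit = "fraction_bound",
                   flags = flags)
  add_noise(tr, noise_sigma, seed, clip = c(0, 1))
}

#' Synthetic DNA-carpet TIRF time course with a flow switch
#'
#' Piecewise kinetics of ParA2-GFP on a DNA carpet in a two-inlet flowcell:
#' an association phase while sample flows (one-phase exponential toward the
#' steady-state plateau; the rate is \code{k3} times the active-dimer supply,
#' which is instantaneous for nucleotide-pre-incubated protein and limited by
#' the remodeling rate \code{k2} in an ATP-start experiment), then at
#' \code{t_switch} the flow switches to wash buffer, the free protein
#' concentration drops to zero and the bound signal decays biphasically: a
#' fast hydrolysis-stimulated phase at \code{k4 * stim_dna + k_minus3} and a
#' slower protected fraction at \code{k_minus3}. With ATPgS the hydrolysis
#' path is absent and both phases collapse to \code{k_minus3}; with ADP or
#' no nucleotide the carpet plateau is negligible.
#'
#' Carpet attachment in the ATP-start case scales with the square of the
#' active-dimer supply (the 69 bp loading unit carries two dimers), which
#' produces the characteristic delay of about a minute before the signal
#' rises.
#'
#' @param rates a \code{para_rates}.
#' @param protein_uM ParA2-GFP concentration (uM, monomer).
#' @param t_switch flow-switch time (s, > 0).
#' @param condition "ATP", "ADP", "ATPgS" or "none".
#' @param preincubated logical; protein pre-incubated with the nucleotide
#'   (supply of active dimers already at steady state) or mixed at t = 0
#'   ("ATP-start").
#' @param duration total span (s).
#' @param frame_s frame interval (s).
#' @param slow_fraction protected bound fraction decaying at \code{k_minus3}
#'   during the wash.
#' @param noise_sigma,seed noise model (sigma as fraction of dynamic range).
#' @return a \code{para_trace} of carpet-bound intensity (normalized to the
#'   full-carpet ATP plateau) vs time.
#' @export
gen_carpet_timecourse <- function(rates, protein_uM = 1, t_switch = 360,
                                  condition = c("ATP", "ADP", "ATPgS", "none"),
                                  preincubated = TRUE, duration = 600,
                                  frame_s = 1, slow_fraction = 0.25,
                                  noise_sigma = 0, seed = NA_integer_) {
  condition <- match.arg(condition)
  if (t_switch <= 0) stop("t_switch must be positive")
  tt <- seq(0, duration, by = frame_s)
  dimer <- protein_uM / 2
  # concentration-dependent plateau: cooperative occupancy of the carpet
  plateau <- if (condition %in% c("ATP", "ATPgS")) {
    protein_uM^2 / (0.5^2 + protein_uM^2)
  } else {
    0.02
  }
  supply2 <- function(t) {  # squared active-dimer supply fraction
    if (condition %in% c("ADP", "none")) return(rep(0, length(t)))
    if (preincubated) {
      s <- if (condition == "ATPgS") 0.4 else 1
      return(rep(s^2, length(t)))
    }
    s <- 1 - exp(-rates$k2 * t)
    s^2
  }
  ka <- rates$k3 * dimer
  # occupancy from dB/dt = ka * supply2(t) * (1 - B)
  icum <- cumsum(c(0, (supply2(tt[-1]) + supply2(tt[-length(tt)])) / 2 *
                     diff(tt)))
  b <- 1 - exp(-ka * icum)
  y <- plateau * b
  wash <- tt > t_switch
  if (any(wash)) {
    b_s <- stats::approx(tt, y, xout = t_switch)$y
    tau <- tt[wash] - t_switch
    k_fast <- rates$k_minus3 +
      if (condition == "ATP") rates$k4 * rates$stim_dna else 0
    k_slow <- rates$k_minus3
    y[wash] <- b_s * (slow_fraction * exp(-k_slow * tau) +
                        (1 - slow_fraction) * exp(-k_fast * tau))
  }
  tr <- para_trace(x = tt, y = y, assay = "carpet",
                   condition = list(condition = condition,
                                    preincubated = preincubated,
                                    protein_uM = protein_uM,
                                    t_switch = t_switch),
                   params = list(rates = unclass(rates),
                                 slow_fraction = slow_fraction),
                   x_unit = "time_s", y_unit = "carpet_intensity")
  rng <- diff(range(y))
  add_noise(tr, noise_sigma * if (rng > 0) rng else 1, seed)
}

#' Synthetic FRAP recovery curve
#'
#' Double-exponential recovery after a sub-second photobleach:
#' \code{y(t) = (1 - immobile) - f_fast exp(-t/tau_fast) -
#' f_slow exp(-t/tau_slow)}, starting near zero and recovering toward
#' \code{1 - immobile}.
#'
#' @param params a \code{frap_params}.
#' @param duration span (s).
#' @param frame_s frame interval (s).
#' @param noise_sigma,seed noise model (sigma in normalized-recovery units).
#' @return a \code{para_trace} of normalized recovery vs time.
#' @export
gen_frap <- function(params, duration = 600, frame_s = 0.5,
                     noise_sigma = 0, seed = NA_integer_) {
  stopifnot(inherits(params, "frap_params"))
  tt <- seq(0, duration, by = frame_s)
  y <- (1 - params$fraction_immobile) -
    params$fraction_fast * exp(-tt / params$tau_fast) -
    params$fraction_slow * exp(-tt / params$tau_slow)
  tr <- para_trace(x = tt, y = y, assay = "frap",
                   condition = list(), params = unclass(params),
                   x_unit = "time_s", y_unit = "norm_recovery")
  add_noise(tr, noise_sigma, seed)
}

#' Synthetic radiolabel ATP-hydrolysis time course or titration
#'
#' Coarse-grained turnover model of the cycle: hydrolysis flux
#' \code{kcat * stim(condition) * [dimer] * S / (KM + S)} with finite
#' substrate S, so the fixed-time titration saturates at high ParA2 through
#' substrate depletion. Fold-stimulation by DNA, ParB2 or both multiplies the
#' turnover, matching how stimulation is measured (ratio of percent
#' hydrolyzed at equal time in the linear regime). A rate set with
#' \code{k1 = 0} (no ATP binding) or \code{kcat = 0} yields background only.
#'
#' @param rates a \code{para_rates}.
#' @param condition "basal", "DNA", "ParB2" or "both".
#' @param parA2_uM ParA2 monomer concentration (uM); scalar for the
#'   pre-steady-state mode, or a vector (titration) with \code{fixed_time_s}.
#' @param atp_uM initial ATP (uM).
#' @param t_points_s sampling times (s) for the time-course mode.
#' @param fixed_time_s incubation time (s) for the titration mode.
#' @param km_uM Michaelis constant of the turnover coarse-graining (uM).
#' @param noise_sigma,seed noise model (sigma in percent-hydrolyzed units).
#' @return a \code{para_trace}; x is time (s) or ParA2 (uM), y is percent ATP
#'   hydrolyzed.
#' @export
gen_atpase <- function(rates, condition = c("basal", "DNA", "ParB2", "both"),
                       parA2_uM = 1.5, atp_uM = 200,
                       t_points_s = seq(0, 3600, by = 360),
                       fixed_time_s = 1800, km_uM = 20,
                       noise_sigma = 0, seed = NA_integer_) {
  condition <- match.arg(condition)
  stim <- switch(condition, basal = 1, DNA = rates$stim_dna,
                 ParB2 = rates$stim_parb, both = rates$stim_both)
  kcat_eff <- if (rates$k1 <= 0) 0 else rates$kcat
  hydrolyzed <- function(conc_uM, t_s) {
    # integrate dP/dt = v * (S0 - P) / (KM + S0 - P)
    v <- kcat_eff * stim * conc_uM / 2
    if (v == 0 || t_s == 0) return(0)
    f <- function(t, y, p) {
      s <- max(atp_uM - y[1], 0)
      list(v * s / (km_uM + s))
    }
    out <- deSolve::lsoda(c(P = 0), c(0, t_s), f, NULL,
                          rtol = 1e-8, atol = 1e-10)
    out[nrow(out), 2]
  }
  if (length(parA2_uM) > 1) {
    x <- sort(parA2_uM)
    y <- vapply(x, hydrolyzed, numeric(1), t_s = fixed_time_s)
    x_unit <- "parA2_uM"
  } else {
    x <- t_points_s
    y <- vapply(x, function(t) hydrolyzed(parA2_uM, t), numeric(1))
    x_unit <- "time_s"
  }
  y <- 100 * y / atp_uM
  tr <- para_trace(x = x, y = y, assay = "atpase",
                   condition = list(condition = condition, stim = stim,
                                    atp_uM = atp_uM),
                   params = list(rates = unclass(rates), km_uM = km_uM),
                   x_unit = x_unit, y_unit = "pct_hydrolyzed")
  add_noise(tr, noise_sigma, seed, clip = c(0, 100))
}

#' Synthetic CD thermal melt (theta-220 vs temperature)
#'
#' Two-state unfolding sigmoid between folded and unfolded ellipticity
#' baselines with midpoint Tm, sampled on the instrument's temperature ramp
#' (2 degC increments by default).
#'
#' @param params a \code{melt_params}.
#' @param t_grid_C temperature grid (degC).
#' @param noise_sigma,seed noise model (sigma in ellipticity a.u.).
#' @return a \code{para_trace} of ellipticity vs temperature; flag
#'   \code{"Tm outside scanned range"} when applicable.
#' @export
gen_thermal_melt <- function(params, t_grid_C = seq(23, 63, by = 2),
                             noise_sigma = 0, seed = NA_integer_) {
  stopifnot(inherits(params, "melt_params"))
  th <- params$theta_folded +
    (params$theta_unfolded - params$theta_folded) /
    (1 + exp((params$tm_C - t_grid_C) / params$slope_C))
  flags <- if (params$tm_C < min(t_grid_C) || params$tm_C > max(t_grid_C)) {
    "Tm outside scanned range"
  } else {
    character()
  }
  tr <- para_trace(x = t_grid_C, y = th, assay = "thermal_melt",
                   condition = list(tm_C = params$tm_C),
                   params = unclass(params),
                   x_unit = "temperature_C", y_unit = "theta220_au",
                   flags = flags)
  add_noise(tr, noise_sigma, seed)
}
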