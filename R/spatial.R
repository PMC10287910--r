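#' Configuration of the 1D tug-of-war cell simulator
#'
#' Describes a rod-shaped cell of length \code{L} discretized into \code{N}
#' lattice sites on which ParA2 cycles between four cytoplasmic states
#' (ADP-bound, apo, closed ATP dimer, remodeled active dimer) and a
#' nucleoid-bound state. The nucleoid spans the whole cell. Cytoplasmic
#' states diffuse with \code{d_cyto}; the bound state is (nearly) immobile.
#' A ParB2-parS2 focus occupies a window around \code{focus_pos} and
#' multiplies the local hydrolysis-release rate by \code{focus_stim},
#' modelling ParB2-stimulated ATP hydrolysis at the partition complex. The
#' tug on the focus is not mechanically modelled: the focus is a fixed
#' position acting as a localized sink.
#'
#' @param rates a \code{para_rates}; the cycle constants feed the lattice
#'   rates (ATP binding, remodeling delay, nucleoid loading and release,
#'   ADP release and exchange at the fixed cytoplasmic ATP level).
#' @param L cell length (um).
#' @param N lattice sites (>= 50).
#' @param d_cyto cytoplasmic diffusion coefficient (um^2/s).
#' @param d_bound bound-state diffusion coefficient (um^2/s, ~0).
#' @param copies total ParA2 dimers in the cell.
#' @param focus_pos focus centre as a fraction of cell length in [0, 1].
#' @param focus_width focus width as a fraction of cell length.
#' @param focus_stim local fold-stimulation of hydrolysis-release at the
#'   focus (1 = knockout, no ParB2 effect).
#' @param focus_mode "fixed" (the focus stays at \code{focus_pos}) or
#'   "tracking" (the focus drifts toward the bound-ParA2 centroid at
#'   \code{focus_speed}, the scripted stand-in for the tug exerted by the
#'   ParA2 wave on the partition complex; required for sustained pole-to-pole
#'   oscillations in the mean-field engine).
#' @param focus_speed focus drift speed (um/s) in tracking mode.
#' @param site_capacity nucleoid binding capacity per lattice site (dimers).
#' @param atp_uM fixed cytoplasmic ATP concentration (uM).
#' @param nucleoid_sites_uM effective nucleoid site concentration seen by an
#'   active dimer (uM); with \code{rates$k3} this sets the attachment rate.
#' @param t_end simulation span (s).
#' @param dt_record kymograph frame interval (s).
#' @param seed integer seed for the stochastic engine.
#' @return an object of class \code{spatial_config}.
#' @export
spatial_config <- function(rates = rate_set(), L = 2, N = 100, d_cyto = 3,
                           d_bound = 0, copies = 1200, focus_pos = 0.5,
                           focus_width = 0.1, focus_stim = 40,
                           focus_mode = c("fixed", "tracking"),
                           focus_speed = 0.01, site_capacity = NULL,
                           atp_uM = 1000, nucleoid_sites_uM = 10,
                           t_end = 1800, dt_record = 2, seed = 1L) {
  focus_mode <- match.arg(focus_mode)
  if (L <= 0) stop("cell length must be positive")
  if (N < 50) stop("lattice must have at least 50 sites")
  if (d_cyto < 0 || d_bound < 0) stop("diffusion coefficients must be >= 0")
  if (any(focus_pos < 0 | focus_pos > 1)) {
    stop("focus positions must lie in [0, 1]")
  }
  if (focus_stim < 1) stop("focus stimulation factor must be >= 1")
  if (is.null(site_capacity)) {
    site_capacity <- ceiling(1.6 * copies / N)
  }
  structure(list(rates = rates, L = L, N = as.integer(N), d_cyto = d_cyto,
                 d_bound = d_bound, copies = as.integer(copies),
                 focus_pos = focus_pos, focus_width = focus_width,
                 focus_stim = focus_stim, focus_mode = focus_mode,
                 focus_speed = focus_speed,
                 site_capacity = as.integer(site_capacity), atp_uM = atp_uM,
                 nucleoid_sites_uM = nucleoid_sites_uM, t_end = t_end,
                 dt_record = dt_record, seed = as.integer(seed)),
            class = "spatial_config")
}

spatial_rates <- function(cfg) {
  r <- cfg$rates
  h <- cfg$L / cfg$N
  # away from the focus, hydrolysis-release runs at the bulk DNA-stimulated
  # scale; the ParB2 focus lifts it toward the fast (carpet-scale) release
  k_hyd_base <- r$k_hyd * r$stim_dna
  list(k_bind = r$k1 * cfg$atp_uM,
       k_unbind = r$k_minus1,
       k_remodel = r$k2,
       k_on = r$k3 * cfg$nucleoid_sites_uM,
       omega = r$coop_omega,
       k_off = r$k_minus3,
       k_hyd_base = k_hyd_base,
       k_adp_release = r$k_minus5,
       k_exch = r$k6_adp_to_atp * cfg$atp_uM,
       hop = cfg$d_cyto / h^2,
       hop_b = cfg$d_bound / h^2)
}

#' Simulate a cell with the 1D tug-of-war model
#'
#' Runs the lattice reaction-diffusion model either as an exact stochastic
#' simulation (\code{engine = "ssa"}, Gillespie direct method, the default)
#' or as the mean-field PDE (\code{engine = "pde"}, method-of-lines with a
#' stiff adaptive solver; a fixed-step explicit solver is also available and
#' enforces the diffusive stability limit). Total ParA2 is conserved exactly
#' in the SSA and to the solver tolerance in the PDE. The PDE preserves the
#' deterministic symmetry of a symmetric initial condition; by default a
#' 2 percent left-right bias is applied to the initial bound seed so that
#' the physically relevant asymmetric attractor is reachable (the SSA breaks
#' symmetry on its own).
#'
#' @param config a \code{spatial_config}.
#' @param engine "ssa" or "pde".
#' @param init_bias fractional left-right bias of the initial bound seed
#'   (PDE only; the SSA starts unbiased and breaks symmetry on its own).
#' @param init_bound fraction of the protein initially seeded into the bound
#'   state in the PDE engine (0 starts fully cytoplasmic, as the SSA does).
#' @param pde_method deSolve method for the PDE engine ("lsoda", or "euler"
#'   with \code{pde_dt}).
#' @param pde_dt fixed step for the explicit PDE solver; must satisfy the
#'   diffusive stability (Courant) limit \code{dt <= h^2 / (2 d_cyto)}.
#' @return a \code{para_kymograph}: list with \code{time}, \code{bound}
#'   (time x site matrix of nucleoid-bound dimers), \code{cyto} (summed
#'   cytoplasmic dimers), \code{x} (site centres, um), \code{config}.
focus_profile <- function(cfg, positions) {
  focus <- rep(1, cfg$N)
  centre <- (seq_len(cfg$N) - 0.5) / cfg$N
  for (fp in positions) {
    focus[abs(centre - fp) <= cfg$focus_width / 2] <- cfg$focus_stim
  }
  focus
}

#' @export
simulate_cell <- function(config, engine = c("ssa", "pde"),
                          init_bias = 0.02, init_bound = 0.02,
                          pde_method = "lsoda", pde_dt = NULL) {
  stopifnot(inherits(config, "spatial_config"))
  engine <- match.arg(engine)
  sr <- spatial_rates(config)
  N <- config$N

  x_centres <- (seq_len(N) - 0.5) * config$L / N
  if (engine == "ssa") {
    init <- matrix(0L, nrow = 5, ncol = N)
    # start with all protein cytoplasmic ADP-bound, uniformly spread
    base <- config$copies %/% N
    extra <- config$copies - base * N
    init[1, ] <- base
    if (extra > 0) init[1, seq_len(extra)] <- init[1, seq_len(extra)] + 1L
    if (config$focus_mode == "fixed") {
      out <- spatial_ssa_cpp(init, config$t_end, config$dt_record,
                             sr$k_bind, sr$k_unbind, sr$k_remodel, sr$k_on,
                             sr$omega, config$site_capacity, sr$k_off,
                             sr$k_hyd_base * focus_profile(config,
                                                           config$focus_pos),
                             sr$k_adp_release, sr$k_exch,
                             sr$hop, sr$hop_b, config$seed)
      tgrid <- out$time
      bound <- out$bound
      cyto <- out$cyto
      exhausted <- out$exhausted
      fpos <- rep(config$focus_pos[1], length(tgrid))
    } else {
      # tracking focus: position updated once per recording frame, drifting
      # toward the bound-mass centroid (scripted tug)
      n_frames <- floor(config$t_end / config$dt_record)
      bound <- matrix(0L, n_frames + 1, N)
      cyto <- matrix(0, n_frames + 1, N)
      tgrid <- (0:n_frames) * config$dt_record
      fpos <- numeric(n_frames + 1)
      p <- config$focus_pos[1]
      state <- init
      exhausted <- FALSE
      bound[1, ] <- state[5, ]
      cyto[1, ] <- colSums(state[1:4, , drop = FALSE])
      fpos[1] <- p
      for (fr in seq_len(n_frames)) {
        out <- spatial_ssa_cpp(state, config$dt_record, config$dt_record,
                               sr$k_bind, sr$k_unbind, sr$k_remodel, sr$k_on,
                               sr$omega, config$site_capacity, sr$k_off,
                               sr$k_hyd_base * focus_profile(config, p),
                               sr$k_adp_release, sr$k_exch,
                               sr$hop, sr$hop_b,
                               config$seed + fr)
        state <- out$final
        exhausted <- exhausted || out$exhausted
        bound[fr + 1, ] <- state[5, ]
        cyto[fr + 1, ] <- colSums(state[1:4, , drop = FALSE])
        btot <- sum(state[5, ])
        if (btot > 0) {
          cf <- x_centres / config$L
          w <- exp(-((cf - p) / 0.15)^2) * state[5, ]
          off <- if (sum(w) > 0) sum(w * (cf - p)) / sum(w) else 0
          p <- p + config$focus_speed * config$dt_record / config$L *
            tanh(off / 0.02)
          p <- min(max(p, 0.05), 0.95)
        }
        fpos[fr + 1] <- p
      }
    }
    kym <- list(time = tgrid, bound = bound, cyto = cyto,
                x = x_centres, config = config,
                engine = "ssa", focus_trajectory = fpos,
                exhausted = exhausted)
  } else {
    h <- config$L / N
    if (identical(pde_method, "euler")) {
      if (is.null(pde_dt)) stop("explicit PDE solver needs pde_dt")
      if (config$d_cyto > 0 && pde_dt > h^2 / (2 * config$d_cyto)) {
        stop(sprintf(
          "Courant condition violated: dt = %.4g > h^2/(2D) = %.4g",
          pde_dt, h^2 / (2 * config$d_cyto)))
      }
    }
    per_site <- config$copies / N
    tracking <- config$focus_mode == "tracking"
    y0 <- c(DD = rep(per_site, N), D = rep(0, N), DT = rep(0, N),
            DS = rep(0, N), B = rep(0, N))
    # seed a slightly asymmetric trace of bound protein
    seedb <- init_bound * per_site *
      (1 + init_bias * sign(seq_len(N) - (N + 1) / 2))
    y0[(4 * N + 1):(5 * N)] <- seedb
    y0[1:N] <- y0[1:N] - seedb
    if (tracking) y0 <- c(y0, fpos = config$focus_pos[1])
    lap <- function(v) (c(v[-1], v[N]) + c(v[1], v[-N]) - 2 * v)
    cap <- config$site_capacity
    centre_frac <- (seq_len(N) - 0.5) / N
    fixed_focus <- sr$k_hyd_base * focus_profile(config, config$focus_pos)
    deriv <- function(t, y, p) {
      DD <- y[1:N]; D <- y[(N + 1):(2 * N)]; DT <- y[(2 * N + 1):(3 * N)]
      DS <- y[(3 * N + 1):(4 * N)]; B <- y[(4 * N + 1):(5 * N)]
      if (tracking) {
        fp <- y[5 * N + 1]
        # smooth focus window for the continuum solver
        w <- config$focus_width / 2
        k_hyd_site <- sr$k_hyd_base *
          (1 + (config$focus_stim - 1) * exp(-((centre_frac - fp) / w)^2))
      } else {
        k_hyd_site <- fixed_focus
      }
      fnb <- (c(B[1], B[-N]) + B + c(B[-1], B[N])) / (3 * cap)
      fnb <- pmin(fnb, 1)
      avail <- pmax(1 - B / cap, 0)
      # nearest-neighbour pair cooperativity (two-dimer loading unit)
      kon <- sr$k_on * (1 + (sr$omega - 1) * fnb^2) * avail
      v_bind <- sr$k_bind * D
      v_unbind <- sr$k_unbind * DT
      v_rem <- sr$k_remodel * DT
      v_on <- kon * DS
      v_off <- sr$k_off * B
      v_hyd <- k_hyd_site * B
      v_rel <- sr$k_adp_release * DD
      v_exch <- sr$k_exch * DD
      dyn <- c(v_hyd - v_rel - v_exch + sr$hop * lap(DD),
               v_unbind + v_rel - v_bind + sr$hop * lap(D),
               v_bind + v_exch - v_unbind - v_rem + sr$hop * lap(DT),
               v_rem + v_off - v_on + sr$hop * lap(DS),
               v_on - v_off - v_hyd + sr$hop_b * lap(B))
      if (tracking) {
        # the focus chases the local bound-ParA2 gradient (diffusion-ratchet
        # tug): density is sensed with a Gaussian kernel around the focus
        w <- exp(-((centre_frac - fp) / 0.15)^2) * B
        wtot <- sum(w)
        off <- if (wtot > 0) sum(w * (centre_frac - fp)) / wtot else 0
        dp <- config$focus_speed / config$L * tanh(off / 0.02)
        dyn <- c(dyn, dp)
      }
      list(dyn)
    }
    times <- seq(0, config$t_end, by = config$dt_record)
    sol <- if (identical(pde_method, "euler")) {
      deSolve::ode(y0, times, deriv, NULL, method = "euler",
                   hini = pde_dt)
    } else {
      deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                   rtol = 1e-8, atol = 1e-10)
    }
    if (nrow(sol) < length(times)) stop("PDE integration failed")
    st <- sol[, -1, drop = FALSE]
    kym <- list(time = sol[, 1],
                bound = st[, (4 * N + 1):(5 * N), drop = FALSE],
                cyto = st[, 1:N] + st[, (N + 1):(2 * N)] +
                  st[, (2 * N + 1):(3 * N)] + st[, (3 * N + 1):(4 * N)],
                x = x_centres, config = config,
                engine = "pde",
                focus_trajectory = if (tracking) st[, 5 * N + 1] else
                  rep(config$focus_pos[1], length(times)),
                exhausted = FALSE)
  }
  class(kym) <- "para_kymograph"
  kym
}

#' @export
print.para_kymograph <- function(x, ...) {
  cat(sprintf(
    "ParA2 kymograph (%s): %d frames x %d sites, span %.4g s, L = %.3g um\n",
    x$engine, length(x$time), ncol(x$bound), max(x$time), x$config$L))
  invisible(x)
}

#' Total ParA2 (all states, all sites) per kymograph frame
#' @param kymo a \code{para_kymograph}.
#' @return numeric vector, one total per frame.
#' @export
kymograph_total <- function(kymo) {
  rowSums(kymo$bound) + rowSums(kymo$cyto)
}

#' Left-right bound-mass difference signal of a kymograph
#' @param kymo a \code{para_kymograph}.
#' @return numeric vector (left-half minus right-half bound mass per frame).
#' @keywords internal
lr_signal <- function(kymo) {
  N <- ncol(kymo$bound)
  half <- N %/% 2
  left <- rowSums(kymo$bound[, 1:half, drop = FALSE])
  right <- rowSums(kymo$bound[, (N - half + 1):N, drop = FALSE])
  left - right
}

#' Oscillation period of a kymograph
#'
#' Estimates the pole-to-pole oscillation period from the autocorrelation of
#' the left-half minus right-half bound-mass signal: the lag of the first
#' positive-lag autocorrelation peak. Significance is assessed against the
#' 95th percentile of the peak autocorrelation of time-shuffled surrogates;
#' a kymograph whose peak does not exceed that band is flagged
#' non-oscillatory.
#'
#' @param kymo a \code{para_kymograph}.
#' @param n_surrogates surrogates for the noise band (default 100).
#' @param min_periods minimum number of putative periods the span must cover
#'   (default 3).
#' @return list with \code{period_s} (NA when non-oscillatory),
#'   \code{oscillatory} (logical), \code{peak_acf} and \code{threshold}.
#' @export
measure_period <- function(kymo, n_surrogates = 100, min_periods = 3) {
  s <- lr_signal(kymo)
  s <- s - mean(s)
  if (length(s) < 16 || stats::sd(s) == 0) {
    stop("kymograph span too short or signal degenerate")
  }
  dt <- diff(kymo$time[1:2])
  max_lag <- floor(length(s) / 2)
  ac <- stats::acf(s, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  # first local maximum after the initial decay
  pk <- NA_integer_
  for (i in 2:(length(ac) - 1)) {
    if (ac[i] > ac[i - 1] && ac[i] >= ac[i + 1] && ac[i] > 0) {
      pk <- i
      break
    }
  }
  set.seed(20230504L)
  thr <- stats::quantile(vapply(seq_len(n_surrogates), function(j) {
    ss <- sample(s)
    acs <- stats::acf(ss, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf[-1]
    max(acs)
  }, numeric(1)), 0.95)
  if (is.na(pk) || ac[pk] <= thr) {
    return(list(period_s = NA_real_, oscillatory = FALSE,
                peak_acf = if (is.na(pk)) NA_real_ else ac[pk],
                threshold = unname(thr)))
  }
  period <- pk * dt
  if (max(kymo$time) < min_periods * period) {
    stop(sprintf(
      "span %.4g s covers fewer than %d putative periods of %.4g s",
      max(kymo$time), min_periods, period))
  }
  list(period_s = period, oscillatory = TRUE, peak_acf = ac[pk],
       threshold = unname(thr))
}

#' Pole-to-pole transit time of the bound-mass centroid
#'
#' Mean time for the bound-density centroid to cross from the 25 percent to
#' the 75 percent cell-length position (or back) within one half-cycle of an
#' oscillatory kymograph.
#'
#' @param kymo a \code{para_kymograph}.
#' @return list with \code{transit_s} (mean, NA when non-oscillatory or no
#'   complete crossing), \code{n_crossings}, and \code{oscillatory}.
#' @export
measure_transit <- function(kymo) {
  per <- measure_period(kymo)
  if (!per$oscillatory) {
    return(list(transit_s = NA_real_, n_crossings = 0L, oscillatory = FALSE))
  }
  tot <- rowSums(kymo$bound)
  cen <- as.vector(kymo$bound %*% kymo$x) / pmax(tot, 1e-12)
  cen[tot <= 0] <- NA
  L <- kymo$config$L
  lo <- 0.25 * L
  hi <- 0.75 * L
  tt <- kymo$time
  transits <- numeric(0)
  state <- NA_character_  # side last exited: "lo" or "hi"
  t_enter <- NA_real_
  for (i in seq_along(cen)) {
    c_i <- cen[i]
    if (is.na(c_i)) next
    if (c_i <= lo) {
      if (identical(state, "hi") && !is.na(t_enter)) {
        transits <- c(transits, tt[i] - t_enter)
      }
      state <- "lo"
      t_enter <- tt[i]
    } else if (c_i >= hi) {
      if (identical(state, "lo") && !is.na(t_enter)) {
        transits <- c(transits, tt[i] - t_enter)
      }
      state <- "hi"
      t_enter <- tt[i]
    }
  }
  if (!length(transits)) {
    return(list(transit_s = NA_real_, n_crossings = 0L, oscillatory = TRUE))
  }
  list(transit_s = mean(transits), n_crossings = length(transits),
       oscillatory = TRUE)
}

#' Left-right asymmetry index of the bound ParA2 distribution
#'
#' (left-half bound mass - right-half bound mass) / total bound mass at the
#' frame closest to time t; +1 means all mass in the left half, 0 a uniform
#' profile.
#'
#' @param kymo a \code{para_kymograph}.
#' @param t time (s) within the simulated span.
#' @return a single value in [-1, 1], or NA (flagged with attribute
#'   \code{undefined}) when no protein is bound at that frame.
#' @export
asymmetry_index <- function(kymo, t) {
  if (t < min(kymo$time) || t > max(kymo$time)) {
    stop("t outside the simulated span")
  }
  i <- which.min(abs(kymo$time - t))
  row <- kymo$bound[i, ]
  tot <- sum(row)
  if (tot <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  N <- length(row)
  half <- N %/% 2
  (sum(row[1:half]) - sum(row[(N - half + 1):N])) / tot
}

#' Write a kymograph as CSV plus JSON metadata
#' @param kymo a \code{para_kymograph}.
#' @param path CSV path (first column time_s, then one column per site).
#' @return \code{path}, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  df <- data.frame(time_s = kymo$time, kymo$bound)
  names(df)[-1] <- sprintf("x_%0.3fum", kymo$x)
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- kymo$config
  cfg$rates <- unclass(cfg$rates)
  jsonlite::write_json(list(engine = kymo$engine, config = unclass(cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
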