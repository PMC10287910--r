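#' Fit result container
#' @keywords internal
para_fit <- function(model, estimates, se = NULL, rss = NA_real_,
                     converged = TRUE, flags = character(),
                     window = c(NA_real_, NA_real_), n = NA_integer_,
                     aicc = NA_real_) {
  structure(list(model = model, estimates = estimates,
                 se = se %||% stats::setNames(rep(NA_real_,
                                                  length(estimates)),
                                              names(estimates)),
                 rss = rss, converged = converged, flags = flags,
                 window = window, n = n, aicc = aicc),
            class = "para_fit")
}

#' @export
print.para_fit <- function(x, ...) {
  cat(sprintf("para_fit [%s]%s\n", x$model,
              if (!x$converged) " (NOT converged)" else ""))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-14s %.6g%s\n", nm, x$estimates[[nm]],
                if (is.finite(x$se[[nm]])) sprintf(" +/- %.3g", x$se[[nm]])
                else ""))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.6g, n = %d\n", x$rss, x$n))
  invisible(x)
}

#' Coefficients of a fit result
#' @param object a \code{para_fit}.
#' @param ... unused.
#' @export
coef.para_fit <- function(object, ...) object$estimates

aicc_from_rss <- function(rss, n, k) {
  # least-squares AICc (k parameters + 1 for the noise variance)
  kk <- k + 1
  n * log(max(rss, 1e-300) / n) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1)
}

noise_sd_hat <- function(y) stats::sd(diff(y)) / sqrt(2)

trace_xy <- function(trace) {
  if (inherits(trace, "para_trace")) {
    data.frame(x = trace$x, y = trace$y)
  } else {
    df <- as.data.frame(trace)
    stats::setNames(df[, 1:2], c("x", "y"))
  }
}

# multi-start nlsLM wrapper: returns best fit by SSE or NULL
nls_multistart <- function(formula, data, starts, lower = NULL, upper = NULL) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15 * (1 + best$rss)) {
      best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Detect the initial lag window of a rising trace
#'
#' The fit start is the first time at which the smoothed derivative exceeds
#' 20 percent of its maximum; used when a nucleotide-binding lag precedes the
#' conformational-switch rise.
#' @param x,y trace data.
#' @return index of the first point after the lag.
#' @keywords internal
detect_lag <- function(x, y) {
  d <- diff(y) / diff(x)
  w <- max(3L, round(length(d) / 50))
  sm <- stats::filter(d, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- 0
  thr <- 0.2 * max(abs(sm))
  i <- which(abs(sm) >= thr)[1]
  if (is.na(i)) 1L else i
}

#' Fit a single-exponential rise or decay
#'
#' The stopped-flow workhorse: least-squares fit of
#' \code{y = y0 + A (1 - exp(-kobs t))} (rise) or
#' \code{y = y0 + A exp(-kobs t)} (decay). With \code{exclude_lag} the
#' initial lag phase is detected from the smoothed derivative (first crossing
#' of 20 percent of its maximum) and excluded; the fitted window is reported.
#' A trace whose amplitude is indistinguishable from zero (|A| < 3 sigma-hat,
#' sigma-hat from first differences) returns a non-converged result flagged
#' \code{"flat trace"}.
#'
#' @param trace a \code{para_trace} (or two-column data.frame).
#' @param direction "rise" or "decay".
#' @param exclude_lag logical.
#' @return a \code{para_fit} with estimates \code{kobs}, \code{amplitude},
#'   \code{y0}.
#' @export
fit_single_exponential <- function(trace, direction = c("rise", "decay"),
                                   exclude_lag = FALSE) {
  direction <- match.arg(direction)
  d <- trace_xy(trace)
  if (nrow(d) < 20) stop("need at least 20 points")
  i0 <- if (exclude_lag) detect_lag(d$x, d$y) else 1L
  window <- c(d$x[i0], d$x[nrow(d)])
  d <- d[i0:nrow(d), ]
  t0 <- d$x[1]
  d$tt <- d$x - t0
  sig <- noise_sd_hat(d$y)
  rng <- diff(range(d$y))
  if (rng <= max(3 * sig, 1e-12 * max(abs(d$y), 1))) {
    return(para_fit("single_exponential",
                    c(kobs = NA_real_, amplitude = 0, y0 = mean(d$y)),
                    converged = FALSE, flags = "flat trace",
                    window = window, n = nrow(d)))
  }
  span <- max(d$tt)
  kgrid <- exp(seq(log(0.2 / span), log(50 / span), length.out = 5))
  if (direction == "rise") {
    form <- y ~ y0 + A * (1 - exp(-k * tt))
    starts <- lapply(kgrid, function(k) list(y0 = d$y[1], A = rng, k = k))
  } else {
    form <- y ~ y0 + A * exp(-k * tt)
    starts <- lapply(kgrid, function(k) {
      list(y0 = d$y[nrow(d)], A = d$y[1] - d$y[nrow(d)], k = k)
    })
  }
  best <- nls_multistart(form, d, starts,
                         lower = c(-Inf, -Inf, 1e-8 / span),
                         upper = c(Inf, Inf, Inf))
  if (is.null(best)) {
    return(para_fit("single_exponential",
                    c(kobs = NA_real_, amplitude = NA_real_, y0 = NA_real_),
                    converged = FALSE, flags = "fit failed",
                    window = window, n = nrow(d)))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, 2],
                 error = function(e) NULL)
  if (abs(cf[["A"]]) < 3 * sig) {
    return(para_fit("single_exponential",
                    c(kobs = cf[["k"]], amplitude = cf[["A"]],
                      y0 = cf[["y0"]]),
                    rss = best$rss, converged = FALSE,
                    flags = "flat trace", window = window, n = nrow(d)))
  }
  para_fit("single_exponential",
           c(kobs = cf[["k"]], amplitude = cf[["A"]], y0 = cf[["y0"]]),
           se = c(kobs = unname(se["k"]), amplitude = unname(se["A"]),
                  y0 = unname(se["y0"])),
           rss = best$rss, converged = TRUE, window = window, n = nrow(d),
           aicc = aicc_from_rss(best$rss, nrow(d), 3))
}

#' Fit a two-phase (double-exponential) decay
#'
#' \code{y = y0 + A1 exp(-k_fast t) + A2 exp(-k_slow t)} with non-negative
#' amplitudes and \code{k_fast > k_slow}. Model selection against the
#' single-exponential decay uses AICc with a threshold of 2: when the single
#' phase is preferred the single-phase result is returned flagged
#' \code{"collapsed"}.
#'
#' @param trace a \code{para_trace} or two-column data.frame (decaying).
#' @return a \code{para_fit} with estimates \code{k_fast}, \code{k_slow},
#'   \code{amplitude_fast}, \code{amplitude_slow}, \code{y0}.
#' @export
fit_two_phase_decay <- function(trace) {
  d <- trace_xy(trace)
  if (nrow(d) < 40) stop("need at least 40 points")
  d$tt <- d$x - d$x[1]
  span <- max(d$tt)
  rng <- d$y[1] - d$y[nrow(d)]
  single <- fit_single_exponential(d[, c("x", "y")], direction = "decay")
  kg <- exp(seq(log(0.5 / span), log(100 / span), length.out = 4))
  starts <- list()
  for (kf in kg) for (ks in kg) {
    if (kf > ks * 3) {
      starts[[length(starts) + 1]] <-
        list(y0 = d$y[nrow(d)], A1 = rng / 2, A2 = rng / 2, kf = kf, ks = ks)
    }
  }
  if (!is.na(single$estimates[["kobs"]]) && single$converged) {
    k1 <- single$estimates[["kobs"]]
    starts[[length(starts) + 1]] <-
      list(y0 = single$estimates[["y0"]], A1 = rng * 0.7, A2 = rng * 0.3,
           kf = k1 * 5, ks = k1 / 2)
  }
  best <- nls_multistart(y ~ y0 + A1 * exp(-kf * tt) + A2 * exp(-ks * tt),
                         d, starts,
                         lower = c(-Inf, 0, 0, 1e-8 / span, 1e-9 / span),
                         upper = c(Inf, Inf, Inf, Inf, Inf))
  if (is.null(best)) {
    if (single$converged) {
      out <- single
      out$flags <- c(out$flags, "collapsed")
      return(out)
    }
    return(para_fit("two_phase_decay",
                    c(k_fast = NA_real_, k_slow = NA_real_),
                    converged = FALSE, flags = "fit failed", n = nrow(d)))
  }
  cf <- stats::coef(best$fit)
  if (cf[["kf"]] < cf[["ks"]]) {  # enforce k_fast > k_slow by swap
    cf[c("kf", "ks")] <- cf[c("ks", "kf")]
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
  }
  aicc2 <- aicc_from_rss(best$rss, nrow(d), 5)
  if (single$converged && is.finite(single$aicc) &&
      single$aicc < aicc2 + 2) {
    out <- single
    out$flags <- c(out$flags, "collapsed")
    return(out)
  }
  para_fit("two_phase_decay",
           c(k_fast = cf[["kf"]], k_slow = cf[["ks"]],
             amplitude_fast = cf[["A1"]], amplitude_slow = cf[["A2"]],
             y0 = cf[["y0"]]),
           rss = best$rss, converged = TRUE, n = nrow(d), aicc = aicc2)
}

#' Pseudo-first-order analysis of observed rates
#'
#' Ordinary least-squares line through (substrate concentration, kobs):
#' \code{kon} is the slope, \code{koff} the y-intercept, and
#' \code{KD = koff/kon} with standard error propagated from the fit. A
#' negative fitted intercept is reported as \code{koff = 0} with a flag
#' (\code{KD} undefined).
#'
#' @param kobs_points a data.frame/matrix with columns (conc_uM, kobs) or a
#'   list of such pairs.
#' @return a \code{para_fit} with estimates \code{kon} (per-uM per-s),
#'   \code{koff} (per-s), \code{kd_uM}, and \code{r_squared}.
#' @export
pseudo_first_order <- function(kobs_points) {
  d <- as.data.frame(kobs_points)
  names(d)[1:2] <- c("conc", "kobs")
  if (nrow(d) < 2) stop("need at least 2 (concentration, kobs) points")
  fit <- stats::lm(kobs ~ conc, data = d)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  se <- if (nrow(d) > 2) sm$coefficients[, 2] else c(0, 0)
  kon <- cf[["conc"]]; koff <- cf[["(Intercept)"]]
  flags <- character()
  if (koff < 0) {
    flags <- "negative intercept: koff set to 0, KD undefined"
    koff <- 0
    kd <- NA_real_; kd_se <- NA_real_
  } else {
    kd <- koff / kon
    kd_se <- if (kon > 0 && koff > 0) {
      kd * sqrt((se[[1]] / koff)^2 + (se[[2]] / kon)^2)
    } else NA_real_
  }
  para_fit("pseudo_first_order",
           c(kon = kon, koff = koff, kd_uM = kd,
             r_squared = sm$r.squared),
           se = c(kon = unname(se[2]), koff = unname(se[1]), kd_uM = kd_se,
                  r_squared = NA_real_),
           rss = sum(stats::residuals(fit)^2), converged = TRUE,
           flags = flags, n = nrow(d))
}

#' Fit a Hill binding isotherm to a titration
#'
#' \code{f = plateau c^n / (KD^n + c^n)}. The Hill coefficient is only
#' identifiable when the titration reaches at least 80 percent of the
#' plateau; otherwise n is fixed to 1 and flagged. A plateau that the fit
#' cannot pin down (fitted plateau far above the data) is fixed to the
#' maximum observed fraction and flagged.
#'
#' @param titration a \code{para_trace} (x = concentration, y = fraction
#'   bound) with at least 6 concentrations.
#' @return a \code{para_fit} with estimates \code{kd}, \code{n},
#'   \code{plateau} (kd in the x units of the trace, nM for EMSA titrations).
#' @export
fit_hill <- function(titration) {
  d <- trace_xy(titration)
  if (nrow(d) < 6) stop("need at least 6 concentrations")
  flags <- character()
  ymax <- max(d$y)
  kd0 <- stats::approx(d$y, d$x, xout = ymax / 2, ties = "ordered")$y
  if (is.na(kd0)) kd0 <- stats::median(d$x)
  starts <- list()
  for (n0 in c(1, 2, 4, 6)) {
    starts[[length(starts) + 1]] <- list(plateau = ymax, kd = kd0, n = n0)
  }
  best <- nls_multistart(y ~ plateau * x^n / (kd^n + x^n), d, starts,
                         lower = c(1e-6, min(d$x) / 100, 1),
                         upper = c(1.5, max(d$x) * 100, 12))
  if (is.null(best)) {
    return(para_fit("hill", c(kd = NA_real_, n = NA_real_,
                              plateau = NA_real_),
                    converged = FALSE, flags = "fit failed", n = nrow(d)))
  }
  cf <- stats::coef(best$fit)
  if (ymax < 0.8 * cf[["plateau"]]) {
    flags <- c(flags, "n fixed to 1: titration below 80% of plateau")
    best <- nls_multistart(y ~ plateau * x / (kd + x), d,
                           list(list(plateau = ymax, kd = kd0)),
                           lower = c(1e-6, min(d$x) / 100),
                           upper = c(1.5, max(d$x) * 100))
    cf <- c(stats::coef(best$fit), n = 1)
  }
  if (cf[["plateau"]] > 1.05) {
    flags <- c(flags, "plateau fixed to max observed fraction")
    plat <- ymax
    best <- nls_multistart(y ~ plat * x^n / (kd^n + x^n),
                           cbind(d, plat = plat),
                           list(list(kd = kd0, n = max(cf[["n"]], 1))),
                           lower = c(min(d$x) / 100, 1),
                           upper = c(max(d$x) * 100, 12))
    cf <- c(stats::coef(best$fit), plateau = plat)
  }
  se <- tryCatch(summary(best$fit)$coefficients[, 2], error = function(e) NULL)
  para_fit("hill", c(kd = cf[["kd"]], n = cf[["n"]],
                     plateau = cf[["plateau"]]),
           se = c(kd = unname(se["kd"]) %||% NA_real_,
                  n = unname(se["n"]) %||% NA_real_,
                  plateau = unname(se["plateau"]) %||% NA_real_),
           rss = best$rss, converged = TRUE, flags = flags, n = nrow(d))
}

#' Fit a hyperbolic (non-cooperative) binding isotherm
#'
#' \code{y = ymax c / (KD + c)}; the steady-state MANT-nucleotide affinity
#' fit. Equivalent to [fit_hill()] with n fixed to 1. When the titration is
#' entirely saturated the KD is flagged unidentifiable.
#'
#' @param titration a \code{para_trace} with at least 5 concentrations.
#' @return a \code{para_fit} with estimates \code{kd}, \code{ymax}.
#' @export
fit_hyperbolic_kd <- function(titration) {
  d <- trace_xy(titration)
  if (nrow(d) < 5) stop("need at least 5 concentrations")
  flags <- character()
  ymax0 <- max(d$y)
  kd0 <- stats::approx(d$y, d$x, xout = ymax0 / 2, ties = "ordered")$y
  if (is.na(kd0)) kd0 <- stats::median(d$x)
  best <- nls_multistart(y ~ ymax * x / (kd + x), d,
                         lapply(c(0.3, 1, 3), function(f) {
                           list(ymax = ymax0, kd = kd0 * f)
                         }),
                         lower = c(1e-9, min(d$x) / 1e3),
                         upper = c(Inf, max(d$x) * 1e3))
  if (is.null(best)) {
    return(para_fit("hyperbolic", c(kd = NA_real_, ymax = NA_real_),
                    converged = FALSE, flags = "fit failed", n = nrow(d)))
  }
  cf <- stats::coef(best$fit)
  if (min(d$y) > 0.9 * max(d$y)) {
    flags <- "KD unidentifiable: titration saturated"
  }
  se <- tryCatch(summary(best$fit)$coefficients[, 2], error = function(e) NULL)
  para_fit("hyperbolic", c(kd = cf[["kd"]], ymax = cf[["ymax"]]),
           se = c(kd = unname(se["kd"]) %||% NA_real_,
                  ymax = unname(se["ymax"]) %||% NA_real_),
           rss = best$rss, converged = length(flags) == 0, flags = flags,
           n = nrow(d))
}

#' Fit a double-exponential FRAP recovery
#'
#' \code{y = (1 - immobile) - f_fast exp(-t/tau_fast) -
#' f_slow exp(-t/tau_slow)}. Returns the two time constants, the mobile
#' fractions and the immobile fraction (one minus the asymptote). A flat
#' curve (no recovery) reports immobile near 1 with the time constants
#' flagged unidentifiable.
#'
#' @param curve a \code{para_trace} starting near zero.
#' @return a \code{para_fit} with estimates \code{tau_fast}, \code{tau_slow},
#'   \code{fraction_fast}, \code{fraction_slow}, \code{immobile}.
#' @export
fit_frap <- function(curve) {
  d <- trace_xy(curve)
  sig <- noise_sd_hat(d$y)
  if (diff(range(d$y)) <= max(3 * sig, 1e-12)) {
    return(para_fit("frap_double_exponential",
                    c(tau_fast = NA_real_, tau_slow = NA_real_,
                      fraction_fast = 0, fraction_slow = 0,
                      immobile = 1 - mean(d$y)),
                    converged = FALSE,
                    flags = "no recovery: time constants unidentifiable",
                    n = nrow(d)))
  }
  span <- max(d$x)
  kg <- exp(seq(log(1 / span), log(200 / span), length.out = 4))
  starts <- list()
  for (kf in kg) for (ks in kg) {
    if (kf > ks * 3) {
      starts[[length(starts) + 1]] <-
        list(asym = max(d$y), A1 = 0.5, A2 = 0.3, kf = kf, ks = ks)
    }
  }
  d$tt <- d$x
  best <- nls_multistart(y ~ asym - A1 * exp(-kf * tt) - A2 * exp(-ks * tt),
                         d, starts,
                         lower = c(0, 0, 0, 1e-9, 1e-10),
                         upper = c(Inf, Inf, Inf, Inf, Inf))
  if (is.null(best)) {
    return(para_fit("frap_double_exponential",
                    c(tau_fast = NA_real_, tau_slow = NA_real_),
                    converged = FALSE, flags = "fit failed", n = nrow(d)))
  }
  cf <- stats::coef(best$fit)
  if (cf[["kf"]] < cf[["ks"]]) {
    cf[c("kf", "ks")] <- cf[c("ks", "kf")]
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
  }
  para_fit("frap_double_exponential",
           c(tau_fast = 1 / cf[["kf"]], tau_slow = 1 / cf[["ks"]],
             fraction_fast = cf[["A1"]], fraction_slow = cf[["A2"]],
             immobile = 1 - cf[["asym"]]),
           rss = best$rss, converged = TRUE, n = nrow(d),
           aicc = aicc_from_rss(best$rss, nrow(d), 5))
}

#' Fit a two-state Boltzmann thermal melt
#'
#' \code{theta(T) = theta_f + (theta_u - theta_f) /
#' (1 + exp((Tm - T)/slope))}; returns the melting midpoint and transition
#' slope. A flat trace is flagged unidentifiable.
#'
#' @param curve a \code{para_trace} (x = temperature degC, y = ellipticity).
#' @return a \code{para_fit} with estimates \code{tm}, \code{slope},
#'   \code{theta_folded}, \code{theta_unfolded}.
#' @export
fit_melt <- function(curve) {
  d <- trace_xy(curve)
  sig <- noise_sd_hat(d$y)
  if (diff(range(d$y)) <= max(3 * sig, 1e-12)) {
    return(para_fit("boltzmann_melt",
                    c(tm = NA_real_, slope = NA_real_),
                    converged = FALSE, flags = "flat melt: Tm unidentifiable",
                    n = nrow(d)))
  }
  mid <- (max(d$y) + min(d$y)) / 2
  tm0 <- stats::approx(d$y, d$x, xout = mid, ties = "ordered")$y
  if (is.na(tm0)) tm0 <- stats::median(d$x)
  best <- nls_multistart(
    y ~ tf + (tu - tf) / (1 + exp((tm - x) / sl)), d,
    lapply(c(1, 2, 4), function(s) {
      list(tf = d$y[1], tu = d$y[nrow(d)], tm = tm0, sl = s)
    }),
    lower = c(-Inf, -Inf, min(d$x) - 20, 0.05),
    upper = c(Inf, Inf, max(d$x) + 20, 30))
  if (is.null(best)) {
    return(para_fit("boltzmann_melt", c(tm = NA_real_, slope = NA_real_),
                    converged = FALSE, flags = "fit failed", n = nrow(d)))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, 2], error = function(e) NULL)
  para_fit("boltzmann_melt",
           c(tm = cf[["tm"]], slope = cf[["sl"]],
             theta_folded = cf[["tf"]], theta_unfolded = cf[["tu"]]),
           se = c(tm = unname(se["tm"]) %||% NA_real_,
                  slope = unname(se["sl"]) %||% NA_real_,
                  theta_folded = NA_real_, theta_unfolded = NA_real_),
           rss = best$rss, converged = TRUE, n = nrow(d))
}
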