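#' Linear observable map over model species
#'
#' An observable is a linear functional of the species state:
#' \code{signal(t) = baseline + sum(coeff_s * concentration_s(t))}. The
#' tryptophan conformational-switch signal, for example, weights the active
#' D*-ATP state at +5 percent and the DNA-bound state at +13 percent of the
#' baseline per fully converted population.
#'
#' @param coefficients named numeric vector of per-species signal
#'   coefficients (signal units per uM); every species present in a
#'   trajectory must be named here, explicitly zero if silent.
#' @param baseline additive offset.
#' @return an object of class \code{para_observable}.
#' @export
observable_map <- function(coefficients, baseline = 0) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    stop("coefficients must be a fully named vector")
  }
  if (any(!is.finite(coefficients)) || !is.finite(baseline)) {
    stop("coefficients and baseline must be finite")
  }
  structure(list(coefficients = coefficients, baseline = baseline),
            class = "para_observable")
}

#' Project a trajectory onto an observable
#'
#' @param traj a \code{para_trajectory}.
#' @param map a \code{para_observable}. The map must cover every species that
#'   appears in the trajectory; silently treating a missing species as zero
#'   is not allowed and raises an error.
#' @return a \code{para_trace} with x = time (s) and y = projected signal.
#' @export
project_observable <- function(traj, map) {
  stopifnot(inherits(traj, "para_trajectory"), inherits(map, "para_observable"))
  present <- colnames(traj$state)[apply(traj$state, 2, function(c) any(c != 0))]
  missing <- setdiff(present, names(map$coefficients))
  if (length(missing)) {
    stop("observable map does not cover species present in trajectory: ",
         paste(missing, collapse = ", "))
  }
  co <- map$coefficients[intersect(names(map$coefficients), colnames(traj$state))]
  y <- map$baseline + as.vector(traj$state[, names(co), drop = FALSE] %*% co)
  para_trace(x = traj$time, y = y, assay = "observable",
             condition = traj$scheme$condition, sigma = 0,
             seed = traj$seed, x_unit = "s", y_unit = "signal_au")
}

#' Observable map covering all species with a few nonzero weights
#'
#' Convenience wrapper: zero coefficient for every model species, overridden
#' by the named values supplied.
#' @param ... named coefficients, e.g. \code{DS = 0.05, B = 0.13}.
#' @param baseline additive offset.
#' @return a \code{para_observable}.
#' @export
observable_over_species <- function(..., baseline = 0) {
  co <- stats::setNames(numeric(length(PARA_SPECIES)), PARA_SPECIES)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), PARA_SPECIES)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    co[names(ov)] <- ov
  }
  observable_map(co, baseline = baseline)
}
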