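#' Synthetic assay trace
#'
#' The common container for one synthetic assay readout: paired (x, y)
#' observations plus metadata (assay kind, condition, noise sigma, seed,
#' generator parameters). x may be time (s), concentration (uM or nM) or
#' temperature (degC) depending on the assay.
#'
#' @param x,y numeric vectors of equal length; x strictly increasing.
#' @param assay character tag, e.g. "mant_binding", "emsa", "frap".
#' @param condition condition descriptor (list or \code{para_condition}).
#' @param sigma Gaussian noise sd used (same units as y).
#' @param seed RNG seed used (NA for deterministic traces).
#' @param params generator parameter list, kept for provenance.
#' @param x_unit,y_unit unit strings encoded into CSV headers.
#' @param flags character vector of generator warnings (e.g. pseudo-first-order
#'   excess assumption violated).
#' @param n_clipped number of y values clipped into a physical range;
#'   clipping is counted, never silent.
#' @return an object of class \code{para_trace}.
#' @export
para_trace <- function(x, y, assay, condition = NULL, sigma = 0,
                       seed = NA_integer_, params = list(),
                       x_unit = "x", y_unit = "y", flags = character(),
                       n_clipped = 0L) {
  stopifnot(length(x) == length(y))
  if (any(diff(x) <= 0)) stop("trace x values must be strictly increasing")
  if (any(!is.finite(y))) stop("trace y values must be finite")
  structure(list(x = x, y = y, assay = assay, condition = condition,
                 sigma = sigma, seed = seed, params = params,
                 x_unit = x_unit, y_unit = y_unit, flags = flags,
                 n_clipped = as.integer(n_clipped)),
            class = "para_trace")
}

#' @export
print.para_trace <- function(x, ...) {
  cat(sprintf("para_trace [%s]: %d points, %s in [%.4g, %.4g]%s%s\n",
              x$assay, length(x$x), x$x_unit, min(x$x), max(x$x),
              if (x$sigma > 0) sprintf(", sigma = %.3g", x$sigma) else "",
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = "; ")) else ""))
  invisible(x)
}

#' @export
as.data.frame.para_trace <- function(x, ...) {
  df <- data.frame(x = x$x, y = x$y)
  names(df) <- c(x$x_unit, x$y_unit)
  df
}

#' Add iid Gaussian noise to a trace and clip fraction-type signals
#'
#' @param tr a \code{para_trace}.
#' @param sigma noise sd in y units; 0 returns the trace unchanged.
#' @param seed integer seed (required when sigma > 0).
#' @param clip optional c(lo, hi); clipped values are counted in
#'   \code{n_clipped}.
#' @return the noisy \code{para_trace}.
#' @keywords internal
add_noise <- function(tr, sigma, seed, clip = NULL) {
  if (sigma > 0) {
    if (is.na(seed)) stop("a seed is required when noise_sigma > 0")
    set.seed(as.integer(seed))
    tr$y <- tr$y + stats::rnorm(length(tr$y), 0, sigma)
    tr$sigma <- sigma
    tr$seed <- as.integer(seed)
  }
  if (!is.null(clip)) {
    n <- sum(tr$y < clip[1] | tr$y > clip[2])
    tr$y <- pmin(pmax(tr$y, clip[1]), clip[2])
    tr$n_clipped <- as.integer(n)
  }
  tr
}

#' Write a trace as CSV with a JSON metadata sidecar
#'
#' The CSV carries a mandatory header with units encoded in the column names
#' (e.g. \code{time_s, signal_au}); the sidecar \code{<path>.json} records
#' assay, condition, seed, sigma, flags, clipping count, generator
#' parameters, and package version, so a run can be reproduced bit-for-bit.
#'
#' @param tr a \code{para_trace}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(tr, path) {
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  meta <- list(assay = tr$assay, condition = tr$condition, sigma = tr$sigma,
               seed = tr$seed, params = tr$params, x_unit = tr$x_unit,
               y_unit = tr$y_unit, flags = tr$flags,
               n_clipped = tr$n_clipped,
               package_version = as.character(utils::packageVersion("para2kin")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#' @param path CSV file path (sidecar \code{<path>.json} must exist).
#' @return a \code{para_trace}.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop(sprintf("malformed trace CSV '%s': need a header row and two columns",
                 path))
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(assay = "unknown", sigma = 0, seed = NA_integer_, params = list(),
         flags = character(), n_clipped = 0L)
  }
  para_trace(x = df[[1]], y = df[[2]], assay = meta$assay,
             condition = meta$condition, sigma = meta$sigma,
             seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
             params = meta$params, x_unit = names(df)[1],
             y_unit = names(df)[2],
             flags = as.character(meta$flags %||% character()),
             n_clipped = meta$n_clipped %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
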