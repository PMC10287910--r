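#' Shipped assay parameter presets
#'
#' Returns the packaged parameter presets for wild-type ParA2 and the
#' Walker-A K124 variants, ready to hand to the matching generator:
#' \code{kind = "emsa"} gives a [hill_params()] (DNA-binding titration),
#' \code{"melt"} a [melt_params()] (CD thermal melt), \code{"frap"} a
#' [frap_params()] (carpet FRAP), and \code{"rates"} a [rate_set()] with the
#' variant's overrides applied.
#'
#' @param kind preset family: "emsa", "melt", "frap", "rates" or "spatial"
#'   (a full [spatial_config()] for the tug-of-war cell).
#' @param name preset name; call with \code{name = NULL} to list the
#'   available names.
#' @return the parameter object, or a character vector of names.
#' @examples
#' gen_emsa(preset("emsa", "wt-atp"))
#' @export
preset <- function(kind = c("emsa", "melt", "frap", "rates", "spatial"),
                   name = NULL) {
  kind <- match.arg(kind)
  all <- yaml::read_yaml(system.file("extdata", "presets.yaml",
                                     package = "para2kin"))[[kind]]
  if (is.null(name)) return(names(all))
  if (!name %in% names(all)) {
    stop("unknown ", kind, " preset '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  }
  p <- all[[name]]
  switch(kind,
         emsa = do.call(hill_params, p),
         melt = do.call(melt_params, p),
         frap = do.call(frap_params, p),
         rates = do.call(rate_set, p),
         spatial = {
           p$rates <- rate_set(coop_omega = p$coop_omega %||% 2)
           p$coop_omega <- NULL
           do.call(spatial_config, p)
         })
}
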