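#' Species tracked by the well-mixed cycle model
#'
#' Dimer states (uM, dimer basis): \code{D} apo dimer, \code{DT} closed
#' ATP-sandwich dimer, \code{DS} remodeled active D*-ATP dimer, \code{B}
#' DNA-bound dimer, \code{DD} post-hydrolysis ADP dimer. The \code{m}-prefixed
#' states carry MANT-labelled nucleotide. Free pools (uM, nucleotide or site
#' basis): \code{ATP}, \code{ADP}, \code{mATP}, \code{mADP}, \code{sites}
#' (30 bp nonspecific DNA sites), \code{ParB} (ParB2, monomer basis; a
#' kinetic spectator that sets the hydrolysis stimulation).
#' @keywords internal
#' @name species
NULL

PARA_SPECIES <- c("D", "DT", "DS", "B", "DD",
                  "mDT", "mDS", "mB", "mDD",
                  "ATP", "ADP", "mATP", "mADP", "sites", "ParB")

DIMER_SPECIES <- c("D", "DT", "DS", "B", "DD", "mDT", "mDS", "mB", "mDD")

#' Initial species state for the well-mixed model
#'
#' Builds a full named concentration vector (uM) with zeros for unnamed
#' species. Protein concentrations are supplied on the dimer basis here; use
#' \code{monomer_uM/2} to convert printed monomer concentrations.
#'
#' @param ... named concentrations, e.g. \code{D = 1.25, mATP = 25}.
#' @return named numeric vector over all model species.
#' @export
species_state <- function(...) {
  vals <- c(...)
  x <- stats::setNames(numeric(length(PARA_SPECIES)), PARA_SPECIES)
  if (length(vals)) {
    bad <- setdiff(names(vals), PARA_SPECIES)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    if (any(vals < 0)) stop("species concentrations must be >= 0")
    x[names(vals)] <- vals
  }
  x
}

#' Assay condition descriptor
#'
#' Names which cofactors and nucleotide species are present in a well-mixed
#' assay. \code{nucleotide} selects the chemistry of the free nucleotide pool:
#' \code{"ATP"} supports the full cycle; \code{"ATPgS"} supports binding,
#' remodeling (DNA-induced only) and DNA loading but removes the hydrolysis
#' branch; \code{"ADP"} supports only ADP binding; \code{"none"} leaves the
#' apo dimer inert. Without Mg2+ no remodeling occurs.
#'
#' @param nucleotide one of "ATP", "ADP", "ATPgS", "none".
#' @param dna logical, nonspecific DNA present.
#' @param parb logical, ParB2 present.
#' @param mg logical, Mg2+ present (remodeling requires ATP + Mg2+).
#' @return an object of class \code{para_condition}.
#' @export
assay_condition <- function(nucleotide = "ATP", dna = FALSE, parb = FALSE,
                            mg = TRUE) {
  nucleotide <- match.arg(nucleotide, c("ATP", "ADP", "ATPgS", "none"))
  structure(list(nucleotide = nucleotide, dna = isTRUE(dna),
                 parb = isTRUE(parb), mg = isTRUE(mg)),
            class = "para_condition")
}

reaction <- function(name, rate, order, stoich, modifier = NULL) {
  list(name = name, rate = rate, order = order, stoich = stoich,
       modifier = modifier)
}

#' Assemble the mass-action reaction scheme for a condition
#'
#' Realizes the ParA2 cycle as a list of elementary mass-action reactions for
#' the given assay condition. The condition selects which branches exist
#' (no remodeling without ATP + Mg2+; no hydrolysis with ATPgS; DNA loading
#' only when DNA is present) and sets the effective hydrolysis rate to the
#' basal constant times \code{stim_factor(condition)} (the fold-stimulation
#' by DNA, ParB2 or both). With DNA present the remodeling rate is multiplied
#' by \code{k2_dna_factor}. Cooperative DNA loading enters as a mean-field
#' modifier multiplying \code{k3} by \code{1 + (coop_omega - 1) * f} where
#' \code{f} is the current bound-site fraction.
#'
#' Nucleotide stoichiometry: a dimer loads or releases its two nucleotides in
#' a single kinetic step (first order in the free nucleotide, stoichiometric
#' coefficient two), so free nucleotide pools are in nucleotide units while
#' protein states are in dimer units.
#'
#' @param rates a \code{para_rates} object.
#' @param condition a \code{para_condition} from [assay_condition()].
#' @return an object of class \code{para_scheme}: list of reactions plus the
#'   generating rates and condition.
#' @export
assemble_scheme <- function(rates, condition = assay_condition()) {
  validate_rate_set(rates)
  if (!inherits(condition, "para_condition")) {
    stop("condition must be built with assay_condition()")
  }
  stim <- stim_factor(rates, condition$dna, condition$parb)
  rx <- list()
  add <- function(...) rx[[length(rx) + 1L]] <<- reaction(...)

  atp_like <- condition$nucleotide %in% c("ATP", "ATPgS")
  hydrolyzable <- condition$nucleotide == "ATP"
  remodel_rate <- if (!atp_like || !condition$mg) {
    0
  } else if (condition$nucleotide == "ATPgS") {
    # ATPgS does not drive remodeling on its own; DNA induces it
    if (condition$dna) rates$k2 else 0
  } else {
    rates$k2 * if (condition$dna) rates$k2_dna_factor else 1
  }

  if (atp_like) {
    for (lab in c("", "m")) {
      nt <- paste0(lab, "ATP"); dt <- paste0(lab, "DT")
      ds <- paste0(lab, "DS"); b <- paste0(lab, "B"); dd <- paste0(lab, "DD")
      add(paste0("bind_", nt), rates$k1,
          c(D = 1, stats::setNames(1, nt)),
          c(D = -1, stats::setNames(-2, nt), stats::setNames(1, dt)))
      add(paste0("release_", nt), rates$k_minus1,
          stats::setNames(1, dt),
          c(stats::setNames(-1, dt), D = 1, stats::setNames(2, nt)))
      if (remodel_rate > 0) {
        add(paste0("remodel_", dt), remodel_rate,
            stats::setNames(1, dt),
            c(stats::setNames(-1, dt), stats::setNames(1, ds)))
      }
      if (condition$dna) {
        add(paste0("load_", ds), rates$k3,
            c(stats::setNames(1, ds), sites = 1),
            c(stats::setNames(-1, ds), sites = -1, stats::setNames(1, b)),
            modifier = coop_modifier(rates$coop_omega))
        add(paste0("unload_", b), rates$k_minus3,
            stats::setNames(1, b),
            c(stats::setNames(-1, b), stats::setNames(1, ds), sites = 1))
        if (hydrolyzable && rates$k_hyd > 0) {
          # bulk-scale hydrolysis-coupled release; the fast carpet/in-vivo
          # release constant k4 belongs to the flow-cell and lattice models
          add(paste0("hydrolyze_release_", b), rates$k_hyd * stim,
              stats::setNames(1, b),
              c(stats::setNames(-1, b), stats::setNames(1, dd), sites = 1))
        }
      }
      if (hydrolyzable && rates$k_hyd > 0) {
        add(paste0("hydrolyze_", ds), rates$k_hyd * stim,
            stats::setNames(1, ds),
            c(stats::setNames(-1, ds), stats::setNames(1, dd)))
      }
    }
  }

  # ADP binding/release exists whenever ADP (labelled or not) can appear:
  # after hydrolysis, or in ADP-condition assays
  if (condition$nucleotide != "none") {
    for (lab in c("", "m")) {
      nd <- paste0(lab, "ADP"); dd <- paste0(lab, "DD")
      add(paste0("bind_", nd), rates$k5,
          c(D = 1, stats::setNames(1, nd)),
          c(D = -1, stats::setNames(-2, nd), stats::setNames(1, dd)))
      add(paste0("release_", nd), rates$k_minus5,
          stats::setNames(1, dd),
          c(stats::setNames(-1, dd), D = 1, stats::setNames(2, nd)))
    }
    # effective nucleotide exchange on loaded dimers (all label pairings)
    for (out_lab in c("", "m")) for (in_lab in c("", "m")) {
      dd_out <- paste0(out_lab, "DD")
      # ADP -> ATP exchange (only meaningful when ATP chemistry is present)
      if (atp_like) {
        nt_in <- paste0(in_lab, "ATP"); dt_in <- paste0(in_lab, "DT")
        add(paste0("exch_", dd_out, "_", nt_in), rates$k6_adp_to_atp,
            c(stats::setNames(1, dd_out), stats::setNames(1, nt_in)),
            sum_stoich(c(stats::setNames(-1, dd_out),
                         stats::setNames(1, dt_in)),
                       stats::setNames(-2, nt_in),
                       stats::setNames(2, paste0(out_lab, "ADP"))))
        dt_out <- paste0(out_lab, "DT")
        add(paste0("exch_", dt_out, "_", nt_in), rates$k6_atp_to_atp,
            c(stats::setNames(1, dt_out), stats::setNames(1, nt_in)),
            sum_stoich(c(stats::setNames(-1, dt_out),
                         stats::setNames(1, dt_in)),
                       stats::setNames(-2, nt_in),
                       stats::setNames(2, paste0(out_lab, "ATP"))))
      }
      nd_in <- paste0(in_lab, "ADP"); dd_in <- paste0(in_lab, "DD")
      add(paste0("exch_", dd_out, "_", nd_in), rates$k6_adp_to_adp,
          c(stats::setNames(1, dd_out), stats::setNames(1, nd_in)),
          sum_stoich(c(stats::setNames(-1, dd_out),
                       stats::setNames(1, dd_in)),
                     stats::setNames(-2, nd_in),
                     stats::setNames(2, paste0(out_lab, "ADP"))))
    }
  }

  # drop null reactions (zero rate or self-cancelling stoichiometry)
  rx <- Filter(function(r) r$rate > 0 && any(r$stoich != 0), rx)
  structure(list(reactions = rx, rates = rates, condition = condition),
            class = "para_scheme")
}

# add stoichiometry vectors with shared names (e.g. same-label exchange,
# where release and uptake of the same pool partially cancel)
sum_stoich <- function(...) {
  v <- c(...)
  agg <- tapply(v, names(v), sum)
  out <- stats::setNames(as.numeric(agg), names(agg))
  out[out != 0]
}

coop_modifier <- function(omega) {
  if (omega == 1) return(NULL)
  force(omega)
  function(state) {
    tot <- state[["B"]] + state[["mB"]] + state[["sites"]]
    if (tot <= 0) return(1)
    f <- (state[["B"]] + state[["mB"]]) / tot
    1 + (omega - 1) * f
  }
}

#' @export
print.para_scheme <- function(x, ...) {
  cat(sprintf("ParA2 reaction scheme: %d reactions (nucleotide %s%s%s%s)\n",
              length(x$reactions), x$condition$nucleotide,
              if (x$condition$dna) " +DNA" else "",
              if (x$condition$parb) " +ParB2" else "",
              if (!x$condition$mg) " -Mg" else ""))
  for (r in x$reactions) {
    cat(sprintf("  %-22s k = %.4g\n", r$name, r$rate))
  }
  invisible(x)
}

#' Look up the rate of a named reaction in a scheme
#' @param scheme a \code{para_scheme}.
#' @param name reaction name, e.g. \code{"hydrolyze_release_B"}.
#' @return the rate constant, or \code{NA} if the reaction is absent.
#' @export
scheme_rate <- function(scheme, name) {
  for (r in scheme$reactions) if (r$name == name) return(r$rate)
  NA_real_
}
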