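# Assay parameter presets for wild-type ParA2 and its Walker-A K124 variants.
# EMSA affinities (kd_nM) are the fitted dissociation constants of binding to
# a 69 bp nonspecific DNA probe under the named nucleotide. The ADP-condition
# Hill coefficient and the ParB2-FRAP fractions are synthetic defaults (not
# printed values); see the methods vignette.
emsa:
  wt-atp:    {kd_nM: 46,    "n": 4, plateau: 1.0}
  wt-atpgs:  {kd_nM: 34,    "n": 4, plateau: 1.0}
  wt-adp:    {kd_nM: 378,   "n": 2, plateau: 1.0}
  wt-apo:    {kd_nM: 1000,  "n": 1, plateau: 1.0}
  k124r:     {kd_nM: 47.1,  "n": 4, plateau: 1.0}
  k124q:     {kd_nM: 137.5, "n": 3, plateau: 1.0}
  k124e:     {kd_nM: 452,   "n": 2, plateau: 1.0}
melt:
  apo:       {tm_C: 44, slope_C: 1.8}
  atp:       {tm_C: 53, slope_C: 1.8}
  adp:       {tm_C: 51, slope_C: 1.8}
  atpgs:     {tm_C: 50, slope_C: 1.8}
  amppnp:    {tm_C: 44, slope_C: 1.8}
  atp-no-mg: {tm_C: 44, slope_C: 1.8}
frap:
  carpet-low-density: {fraction_fast: 0.64, fraction_slow: 0.23,
                       fraction_immobile: 0.13, tau_fast: 2.3, tau_slow: 121}
  carpet-parb-1to2:   {fraction_fast: 0.40, fraction_slow: 0.25,
                       fraction_immobile: 0.35, tau_fast: 8.2, tau_slow: 308}
rates:
  # overrides applied to rate_set() defaults
  wt: {}
  k124r: {kcat: 0, k4: 0, k_hyd: 0}            # binds ATP/DNA, no hydrolysis
  k124q: {kcat: 0.002, stim_dna: 1.3}          # residual ATPase, weak DNA stim
  k124e: {k1: 0, kcat: 0, k4: 0, k_hyd: 0}     # no ATP binding at all
spatial:
  # tug-of-war demonstration cell: parameters located by a coarse scan of the
  # mean-field engine; oscillates pole-to-pole with a period of ~6 min
  tugofwar-demo:
    coop_omega: 100
    L: 2
    "N": 50
    d_cyto: 3
    copies: 600
    focus_pos: 0.5
    focus_width: 0.2
    focus_stim: 40
    focus_mode: tracking
    focus_speed: 0.01
    site_capacity: 40
    nucleoid_sites_uM: 0.3
    t_end: 1800
    dt_record: 2
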