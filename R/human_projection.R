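# Interspecies %kg/g projection: mouse whole-organ uptake fractions scaled by
# the body-weight ratio give human source-organ %ID time courses, which are
# integrated and dosed with a human-phantom S-value table.

#' Species scaling weights for the %kg/g method
#'
#' @param mouse_body_weight_g Mouse body weight in grams (default 30).
#' @param human_body_weight_g Human body weight in grams (default 56,900, an
#'   adult female reference).
#' @return Object of class `species_scaling`.
#' @export
species_scaling <- function(mouse_body_weight_g = 30,
                            human_body_weight_g = 56900) {
  assert_scalar_number(mouse_body_weight_g, "mouse_body_weight_g", positive = TRUE)
  assert_scalar_number(human_body_weight_g, "human_body_weight_g", positive = TRUE)
  structure(list(mouse_body_weight_g = mouse_body_weight_g,
                 human_body_weight_g = human_body_weight_g),
            class = "species_scaling")
}

#' Project a mouse whole-organ uptake fraction to the human
#'
#' The %kg/g method: \eqn{(\%ID/organ)_{human} = (\%ID/organ)_{mouse} \times
#' BW_{mouse} / BW_{human}}. Note the operand is %ID per whole organ
#' (%ID/g times organ mass), not %ID/g.
#'
#' @param pct_id_organ_mouse Mouse %ID/organ, >= 0 (vectorised).
#' @param scaling A [species_scaling()].
#' @return Human %ID/organ.
#' @export
project_pct_id_organ <- function(pct_id_organ_mouse, scaling = species_scaling()) {
  if (any(!is.finite(pct_id_organ_mouse)) || any(pct_id_organ_mouse < 0)) {
    mird_stop("%ID/organ must be non-negative and finite",
              "mirdose_invalid_argument")
  }
  pct_id_organ_mouse * scaling$mouse_body_weight_g / scaling$human_body_weight_g
}

#' Projected human organ and tumour doses from a mouse biodistribution
#'
#' Builds human source-organ %ID time courses by applying
#' [project_pct_id_organ()] to the mouse group-mean whole-organ fractions at
#' each sampling time (time points unchanged), integrates them with the same
#' trapezoid-plus-tail rules as the mouse analysis, and doses them through a
#' human-phantom S-value table. The tumour, when present, is projected like
#' an organ (using its mouse mass for the %ID/organ conversion) and dosed by
#' the sphere self-dose model at the human tumour mass — by default a 2 cm
#' diameter unit-density sphere (4.19 g).
#'
#' Because the projection is a fixed per-organ scale factor, each projected
#' organ's time-integrated activity equals (BW ratio) x the mouse organ TIA
#' on the same time grid.
#'
#' @param measurements Per-animal mouse `biodist` data.
#' @param nuc A [nuclide()].
#' @param human_s_table [svalue_table()] for the human phantom; must cover
#'   every projected source organ.
#' @param organ_masses Named mouse organ masses in grams (tumour included
#'   when a tumour row is present).
#' @param injected_MBq Injected activity in MBq (normalisation basis).
#' @param scaling A [species_scaling()].
#' @param sphere_curve Sphere S-value curve covering the human tumour mass.
#' @param human_tumour_mass_g Human tumour mass (default [sphere_mass_g()] of
#'   a 2 cm sphere, 4.19 g).
#' @param T_h,boundary_rule,decay,w_r As in the mouse dose chain.
#' @return A `dose_report` with columns `target, dose_Sv, dose_Sv_per_MBq,
#'   dose_mSv_per_MBq` (per MBq injected to the human subject basis equal to
#'   the mouse injection; doses are linear in injected activity). The
#'   projected %ID/organ time courses are attached as attribute
#'   `projected_pct_id_organ` for audit.
#' @export
project_human_doses <- function(measurements, nuc, human_s_table, organ_masses,
                                injected_MBq, scaling = species_scaling(),
                                sphere_curve = NULL,
                                human_tumour_mass_g = sphere_mass_g(2),
                                T_h = 48, boundary_rule = "plateau",
                                decay = TRUE, w_r = 1) {
  organs <- unique(measurements$organ)
  ratio <- scaling$mouse_body_weight_g / scaling$human_body_weight_g

  # mouse TIAs on the native time grid; the projection is a per-organ scale
  mouse_tias <- tia_table(measurements, nuc, injected_MBq * 1e6, organ_masses,
                          T_h = T_h, boundary_rule = boundary_rule,
                          decay = decay, organs = organs)
  human_tias <- mouse_tias
  human_tias$auc_Bq_s <- mouse_tias$auc_Bq_s * ratio
  human_tias$tail_Bq_s <- mouse_tias$tail_Bq_s * ratio
  human_tias$total_Bq_s <- mouse_tias$total_Bq_s * ratio

  report <- equivalent_dose(human_tias, human_s_table, w_r = w_r,
                            injected_MBq = injected_MBq,
                            sphere_curve = sphere_curve,
                            tumour_mass_g = if ("tumour" %in% organs)
                              human_tumour_mass_g else NULL)
  report$dose_mSv_per_MBq <- report$dose_Sv_per_MBq * 1000

  # audit trail: projected human %ID/organ per sampling time
  s <- summarize_biodist(measurements)
  s <- s[s$organ %in% organs, ]
  audit <- data.frame(
    organ = s$organ, time_h = s$time_h,
    pct_id_organ_mouse = s$mean * organ_masses[s$organ],
    pct_id_organ_human = project_pct_id_organ(
      s$mean * unname(organ_masses[s$organ]), scaling))
  prov <- attr(report, "provenance")
  prov$scaling <- unclass(scaling)
  prov$human_tumour_mass_g <- if ("tumour" %in% organs) human_tumour_mass_g else NULL
  attr(report, "provenance") <- prov
  attr(report, "projected_pct_id_organ") <- audit
  report
}
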