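# S-value dose kernel: organ-level equivalent doses D = A_s x S x W_R, the
# sphere self-dose model for tumours, and dose-report assembly.

#' Construct an S-value table
#'
#' @param entries data.frame with columns `source, target, S_Gy_per_Bq_s`
#'   (optionally `nuclide, phantom_id`, carried as provenance).
#' @param nuclide_name,phantom_id Provenance labels.
#' @return Object of class `svalue_table`.
#' @export
svalue_table <- function(entries, nuclide_name = NA_character_,
                         phantom_id = NA_character_) {
  need <- c("source", "target", "S_Gy_per_Bq_s")
  if (!all(need %in% names(entries))) {
    mird_stop("S-value entries need columns source, target, S_Gy_per_Bq_s",
              "mirdose_schema_error")
  }
  if (any(entries$S_Gy_per_Bq_s < 0)) {
    mird_stop("S-values must be non-negative", "mirdose_schema_error")
  }
  structure(list(nuclide = nuclide_name, phantom_id = phantom_id,
                 entries = entries[, need]),
            class = "svalue_table")
}

#' @export
print.svalue_table <- function(x, ...) {
  cat(sprintf("<svalue_table> %s / %s: %d source->target entries\n",
              x$nuclide, x$phantom_id, nrow(x$entries)))
  invisible(x)
}

#' Read an S-value table from delimited text
#'
#' Expected header: `nuclide,phantom_id,source,target,S_Gy_per_Bq_s`.
#' @param path File to read.
#' @export
read_svalue_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  svalue_table(tab,
               nuclide_name = if ("nuclide" %in% names(tab)) tab$nuclide[1] else NA,
               phantom_id = if ("phantom_id" %in% names(tab)) tab$phantom_id[1] else NA)
}

s_lookup <- function(s_table, source, target) {
  e <- s_table$entries
  hit <- e$S_Gy_per_Bq_s[e$source == source & e$target == target]
  if (length(hit) == 0) return(NA_real_)
  hit[1]
}

#' Construct a sphere self-dose S-value curve
#'
#' @param mass_g Strictly increasing node masses in grams (>= 2 nodes).
#' @param S_Gy_per_Bq_s Self-dose S at each node, strictly decreasing with
#'   mass.
#' @param nuclide_name Provenance label.
#' @return Object of class `sphere_svalue_curve`.
#' @export
sphere_svalue_curve <- function(mass_g, S_Gy_per_Bq_s,
                                nuclide_name = NA_character_) {
  if (length(mass_g) < 2 || length(mass_g) != length(S_Gy_per_Bq_s)) {
    mird_stop("sphere curve needs >= 2 (mass, S) nodes", "mirdose_schema_error")
  }
  o <- order(mass_g)
  mass_g <- mass_g[o]; S <- S_Gy_per_Bq_s[o]
  if (any(diff(mass_g) <= 0)) {
    mird_stop("sphere node masses must be strictly increasing",
              "mirdose_schema_error")
  }
  if (any(diff(S) >= 0)) {
    mird_stop("sphere S-values must strictly decrease with mass",
              "mirdose_schema_error")
  }
  structure(list(nuclide = nuclide_name, mass_g = mass_g, S_Gy_per_Bq_s = S),
            class = "sphere_svalue_curve")
}

#' Read a sphere S-value curve (`nuclide,mass_g,S_Gy_per_Bq_s`)
#' @param path File to read.
#' @export
read_sphere_curve <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sphere_svalue_curve(tab$mass_g, tab$S_Gy_per_Bq_s,
                      nuclide_name = if ("nuclide" %in% names(tab)) tab$nuclide[1] else NA)
}

#' Sphere self-dose S-value at an arbitrary mass
#'
#' Log-log linear interpolation between the bracketing nodes; exact at nodes.
#' Extrapolation outside the node range is refused unless `clamp = TRUE`, in
#' which case the nearest node value is returned with a warning.
#'
#' @param mass_g Query mass in grams (> 0).
#' @param curve A [sphere_svalue_curve()].
#' @param clamp Permit nearest-node clamping outside the node range.
#' @return S in Gy per Bq.s.
#' @export
sphere_s_value <- function(mass_g, curve, clamp = FALSE) {
  assert_scalar_number(mass_g, "mass_g", positive = TRUE)
  m <- curve$mass_g; S <- curve$S_Gy_per_Bq_s
  if (mass_g < m[1] || mass_g > m[length(m)]) {
    if (!clamp) {
      mird_stop(sprintf("mass %g g outside sphere curve range [%g, %g] g",
                        mass_g, m[1], m[length(m)]),
                "mirdose_range_error")
    }
    mird_warn(sprintf("mass %g g clamped to nearest sphere node", mass_g),
              "mirdose_clamped")
    return(if (mass_g < m[1]) S[1] else S[length(S)])
  }
  exp(stats::approx(log(m), log(S), xout = log(mass_g))$y)
}

#' Mass of a unit-density sphere of given diameter
#' @param diameter_cm Diameter in cm.
#' @return Mass in grams ((4/3) pi r^3 at 1 g/cm^3).
#' @export
sphere_mass_g <- function(diameter_cm) {
  assert_scalar_number(diameter_cm, "diameter_cm", positive = TRUE)
  (4 / 3) * pi * (diameter_cm / 2)^3
}

#' Organ equivalent doses from time-integrated activities and an S-value table
#'
#' For each target region, \eqn{D = \sum_{src} \tilde A(src) \times
#' S(target \leftarrow src) \times W_R}. A self-dose-only table (entries only
#' where source == target) is a first-class degenerate case: cross-organ
#' terms are simply absent. The tumour, when present among the TIAs and a
#' sphere curve plus tumour mass are supplied, is dosed exclusively through
#' the sphere self-dose model.
#'
#' @param tias A `tia_table` (from [tia_table()]), or data.frame with columns
#'   `organ, total_Bq_s`.
#' @param s_table An [svalue_table()].
#' @param w_r Radiation weighting factor (1 for beta/gamma/x-ray).
#' @param injected_MBq Injected activity in MBq, for the Sv/MBq column.
#' @param sphere_curve Optional [sphere_svalue_curve()] for the tumour.
#' @param tumour_mass_g Tumour mass in grams (required when a `tumour` row is
#'   present and `sphere_curve` is given).
#' @param cross_organ Include cross-organ terms from the table (default TRUE;
#'   with a self-dose-only table this is a no-op).
#' @return A `dose_report` data.frame: `target, dose_Sv, dose_Sv_per_MBq`,
#'   with provenance attributes.
#' @export
equivalent_dose <- function(tias, s_table, w_r = 1, injected_MBq = NA_real_,
                            sphere_curve = NULL, tumour_mass_g = NULL,
                            cross_organ = TRUE) {
  assert_scalar_number(w_r, "w_r", positive = TRUE)
  organs <- tias$organ
  tot <- stats::setNames(tias$total_Bq_s, organs)
  body_organs <- setdiff(organs, "tumour")
  # every body source must be resolvable in the table
  have_self <- vapply(body_organs, function(o) !is.na(s_lookup(s_table, o, o)),
                      logical(1))
  if (!all(have_self)) {
    mird_stop(sprintf("S-value table lacks self-dose entries for: %s",
                      paste(body_organs[!have_self], collapse = ", ")),
              "mirdose_missing_svalue")
  }
  dose <- vapply(body_organs, function(target) {
    src <- if (cross_organ) body_organs else target
    contrib <- vapply(src, function(s) {
      S <- s_lookup(s_table, s, target)
      if (is.na(S)) 0 else tot[[s]] * S
    }, numeric(1))
    sum(contrib) * w_r
  }, numeric(1))
  out <- data.frame(target = body_organs, dose_Sv = unname(dose))
  if ("tumour" %in% organs) {
    if (is.null(sphere_curve)) {
      mird_stop("tumour present but no sphere S-value curve supplied",
                "mirdose_missing_svalue")
    }
    if (is.null(tumour_mass_g)) {
      mird_stop("tumour present but no tumour mass supplied",
                "mirdose_missing_mass")
    }
    S_t <- sphere_s_value(tumour_mass_g, sphere_curve)
    out <- rbind(out, data.frame(target = "tumour",
                                 dose_Sv = tot[["tumour"]] * S_t * w_r))
  }
  out$dose_Sv_per_MBq <- out$dose_Sv / injected_MBq
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    s_table = s_table$phantom_id, nuclide = s_table$nuclide, w_r = w_r,
    cross_organ = cross_organ, injected_MBq = injected_MBq,
    tumour_mass_g = tumour_mass_g)
  class(out) <- c("dose_report", "data.frame")
  out
}

#' Whole-body time-integrated activity
#'
#' `measured_row` mode takes the TIA computed from a `whole_body`
#' biodistribution row; `sum_of_sources` sums the organ TIAs in the table.
#'
#' @param tias A `tia_table` (may or may not contain a `whole_body` row).
#' @param mode `"measured_row"` or `"sum_of_sources"`.
#' @return A `time_integrated_activity` for `whole_body`.
#' @export
whole_body_tia <- function(tias, mode = c("measured_row", "sum_of_sources")) {
  mode <- match.arg(mode)
  if (mode == "measured_row") {
    row <- tias[tias$organ == "whole_body", ]
    if (nrow(row) == 0) {
      mird_stop("no whole_body row available for measured_row mode",
                "mirdose_missing_data")
    }
    return(new_tia("whole_body", row$auc_Bq_s[1], row$tail_Bq_s[1], row$T_s[1]))
  }
  rows <- tias[tias$organ != "whole_body", ]
  if (nrow(rows) == 0) return(new_tia("whole_body", 0, 0, NA_real_))
  new_tia("whole_body", sum(rows$auc_Bq_s), sum(rows$tail_Bq_s), rows$T_s[1])
}

#' Write a dose report as delimited text and JSON
#'
#' @param report A `dose_report`.
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.json` (schema-versioned, provenance included).
#' @export
write_dose_report <- function(report, path) {
  utils::write.table(report, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  doc <- list(schema = "mirdose/dose_report/v1",
              provenance = attr(report, "provenance"),
              doses = report)
  jsonlite::write_json(doc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
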