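# End-to-end analyses: configuration, provenance, and the report-writing
# pipeline drivers that tie the stages together. These functions are the
# package's "commands": each reads validated inputs, runs one analysis, and
# writes its reports plus a machine-readable provenance block sufficient to
# reproduce the run.

file_md5 <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  if (length(paths) == 0) return(list())
  paths <- paths[nzchar(paths) & file.exists(paths)]
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, na = "null")
  unname(tools::md5sum(tmp))
}

#' Run configuration for the dose pipelines
#'
#' Collects every assumption of a dosimetry run in one validated object:
#' nuclide, AUC upper limit, boundary rule, radiation weighting factor,
#' S-value table paths, organ-mass source, species scaling weights and
#' whole-body construction mode.
#'
#' @param nuclide_name Registry nuclide name (default `"Lu-177"`).
#' @param s_table_path Path to the organ S-value table (required for dose
#'   runs).
#' @param sphere_curve_path Path to the sphere self-dose curve (required when
#'   a tumour is dosed).
#' @param T_h AUC upper limit, hours (default 48).
#' @param boundary_rule `[0, t_first]` handling: `"plateau"`, `"zero"` or
#'   `"linear"`.
#' @param w_r Radiation weighting factor (default 1: beta/gamma/x-ray).
#' @param organ_mass_path Custom organ-mass registry; `NULL` for the bundled
#'   mouse table.
#' @param species Species key for the mass registry.
#' @param tumour_mass_g Measured tumour mass in grams (mouse side).
#' @param whole_body_mode `"measured_row"` or `"sum_of_sources"`.
#' @param mouse_bw_g,human_bw_g Body weights for the %kg/g projection.
#' @param human_tumour_diameter_cm Human tumour diameter (default 2 cm).
#' @param decay Re-apply physical decay to %ID/g (default TRUE; set FALSE for
#'   tables that are not decay-corrected).
#' @param out_dir Output directory (created if absent).
#' @param seed Seed for simulation commands.
#' @return Object of class `run_config`.
#' @export
run_config <- function(nuclide_name = "Lu-177", s_table_path = NULL,
                       sphere_curve_path = NULL, T_h = 48,
                       boundary_rule = c("plateau", "zero", "linear"),
                       w_r = 1, organ_mass_path = NULL, species = "mouse",
                       tumour_mass_g = NULL,
                       whole_body_mode = c("sum_of_sources", "measured_row"),
                       mouse_bw_g = 30, human_bw_g = 56900,
                       human_tumour_diameter_cm = 2, decay = TRUE,
                       out_dir = ".", seed = NULL) {
  boundary_rule <- match.arg(boundary_rule)
  whole_body_mode <- match.arg(whole_body_mode)
  assert_scalar_number(T_h, "T_h", positive = TRUE)
  assert_scalar_number(w_r, "w_r", positive = TRUE)
  for (p in c(s_table_path, sphere_curve_path, organ_mass_path)) {
    if (!is.null(p) && !file.exists(p)) {
      mird_stop(sprintf("configured path does not exist: %s", p),
                "mirdose_config_error")
    }
  }
  structure(list(nuclide_name = nuclide_name, s_table_path = s_table_path,
                 sphere_curve_path = sphere_curve_path, T_h = T_h,
                 boundary_rule = boundary_rule, w_r = w_r,
                 organ_mass_path = organ_mass_path, species = species,
                 tumour_mass_g = tumour_mass_g,
                 whole_body_mode = whole_body_mode,
                 mouse_bw_g = mouse_bw_g, human_bw_g = human_bw_g,
                 human_tumour_diameter_cm = human_tumour_diameter_cm,
                 decay = decay, out_dir = out_dir, seed = seed),
            class = "run_config")
}

write_provenance <- function(config, inputs, extra, path) {
  doc <- list(schema = "mirdose/provenance/v1",
              package_version = as.character(utils::packageVersion("mirdose")),
              config = unclass(config),
              config_hash = config_hash(unclass(config)),
              input_checksums = file_md5(inputs),
              seed = config$seed)
  doc <- c(doc, extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

.resolve_masses <- function(config, biodist) {
  masses <- organ_mass_registry(config$species, config$organ_mass_path)
  # per-animal masses in the table override the registry (organ-wise mean)
  if ("organ_mass_g" %in% names(biodist)) {
    measured <- biodist[!is.na(biodist$organ_mass_g), ]
    if (nrow(measured) > 0) {
      m <- tapply(measured$organ_mass_g, measured$organ, mean)
      masses[names(m)] <- m
    }
  }
  if (!is.null(config$tumour_mass_g)) masses[["tumour"]] <- config$tumour_mass_g
  masses
}

#' Mouse dose analysis: biodistribution table to dose report
#'
#' Reads a per-animal biodistribution table, computes per-organ
#' time-integrated activities (trapezoid to `T_h` plus decay tail), applies
#' the configured S-value table (tumour via the sphere model), and writes the
#' TIA table, the dose report (Sv and Sv/MBq) and a provenance log recording
#' every assumption.
#'
#' @param config A [run_config()]; `s_table_path` is required.
#' @param biodist_path Path to the biodistribution table.
#' @return The `dose_report`, invisibly; files are written under
#'   `config$out_dir` (`tia.csv`, `dose_report.csv`, `dose_report.json`,
#'   `provenance.json`).
#' @export
run_dose_analysis <- function(config, biodist_path) {
  if (is.null(config$s_table_path)) {
    mird_stop("config lacks s_table_path", "mirdose_config_error")
  }
  biodist <- read_biodist(biodist_path)
  nuc <- get_nuclide(config$nuclide_name)
  s_table <- read_svalue_table(config$s_table_path)
  sphere <- if (!is.null(config$sphere_curve_path))
    read_sphere_curve(config$sphere_curve_path) else NULL
  masses <- .resolve_masses(config, biodist)

  inj_MBq <- if ("injected_activity_MBq" %in% names(biodist) &&
                 any(!is.na(biodist$injected_activity_MBq))) {
    mean(biodist$injected_activity_MBq, na.rm = TRUE)
  } else {
    mird_stop("biodistribution table lacks injected_activity_MBq",
              "mirdose_missing_data")
  }
  organs <- unique(biodist$organ)
  tias <- tia_table(biodist, nuc, inj_MBq * 1e6, masses, T_h = config$T_h,
                    boundary_rule = config$boundary_rule, decay = config$decay,
                    organs = setdiff(organs, "whole_body"))
  wb <- tryCatch(whole_body_tia(tias, config$whole_body_mode),
                 mirdose_missing_data = function(e) NULL)
  if (config$whole_body_mode == "measured_row" && "whole_body" %in% organs) {
    wb_tab <- tia_table(biodist, nuc, inj_MBq * 1e6, masses, T_h = config$T_h,
                        boundary_rule = config$boundary_rule,
                        decay = config$decay, organs = "whole_body")
    wb <- new_tia("whole_body", wb_tab$auc_Bq_s[1], wb_tab$tail_Bq_s[1],
                  wb_tab$T_s[1])
  }
  tias_all <- tias
  if (!is.null(wb) && !is.na(s_lookup(s_table, "whole_body", "whole_body"))) {
    tias_all <- rbind(tias, data.frame(organ = "whole_body",
                                       auc_Bq_s = wb$auc_0_T_Bq_s,
                                       tail_Bq_s = wb$tail_Bq_s,
                                       total_Bq_s = wb$total_Bq_s,
                                       T_s = wb$T_s))
  }
  report <- equivalent_dose(tias_all, s_table, w_r = config$w_r,
                            injected_MBq = inj_MBq, sphere_curve = sphere,
                            tumour_mass_g = if ("tumour" %in% organs)
                              masses[["tumour"]] else NULL)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tias_all, file.path(config$out_dir, "tia.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_dose_report(report, file.path(config$out_dir, "dose_report"))
  write_provenance(config,
                   inputs = list(biodist_path, config$s_table_path,
                                 config$sphere_curve_path),
                   extra = list(stage = "mouse_dose",
                                injected_MBq = inj_MBq,
                                whole_body_mode = config$whole_body_mode,
                                organ_masses = as.list(masses[names(masses) %in%
                                                              c(organs, "tumour")])),
                   file.path(config$out_dir, "provenance.json"))
  invisible(report)
}

#' Projected human dose analysis via the %kg/g method
#'
#' As [run_dose_analysis()], but projects the mouse biodistribution to human
#' source-organ activities with the configured body weights before dosing
#' with the (human-phantom) S-value table; reports mSv/MBq alongside Sv/MBq.
#'
#' @param config A [run_config()]; `s_table_path` points to the human table.
#' @param biodist_path Path to the mouse biodistribution table.
#' @return The human `dose_report`, invisibly; writes
#'   `human_dose_report.csv/.json`, `projected_pct_id_organ.csv` and
#'   `provenance.json`.
#' @export
run_human_projection <- function(config, biodist_path) {
  if (is.null(config$s_table_path)) {
    mird_stop("config lacks s_table_path", "mirdose_config_error")
  }
  biodist <- read_biodist(biodist_path)
  nuc <- get_nuclide(config$nuclide_name)
  s_table <- read_svalue_table(config$s_table_path)
  sphere <- if (!is.null(config$sphere_curve_path))
    read_sphere_curve(config$sphere_curve_path) else NULL
  masses <- .resolve_masses(config, biodist)
  inj_MBq <- if ("injected_activity_MBq" %in% names(biodist) &&
                 any(!is.na(biodist$injected_activity_MBq))) {
    mean(biodist$injected_activity_MBq, na.rm = TRUE)
  } else {
    mird_stop("biodistribution table lacks injected_activity_MBq",
              "mirdose_missing_data")
  }
  scaling <- species_scaling(config$mouse_bw_g, config$human_bw_g)
  report <- project_human_doses(
    biodist, nuc, s_table, masses, inj_MBq, scaling = scaling,
    sphere_curve = sphere,
    human_tumour_mass_g = sphere_mass_g(config$human_tumour_diameter_cm),
    T_h = config$T_h, boundary_rule = config$boundary_rule,
    decay = config$decay, w_r = config$w_r)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dose_report(report, file.path(config$out_dir, "human_dose_report"))
  utils::write.table(attr(report, "projected_pct_id_organ"),
                     file.path(config$out_dir, "projected_pct_id_organ.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  write_provenance(config,
                   inputs = list(biodist_path, config$s_table_path,
                                 config$sphere_curve_path),
                   extra = list(stage = "human_projection",
                                injected_MBq = inj_MBq,
                                scaling = unclass(scaling)),
                   file.path(config$out_dir, "provenance.json"))
  invisible(report)
}

#' Fit a saturation binding assay from file and write the report
#'
#' @param assay_path Path to the assay table (see [read_binding_assay()]).
#' @param out_dir Output directory.
#' @param ... Passed to [fit_one_site()].
#' @return The `one_site_fit`, invisibly.
#' @export
run_binding_fit <- function(assay_path, out_dir = ".", ...) {
  data <- read_binding_assay(assay_path)
  fit <- fit_one_site(data, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fit_report(fit, file.path(out_dir, "one_site_fit.json"))
  invisible(fit)
}

#' Simulate a biodistribution study and write it to disk
#'
#' @param out_dir Output directory; writes `simulated_biodist.csv` and a
#'   provenance log.
#' @param seed Required RNG seed.
#' @param specs Kinetic specs (default [paper_like_kinetics()]).
#' @param ... Passed to [simulate_biodist()].
#' @return The simulated `biodist` data.frame, invisibly.
#' @export
run_biodist_simulation <- function(out_dir = ".", seed,
                                   specs = paper_like_kinetics(), ...) {
  sim <- simulate_biodist(specs, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "simulated_biodist.csv")
  write_biodist(sim, path)
  cfg <- run_config(out_dir = out_dir, seed = seed)
  write_provenance(cfg, inputs = list(),
                   extra = list(stage = "simulate_biodist",
                                output_checksums = file_md5(list(path))),
                   file.path(out_dir, "provenance.json"))
  invisible(sim)
}
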