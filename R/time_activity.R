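# From %ID/g observations to absolute source-region activity curves and
# time-integrated activities (trapezoidal AUC over [0, T] plus the physical
# decay tail A(T)/lambda).

#' Absolute source-organ activity from a %ID/g observation
#'
#' Implements the activity formula
#' \deqn{A(t) = \mathrm{\%ID/g}(t) \times ID/100 \times m_{organ} \times e^{-\lambda t}}
#' where ID is the injected activity in Bq and the exponential re-applies
#' physical decay (the tabulated %ID/g are assumed decay-corrected at
#' measurement; set `decay = FALSE` if they are not).
#'
#' @param pct_id_per_g %ID/g observation, >= 0.
#' @param injected_Bq Injected activity in Bq.
#' @param organ_mass_g Organ mass in grams; required — there is no silent 1 g
#'   default.
#' @param nuc A [nuclide()].
#' @param t_s Time post-injection in seconds.
#' @param decay Apply the exp(-lambda t) physical-decay factor (default TRUE).
#' @return Activity in Bq.
#' @export
activity_at <- function(pct_id_per_g, injected_Bq, organ_mass_g, nuc, t_s,
                        decay = TRUE) {
  assert_scalar_number(pct_id_per_g, "pct_id_per_g", nonnegative = TRUE)
  assert_scalar_number(injected_Bq, "injected_Bq", nonnegative = TRUE)
  if (missing(organ_mass_g) || is.null(organ_mass_g) || is.na(organ_mass_g)) {
    mird_stop("organ mass is required (no implicit 1 g assumption)",
              "mirdose_missing_mass")
  }
  assert_scalar_number(organ_mass_g, "organ_mass_g", positive = TRUE)
  assert_scalar_number(t_s, "t_s", nonnegative = TRUE)
  f <- if (decay) decay_factor(nuc, t_s) else 1
  (pct_id_per_g / 100) * injected_Bq * organ_mass_g * f
}

#' Construct a time-activity curve
#'
#' @param organ Organ name.
#' @param nuc A [nuclide()].
#' @param t_s Strictly increasing times in seconds.
#' @param activity_Bq Non-negative activities at `t_s`.
#' @param injected_activity_Bq Injected activity (for normalisation audit).
#' @param boundary_rule How the unobserved `[0, t_first]` segment is handled
#'   by [integrate_to_T()]: `"plateau"` holds the first observed activity back
#'   to t = 0, `"zero"` ramps linearly from 0, `"linear"` back-extrapolates
#'   the first two points (floored at 0; with a single point it behaves like
#'   plateau).
#' @return Object of class `time_activity_curve`.
#' @export
time_activity_curve <- function(organ, nuc, t_s, activity_Bq,
                                injected_activity_Bq = NA_real_,
                                boundary_rule = c("plateau", "zero", "linear")) {
  boundary_rule <- match.arg(boundary_rule)
  if (length(t_s) != length(activity_Bq) || length(t_s) < 1) {
    mird_stop("t_s and activity_Bq must be equal-length, non-empty",
              "mirdose_invalid_argument")
  }
  if (any(diff(t_s) <= 0)) {
    mird_stop("curve times must be strictly increasing", "mirdose_invalid_argument")
  }
  if (any(t_s < 0) || any(activity_Bq < 0)) {
    mird_stop("times and activities must be non-negative",
              "mirdose_invalid_argument")
  }
  structure(list(organ = organ, nuclide = nuc, t_s = t_s,
                 activity_Bq = activity_Bq,
                 injected_activity_Bq = injected_activity_Bq,
                 boundary_rule = boundary_rule),
            class = "time_activity_curve")
}

#' @export
print.time_activity_curve <- function(x, ...) {
  cat(sprintf("<time_activity_curve> %s (%s), %d points over [%g, %g] s, boundary = %s\n",
              x$organ, x$nuclide$name, length(x$t_s), min(x$t_s), max(x$t_s),
              x$boundary_rule))
  invisible(x)
}

# activity at time t0 implied by the boundary rule / interpolation
.curve_a0 <- function(curve) {
  t <- curve$t_s; a <- curve$activity_Bq
  if (t[1] == 0) return(a[1])
  switch(curve$boundary_rule,
    plateau = a[1],
    zero = 0,
    linear = {
      if (length(t) < 2) return(a[1])
      slope <- (a[2] - a[1]) / (t[2] - t[1])
      max(a[1] - slope * t[1], 0)
    })
}

#' Trapezoidal integral of a time-activity curve over [0, T]
#'
#' The segment before the first observation is handled per the curve's
#' boundary rule; if T falls between observations the activity at T is
#' linearly interpolated; if T exceeds the last observation the integral
#' stops there (the tail is attached at the last observation by
#' [time_integrated_activity()]).
#'
#' @param curve A [time_activity_curve()].
#' @param T_s Upper limit in seconds; must be >= the first observation time.
#' @return AUC in Bq.s.
#' @export
integrate_to_T <- function(curve, T_s) {
  assert_scalar_number(T_s, "T_s", positive = TRUE)
  t <- curve$t_s; a <- curve$activity_Bq
  if (T_s < t[1]) {
    mird_stop(sprintf("T (%g s) precedes the first observation (%g s)", T_s, t[1]),
              "mirdose_invalid_argument")
  }
  # prepend the boundary point at t = 0 when needed
  if (t[1] > 0) {
    t <- c(0, t); a <- c(.curve_a0(curve), a)
  }
  T_eff <- min(T_s, max(t))
  if (T_eff < max(t)) {
    a_T <- stats::approx(t, a, xout = T_eff)$y
    keep <- t < T_eff
    t <- c(t[keep], T_eff); a <- c(a[keep], a_T)
  }
  sum(diff(t) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
}

#' Physical-decay tail integral from T to infinity
#'
#' Assumes elimination after the last observation occurs only by radioactive
#' decay, so the remaining integral is A(T) / lambda.
#'
#' @param activity_at_T_Bq Activity at the attachment time, in Bq.
#' @param nuc A [nuclide()] (or bare decay constant).
#' @return Tail integral in Bq.s.
#' @export
tail_integral <- function(activity_at_T_Bq, nuc) {
  assert_scalar_number(activity_at_T_Bq, "activity_at_T_Bq", nonnegative = TRUE)
  lambda <- if (inherits(nuc, "nuclide")) nuc$decay_constant else nuc
  assert_scalar_number(lambda, "decay constant", positive = TRUE)
  activity_at_T_Bq / lambda
}

new_tia <- function(organ, auc, tail, T_s) {
  structure(list(organ = organ, auc_0_T_Bq_s = auc, tail_Bq_s = tail,
                 total_Bq_s = auc + tail, T_s = T_s),
            class = "time_integrated_activity")
}

#' @export
print.time_integrated_activity <- function(x, ...) {
  cat(sprintf("<TIA> %s: AUC[0,%g s] = %.4g + tail %.4g = %.4g Bq.s\n",
              x$organ, x$T_s, x$auc_0_T_Bq_s, x$tail_Bq_s, x$total_Bq_s))
  invisible(x)
}

#' Time-integrated activity for one source organ
#'
#' Builds the absolute activity curve from the group-mean %ID/g at each time
#' point via [activity_at()], integrates trapezoidally over [0, T] and
#' attaches the physical-decay tail A(T)/lambda. If the last observation
#' precedes T the tail attaches at the last observation instead, with a
#' warning.
#'
#' @param measurements Per-animal `biodist` rows for a single organ (column
#'   `organ` must be constant), or a `biodist_summary` subset for one organ.
#' @param nuc A [nuclide()].
#' @param injected_Bq Injected activity in Bq.
#' @param organ_mass_g Organ mass in grams.
#' @param T_h Upper AUC limit in hours (48 by convention).
#' @param boundary_rule See [time_activity_curve()].
#' @param decay Re-apply physical decay to the %ID/g values (default TRUE;
#'   set FALSE when the input table is not decay-corrected).
#' @return A `time_integrated_activity` with components `auc_0_T_Bq_s`,
#'   `tail_Bq_s`, `total_Bq_s`.
#' @export
time_integrated_activity <- function(measurements, nuc, injected_Bq,
                                     organ_mass_g, T_h = 48,
                                     boundary_rule = "plateau", decay = TRUE) {
  organ <- unique(measurements$organ)
  if (length(organ) != 1) {
    mird_stop("measurements must cover exactly one organ",
              "mirdose_invalid_argument")
  }
  if ("pct_id_per_g" %in% names(measurements)) {
    agg <- stats::aggregate(pct_id_per_g ~ time_h, data = measurements, FUN = mean)
  } else {
    agg <- data.frame(time_h = measurements$time_h, pct_id_per_g = measurements$mean)
  }
  agg <- agg[order(agg$time_h), ]
  t_s <- hours_to_seconds(agg$time_h)
  act <- vapply(seq_along(t_s), function(i) {
    activity_at(agg$pct_id_per_g[i], injected_Bq, organ_mass_g, nuc, t_s[i],
                decay = decay)
  }, numeric(1))
  curve <- time_activity_curve(organ, nuc, t_s, act, injected_Bq, boundary_rule)
  T_s <- hours_to_seconds(T_h)
  if (T_s < t_s[1]) {
    mird_stop("T precedes the first observation", "mirdose_invalid_argument")
  }
  t_attach <- min(T_s, max(t_s))
  if (max(t_s) < T_s) {
    mird_warn(sprintf("last observation (%g h) precedes T (%g h); tail attached at %g h",
                      max(agg$time_h), T_h, max(agg$time_h)),
              "mirdose_early_tail")
  }
  auc <- integrate_to_T(curve, T_s)
  a_T <- act[length(act)]
  if (t_attach < max(t_s)) a_T <- stats::approx(t_s, act, xout = t_attach)$y
  new_tia(organ, auc, tail_integral(a_T, nuc), t_attach)
}

#' Time-integrated activities for every organ in a biodistribution table
#'
#' @param measurements Per-animal `biodist` data (any number of organs).
#' @param nuc A [nuclide()].
#' @param injected_Bq Injected activity in Bq.
#' @param organ_masses Named numeric vector of organ masses in grams (e.g.
#'   from [organ_mass_registry()]); every organ present in `measurements`
#'   must be covered.
#' @param T_h,boundary_rule,decay See [time_integrated_activity()].
#' @param organs Organs to include; default all present except `whole_body`
#'   (handled separately by [whole_body_tia()]).
#' @return data.frame of class `tia_table` with columns
#'   `organ, auc_Bq_s, tail_Bq_s, total_Bq_s, T_s`.
#' @export
tia_table <- function(measurements, nuc, injected_Bq, organ_masses, T_h = 48,
                      boundary_rule = "plateau", decay = TRUE, organs = NULL) {
  if (is.null(organs)) organs <- setdiff(unique(measurements$organ), "whole_body")
  missing_m <- setdiff(organs, names(organ_masses))
  if (length(missing_m) > 0) {
    mird_stop(sprintf("no organ mass for: %s", paste(missing_m, collapse = ", ")),
              "mirdose_missing_mass")
  }
  rows <- lapply(organs, function(o) {
    tia <- time_integrated_activity(measurements[measurements$organ == o, ],
                                    nuc, injected_Bq, organ_masses[[o]],
                                    T_h, boundary_rule, decay)
    data.frame(organ = o, auc_Bq_s = tia$auc_0_T_Bq_s, tail_Bq_s = tia$tail_Bq_s,
               total_Bq_s = tia$total_Bq_s, T_s = tia$T_s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tia_table", "data.frame")
  out
}

#' Species organ-mass registry
#'
#' Returns a named vector of default organ masses (grams). The bundled table
#' carries standard laboratory-mouse values for a ~30 g mouse; they are
#' documented defaults, not study-specific measurements — supply per-animal
#' masses in the biodistribution table when available.
#'
#' @param species Species key in the table (default `"mouse"`).
#' @param path Custom registry (CSV: `species,organ,mass_g`); `NULL` for the
#'   bundled one.
#' @return Named numeric vector, organ -> mass in g.
#' @export
organ_mass_registry <- function(species = "mouse", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mouse_organ_masses.csv", package = "mirdose")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$species == species, ]
  if (nrow(tab) == 0) {
    mird_stop(sprintf("species '%s' not in organ-mass registry", species),
              "mirdose_missing_data")
  }
  stats::setNames(tab$mass_g, tab$organ)
}

#' Export a time-activity curve as delimited text
#' @param curve A `time_activity_curve`.
#' @param path Output file.
#' @export
write_time_activity_curve <- function(curve, path) {
  utils::write.table(
    data.frame(organ = curve$organ, t_s = curve$t_s,
               activity_Bq = curve$activity_Bq),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
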