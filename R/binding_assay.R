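# Saturation radioligand binding: non-specific subtraction, one-site
# Kd/Bmax fit, and conversion of Bmax to receptors per cell.

#' Specific binding from total and non-specific binding
#'
#' SB = TB - NSB, floored at zero (negative specific binding is measurement
#' noise; a warning is raised when the floor engages).
#'
#' @param tb Total bound, pmol (vectorised).
#' @param nsb Non-specifically bound, pmol.
#' @return Specific binding in pmol.
#' @export
specific_binding <- function(tb, nsb) {
  if (any(!is.finite(tb)) || any(!is.finite(nsb)) || any(tb < 0) || any(nsb < 0)) {
    mird_stop("tb and nsb must be non-negative and finite",
              "mirdose_invalid_argument")
  }
  sb <- tb - nsb
  if (any(sb < 0)) {
    mird_warn(sprintf("%d observation(s) with TB < NSB floored at 0",
                      sum(sb < 0)), "mirdose_negative_sb")
    sb[sb < 0] <- 0
  }
  sb
}

#' Read a saturation binding assay table
#'
#' Header: `free_conc_nM,total_bound_pmol,nonspecific_bound_pmol,n_cells,volume_L`.
#' @param path File to read.
#' @export
read_binding_assay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("free_conc_nM", "total_bound_pmol", "nonspecific_bound_pmol")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    mird_stop(sprintf("binding assay table missing column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "mirdose_schema_error")
  }
  if (any(df$free_conc_nM <= 0)) {
    mird_stop("free concentrations must be positive", "mirdose_schema_error")
  }
  df
}

#' One-site receptor binding fit (Kd, Bmax)
#'
#' Fits the hyperbolic one-site model \eqn{SB(F) = B_{max} F / (K_d + F)} to
#' specific binding (TB minus NSB, per [specific_binding()]) by unweighted
#' nonlinear least squares with positivity bounds, and the non-specific arm
#' as a straight line through the origin. Replicate observations are fitted
#' individually. Alternative modes: `joint` fits TB = Bmax F/(Kd+F) + ns F
#' directly (no subtraction); `weights = "1/Y2"` applies inverse-square
#' weighting.
#'
#' @param data data.frame with columns `free_conc_nM, total_bound_pmol,
#'   nonspecific_bound_pmol` and optionally `n_cells`.
#' @param mode `"subtract"` (default, fit SB after NSB subtraction) or
#'   `"joint"`.
#' @param weights `"none"` or `"1/Y2"`.
#' @param depletion_corrected If TRUE, use F = added - bound/volume (needs
#'   `volume_L`); default FALSE: nominal added concentration.
#' @return Object of class `one_site_fit` with `kd_nM`, `bmax_pmol`,
#'   `ns_slope`, standard errors, `receptors_per_cell` (when `n_cells`
#'   present), residual summary and convergence diagnostics.
#' @export
fit_one_site <- function(data, mode = c("subtract", "joint"),
                         weights = c("none", "1/Y2"),
                         depletion_corrected = FALSE) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  f <- data$free_conc_nM
  if (length(unique(f)) < 4) {
    mird_stop("need >= 4 distinct free concentrations", "mirdose_invalid_argument")
  }
  tb <- data$total_bound_pmol
  nsb <- data$nonspecific_bound_pmol
  if (depletion_corrected) {
    if (!"volume_L" %in% names(data)) {
      mird_stop("depletion correction needs a volume_L column",
                "mirdose_invalid_argument")
    }
    f <- pmax(f - (tb * 1e-12) / data$volume_L * 1e9, min(f) * 1e-6)
  }

  ns_fit <- stats::lm(nsb ~ 0 + f)
  ns_slope <- unname(stats::coef(ns_fit)[1])
  # summary.lm warns on an exactly collinear (noise-free) NSB arm
  ns_se <- unname(suppressWarnings(summary(ns_fit))$coefficients[1, 2])

  # starting values: Bmax from the top of the curve, Kd from half-saturation
  sb0 <- pmax(tb - nsb, 0)
  bmax0 <- max(sb0) * 1.05 + 1e-12
  kd0 <- {
    half <- bmax0 / 2
    cand <- f[which.min(abs(sb0 - half))]
    max(cand, min(f))
  }
  w <- NULL
  fit_env <- if (mode == "subtract") {
    sb <- specific_binding(tb, nsb)
    if (weights == "1/Y2") w <- 1 / pmax(sb, max(sb) * 1e-3)^2
    df <- data.frame(f = f, y = sb)
    list(formula = y ~ bmax * f / (kd + f), df = df,
         start = list(bmax = bmax0, kd = kd0),
         lower = c(bmax = 0, kd = 1e-9))
  } else {
    if (weights == "1/Y2") w <- 1 / pmax(tb, max(tb) * 1e-3)^2
    df <- data.frame(f = f, y = tb)
    list(formula = y ~ bmax * f / (kd + f) + ns * f, df = df,
         start = list(bmax = bmax0, kd = kd0, ns = max(ns_slope, 1e-9)),
         lower = c(bmax = 0, kd = 1e-9, ns = 0))
  }
  fit <- tryCatch(
    stats::nls(fit_env$formula, data = fit_env$df, start = fit_env$start,
               lower = fit_env$lower, algorithm = "port", weights = w,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      mird_stop(sprintf("one-site fit failed to converge: %s", conditionMessage(e)),
                "mirdose_fit_failure")
    })
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2],
                 error = function(e) rep(NA_real_, length(est)))
  kd <- unname(est["kd"]); bmax <- unname(est["bmax"])
  if (mode == "joint") {
    ns_slope <- unname(est["ns"])
    ns_se <- unname(se["ns"])
  }
  if (kd <= 2e-9 || bmax <= 1e-9 * max(abs(fit_env$df$y), 1)) {
    mird_stop("fit not identifiable (Kd pinned at the bound or no saturable component)",
              "mirdose_fit_failure")
  }
  rpc <- if ("n_cells" %in% names(data)) {
    receptors_per_cell(bmax, data$n_cells[1])
  } else NA_real_
  res <- stats::resid(fit)
  structure(list(
    kd_nM = kd, bmax_pmol = bmax, ns_slope = ns_slope,
    kd_se = unname(se["kd"]), bmax_se = unname(se["bmax"]), ns_se = ns_se,
    receptors_per_cell = rpc,
    mode = mode, weights = weights,
    rss = sum(res^2), df_residual = stats::df.residual(fit),
    converged = TRUE, n_obs = nrow(data)),
    class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> Kd = %.3g +/- %.2g nM, Bmax = %.3g +/- %.2g pmol, ns = %.3g pmol/nM\n",
              x$kd_nM, x$kd_se, x$bmax_pmol, x$bmax_se, x$ns_slope))
  if (!is.na(x$receptors_per_cell)) {
    cat(sprintf("  receptors/cell = %.3g\n", x$receptors_per_cell))
  }
  cat(sprintf("  mode = %s, n = %d, RSS = %.3g\n", x$mode, x$n_obs, x$rss))
  invisible(x)
}

#' Convert a fitted Bmax to receptors per cell
#'
#' @param bmax_pmol Maximal specific binding in pmol.
#' @param n_cells Number of cells in the assay tube.
#' @return `bmax_pmol * 1e-12 * N_A / n_cells` (N_A = 6.02214e23).
#' @export
receptors_per_cell <- function(bmax_pmol, n_cells) {
  assert_scalar_number(bmax_pmol, "bmax_pmol", nonnegative = TRUE)
  assert_scalar_number(n_cells, "n_cells", positive = TRUE)
  bmax_pmol * 1e-12 * 6.02214e23 / n_cells
}

#' Write a one-site fit report as JSON
#' @param fit A `one_site_fit`.
#' @param path Output file.
#' @export
write_fit_report <- function(fit, path) {
  doc <- c(list(schema = "mirdose/one_site_fit/v1"), unclass(fit))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
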