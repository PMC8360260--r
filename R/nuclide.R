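#' Physical decay constant from a half-life
#'
#' @param half_life_s Half-life in seconds; must be positive and finite.
#' @return The decay constant \eqn{\lambda = \ln 2 / t_{1/2}} in s\eqn{^{-1}}.
#' @examples
#' decay_constant(45720)   # 64Cu (12.7 h): 1.52e-5 per second
#' decay_constant(578880)  # 177Lu (6.7 d): 1.197e-6 per second
#' @export
decay_constant <- function(half_life_s) {
  assert_scalar_number(half_life_s, "half_life_s", positive = TRUE)
  log(2) / half_life_s
}

#' Construct a nuclide
#'
#' A nuclide bundles the physical decay parameters used throughout the dose
#' calculations with emission metadata. Emissions are descriptive only: the
#' dose math works entirely through S-values, which already encapsulate the
#' emission spectrum for a given phantom.
#'
#' @param name Nuclide identifier, e.g. `"Cu-64"`.
#' @param half_life_s Physical half-life in seconds.
#' @param emissions Optional data.frame with columns `kind` (one of `beta-`,
#'   `beta+`, `gamma`, `x-ray`), `energy_MeV`, `abundance` (fraction in
#'   \[0, 1\]).
#' @return An object of class `nuclide` with fields `name`, `half_life_s`,
#'   `decay_constant` and `emissions`.
#' @seealso [decay_constant()], [decay_factor()], [nuclide_registry()]
#' @export
nuclide <- function(name, half_life_s, emissions = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    mird_stop("`name` must be a non-empty string", "mirdose_invalid_argument")
  }
  assert_scalar_number(half_life_s, "half_life_s", positive = TRUE)
  if (is.null(emissions)) {
    emissions <- data.frame(kind = character(), energy_MeV = numeric(),
                            abundance = numeric())
  }
  kinds <- c("beta-", "beta+", "gamma", "x-ray")
  if (!all(c("kind", "energy_MeV", "abundance") %in% names(emissions))) {
    mird_stop("`emissions` needs columns kind, energy_MeV, abundance",
              "mirdose_invalid_argument")
  }
  if (nrow(emissions) > 0) {
    if (!all(emissions$kind %in% kinds)) {
      mird_stop(sprintf("emission kind must be one of %s",
                        paste(kinds, collapse = ", ")),
                "mirdose_invalid_argument")
    }
    if (any(emissions$abundance < 0 | emissions$abundance > 1)) {
      mird_stop("emission abundances must lie in [0, 1]",
                "mirdose_invalid_argument")
    }
    if (any(emissions$energy_MeV <= 0)) {
      mird_stop("emission energies must be positive",
                "mirdose_invalid_argument")
    }
  }
  structure(
    list(name = name,
         half_life_s = half_life_s,
         decay_constant = decay_constant(half_life_s),
         emissions = emissions),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s  t1/2 = %g s (%.3g h)  lambda = %.4g /s\n",
              x$name, x$half_life_s, x$half_life_s / 3600, x$decay_constant))
  if (nrow(x$emissions) > 0) {
    cat(sprintf("  %d emission record(s)\n", nrow(x$emissions)))
  }
  invisible(x)
}

#' Physical decay factor exp(-lambda t)
#'
#' @param nuc A [nuclide()] (or a bare decay constant in s\eqn{^{-1}}).
#' @param t_s Elapsed time in seconds, non-negative.
#' @return The surviving fraction \eqn{e^{-\lambda t}} in (0, 1\].
#' @export
decay_factor <- function(nuc, t_s) {
  lambda <- if (inherits(nuc, "nuclide")) nuc$decay_constant else nuc
  assert_scalar_number(lambda, "decay constant", positive = TRUE)
  if (!is.numeric(t_s) || any(is.na(t_s)) || any(t_s < 0)) {
    mird_stop("`t_s` must be non-negative", "mirdose_invalid_argument")
  }
  exp(-lambda * t_s)
}

#' Convert hours post-injection to seconds
#'
#' All public inputs carry time in hours (the sampling convention); all
#' internal decay and integration math runs in seconds.
#' @param t_h Time in hours.
#' @export
hours_to_seconds <- function(t_h) t_h * 3600

#' Bundled nuclide registry
#'
#' Reads the nuclide table shipped with the package (or a user-supplied table
#' in the same schema) and returns a named list of [nuclide()] objects. The
#' bundled registry carries Cu-64 at 12.7 h and Lu-177 at 6.7 d half-life —
#' the values the source dosimetry arithmetic assumes by default. Users
#' wanting physically precise constants (e.g. 6.647 d for Lu-177) supply
#' their own table or call [nuclide()] directly.
#'
#' @param path Path to a delimited nuclide table with columns
#'   `name,half_life_s`; `NULL` for the bundled table.
#' @param emissions_path Optional companion table
#'   (`name,kind,energy_MeV,abundance`); `NULL` for the bundled one when
#'   `path` is `NULL`, otherwise no emissions are attached.
#' @return Named list of `nuclide` objects.
#' @export
nuclide_registry <- function(path = NULL, emissions_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nuclides.csv", package = "mirdose")
    if (is.null(emissions_path)) {
      emissions_path <- system.file("extdata", "nuclide_emissions.csv",
                                    package = "mirdose")
    }
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "half_life_s") %in% names(tab))) {
    mird_stop("nuclide table needs columns name, half_life_s",
              "mirdose_schema_error")
  }
  emis <- NULL
  if (!is.null(emissions_path) && nzchar(emissions_path) &&
      file.exists(emissions_path)) {
    emis <- utils::read.csv(emissions_path, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    e <- NULL
    if (!is.null(emis)) {
      rows <- emis[emis$name == tab$name[i], c("kind", "energy_MeV", "abundance")]
      if (nrow(rows) > 0) e <- rows
    }
    nuclide(tab$name[i], tab$half_life_s[i], emissions = e)
  })
  names(out) <- tab$name
  out
}

#' Look up a nuclide by name in the bundled registry
#'
#' @param name Registry name, e.g. `"Cu-64"` or `"Lu-177"`.
#' @param registry A registry list from [nuclide_registry()]; `NULL` uses the
#'   bundled one.
#' @export
get_nuclide <- function(name, registry = NULL) {
  if (is.null(registry)) registry <- nuclide_registry()
  if (!name %in% names(registry)) {
    mird_stop(sprintf("nuclide '%s' not in registry (have: %s)", name,
                      paste(names(registry), collapse = ", ")),
              "mirdose_missing_data")
  }
  registry[[name]]
}
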