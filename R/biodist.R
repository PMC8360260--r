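# Biodistribution data model: long-format per-animal %ID/g tables and
# group-level summaries. One row per animal x organ x time; the wide
# publication-style layout is an output report only (see biodist_report()).

.base_organs <- c("heart", "lungs", "stomach", "pancreas", "intestine",
                  "spleen", "liver", "kidneys", "bone", "skin", "muscle",
                  "blood", "tumour", "whole_body")

.organ_synonyms <- c(
  "intestines" = "intestine",
  "tumor"      = "tumour",
  "kidney"     = "kidneys",
  "lung"       = "lungs",
  "whole body" = "whole_body",
  "wholebody"  = "whole_body"
)

#' Controlled organ vocabulary
#'
#' Canonical organ names accepted in biodistribution tables. Matching is
#' case-insensitive and a small synonym map is applied first
#' ("intestines" -> "intestine", "tumor" -> "tumour", ...). The vocabulary is
#' extensible: pass extra organ names where a function accepts
#' `extra_organs`.
#' @return Character vector of canonical organ names.
#' @export
organ_vocabulary <- function() .base_organs

#' Canonicalise organ names
#'
#' @param organ Character vector of organ labels.
#' @param extra_organs Additional canonical names to accept.
#' @return Canonical lower-case names; unknown labels become `NA`.
#' @export
canonical_organ <- function(organ, extra_organs = character()) {
  x <- tolower(trimws(organ))
  hit <- x %in% names(.organ_synonyms)
  x[hit] <- .organ_synonyms[x[hit]]
  vocab <- c(.base_organs, tolower(extra_organs))
  x[!x %in% vocab] <- NA_character_
  x
}

.biodist_required <- c("subject_id", "group_id", "organ", "time_h",
                       "pct_id_per_g")
.biodist_optional <- c("organ_mass_g", "injected_activity_MBq",
                       "injected_protein_ug")

validate_biodist <- function(df, extra_organs = character()) {
  missing_cols <- setdiff(.biodist_required, names(df))
  if (length(missing_cols) > 0) {
    mird_stop(sprintf("biodistribution table missing column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "mirdose_schema_error")
  }
  canon <- canonical_organ(df$organ, extra_organs)
  bad <- which(is.na(canon))
  if (length(bad) > 0) {
    mird_stop(sprintf("unknown organ '%s' at row %d", df$organ[bad[1]], bad[1]),
              "mirdose_schema_error")
  }
  df$organ <- canon
  chk <- function(col, ok, what) {
    if (!col %in% names(df)) return(invisible(NULL))
    v <- df[[col]]
    bad <- which(!is.na(v) & !ok(v))
    if (length(bad) > 0) {
      mird_stop(sprintf("%s at row %d (%s = %g)", what, bad[1], col, v[bad[1]]),
                "mirdose_schema_error")
    }
  }
  chk("pct_id_per_g", function(v) v >= 0, "negative %ID/g")
  chk("time_h", function(v) v >= 0, "negative time")
  chk("organ_mass_g", function(v) v > 0, "non-positive organ mass")
  chk("injected_activity_MBq", function(v) v > 0, "non-positive injected activity")
  chk("injected_protein_ug", function(v) v > 0, "non-positive injected protein")
  class(df) <- c("biodist", "data.frame")
  df
}

#' Read a biodistribution table
#'
#' Expects delimited text (comma by default, tab accepted) in long format:
#' one row per animal x organ x time with header
#' `subject_id,group_id,organ,time_h,pct_id_per_g` and optional columns
#' `organ_mass_g,injected_activity_MBq,injected_protein_ug`. The %ID/g values
#' are taken as decay-corrected at measurement; physical decay is re-applied
#' downstream via the exp(-lambda t) term of the activity formula.
#'
#' @param path File to read.
#' @param sep Field separator; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param extra_organs Additional organ names to accept beyond
#'   [organ_vocabulary()].
#' @return A validated data.frame of class `biodist`.
#' @export
read_biodist <- function(path, sep = NULL, extra_organs = character()) {
  if (!file.exists(path)) {
    mird_stop(sprintf("file not found: %s", path), "mirdose_invalid_argument")
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_biodist(df, extra_organs)
}

#' Write a biodistribution table
#'
#' @param df A `biodist` data.frame (or anything passing [validate_biodist()]).
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_biodist <- function(df, path, sep = ",") {
  out <- as.data.frame(df)
  # full-precision numeric formatting so read(write(x)) is bit-exact
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise per-animal measurements into group means and SEMs
#'
#' One summary row per (group, organ, time) cell: arithmetic mean, SEM
#' computed as the sample SD (n-1 denominator) over sqrt(n), and n. A
#' single-animal cell gets SEM 0.
#'
#' @param df Long-format biodistribution data (`biodist` or plain data.frame
#'   with the same columns).
#' @return data.frame with columns `group_id, organ, time_h, mean, sem, n`,
#'   class `biodist_summary`.
#' @export
summarize_biodist <- function(df) {
  if (nrow(df) == 0) {
    out <- data.frame(group_id = character(), organ = character(),
                      time_h = numeric(), mean = numeric(), sem = numeric(),
                      n = integer())
    class(out) <- c("biodist_summary", "data.frame")
    return(out)
  }
  df <- validate_biodist(as.data.frame(df))
  key <- interaction(df$group_id, df$organ, df$time_h, drop = TRUE)
  pieces <- split(df, key)
  rows <- lapply(pieces, function(p) {
    v <- p$pct_id_per_g
    n <- length(v)
    data.frame(group_id = p$group_id[1], organ = p$organ[1],
               time_h = p$time_h[1], mean = mean(v),
               sem = if (n > 1) stats::sd(v) / sqrt(n) else 0,
               n = n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_id, out$organ, out$time_h), ]
  rownames(out) <- NULL
  class(out) <- c("biodist_summary", "data.frame")
  out
}

#' Write a group summary table
#' @param summary A `biodist_summary` data.frame.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_biodist_summary <- function(summary, path, sep = ",") {
  utils::write.table(summary, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chelator substitution level from a trace-labeling assay
#'
#' The substitution level (moles of chelator per mole of protein) is the
#' proportion of label bound to protein multiplied by the molar excess of
#' activated chelator used in the conjugation reaction (e.g. a 20:1
#' DOTA-NHS:protein ratio with 19% bound gives 3.8 DOTA per protein).
#'
#' @param bound_fraction Fraction of trace label on the protein, in \[0, 1\].
#' @param molar_excess Chelator:protein molar ratio in the reaction, > 0.
#' @return Moles chelator per mole protein.
#' @export
chelator_substitution <- function(bound_fraction, molar_excess) {
  assert_scalar_number(bound_fraction, "bound_fraction", nonnegative = TRUE)
  if (bound_fraction > 1) {
    mird_stop("`bound_fraction` must lie in [0, 1]", "mirdose_invalid_argument")
  }
  assert_scalar_number(molar_excess, "molar_excess", positive = TRUE)
  bound_fraction * molar_excess
}
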