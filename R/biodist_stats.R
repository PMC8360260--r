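# Comparison statistics reported alongside biodistribution tables:
# tumour/blood ratios, fold differences between group means, and exact
# small-sample two-sided rank-sum (Mann-Whitney U) tests.

new_ratio_estimate <- function(label, value, mode, sem = NA_real_, n = NA_integer_) {
  structure(list(label = label, value = value, mode = mode, sem = sem, n = n),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  disp <- if (is.na(x$sem)) "" else sprintf(" ± %.3g (SEM, n = %d)", x$sem, x$n)
  cat(sprintf("<ratio_estimate> %s = %.4g%s  [%s]\n", x$label, x$value, disp, x$mode))
  invisible(x)
}

#' Tumour-to-blood uptake ratio
#'
#' Two conventions are supported. `ratio_of_means` divides the group-mean
#' tumour %ID/g by the group-mean blood %ID/g — the check against printed
#' summary tables. `mean_of_ratios` pairs tumour and blood within each animal
#' (by `subject_id`) and reports the mean and SEM of the per-animal ratios —
#' the convention implied where a published T/B row disagrees with the ratio
#' of the published means. The default `"auto"` uses `mean_of_ratios` when
#' per-animal pairing exists and falls back to `ratio_of_means` otherwise.
#'
#' @param data Per-animal `biodist` data or a `biodist_summary`.
#' @param group Group identifier to select.
#' @param time_h Time point (hours) to select.
#' @param mode `"auto"`, `"mean_of_ratios"` or `"ratio_of_means"`.
#' @return A `ratio_estimate`.
#' @export
tumour_to_blood <- function(data, group, time_h,
                            mode = c("auto", "mean_of_ratios", "ratio_of_means")) {
  mode <- match.arg(mode)
  is_summary <- inherits(data, "biodist_summary") ||
    (!"subject_id" %in% names(data) && "mean" %in% names(data))
  sel <- data[data$group_id == group & data$time_h == time_h, ]
  tum <- sel[sel$organ == "tumour", ]
  blo <- sel[sel$organ == "blood", ]
  if (nrow(tum) == 0 || nrow(blo) == 0) {
    mird_stop(sprintf("tumour and blood required at (%s, %g h); have %s",
                      group, time_h, paste(unique(sel$organ), collapse = ", ")),
              "mirdose_missing_data")
  }
  label <- sprintf("T/B %s @ %g h", group, time_h)
  if (is_summary || mode == "ratio_of_means") {
    mt <- if (is_summary) tum$mean[1] else mean(tum$pct_id_per_g)
    mb <- if (is_summary) blo$mean[1] else mean(blo$pct_id_per_g)
    if (mb == 0) mird_stop("blood mean is zero", "mirdose_division_error")
    return(new_ratio_estimate(label, mt / mb, "ratio_of_means"))
  }
  paired <- merge(tum[, c("subject_id", "pct_id_per_g")],
                  blo[, c("subject_id", "pct_id_per_g")],
                  by = "subject_id", suffixes = c("_t", "_b"))
  if (mode == "auto" && nrow(paired) == 0) {
    return(tumour_to_blood(data, group, time_h, "ratio_of_means"))
  }
  if (nrow(paired) == 0) {
    mird_stop("mean_of_ratios requires tumour/blood pairs sharing subject_id",
              "mirdose_missing_data")
  }
  if (any(paired$pct_id_per_g_b == 0)) {
    mird_stop("zero blood %ID/g in a paired animal", "mirdose_division_error")
  }
  r <- paired$pct_id_per_g_t / paired$pct_id_per_g_b
  n <- length(r)
  new_ratio_estimate(label, mean(r), "mean_of_ratios",
                     sem = if (n > 1) stats::sd(r) / sqrt(n) else 0, n = n)
}

#' Fold difference between two group means
#'
#' @param mean_a Numerator mean.
#' @param mean_b Denominator mean; must be > 0.
#' @return `mean_a / mean_b`.
#' @export
fold_difference <- function(mean_a, mean_b) {
  assert_scalar_number(mean_a, "mean_a", nonnegative = TRUE)
  assert_scalar_number(mean_b, "mean_b")
  if (mean_b <= 0) {
    mird_stop("`mean_b` must be > 0", "mirdose_division_error")
  }
  mean_a / mean_b
}

#' Exact two-sided rank-sum (Mann-Whitney U) test
#'
#' Enumerates all choose(n_a + n_b, n_a) assignments of the pooled
#' observations to the two groups, computes the U statistic from midranks
#' (ties allowed), and returns the exact two-sided p-value: the proportion of
#' assignments whose U deviates from its null mean n_a n_b / 2 by at least as
#' much as the observed U. Intended for the small destructive-sampling group
#' sizes of biodistribution studies (n per group up to 10).
#'
#' @param group_a,group_b Numeric observation vectors, each non-empty.
#' @return Exact two-sided p-value in (0, 1].
#' @export
rank_sum_exact <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    mird_stop("both groups must be non-empty", "mirdose_invalid_argument")
  }
  if (any(!is.finite(c(group_a, group_b)))) {
    mird_stop("observations must be finite", "mirdose_invalid_argument")
  }
  na <- length(group_a); nb <- length(group_b)
  if (na > 10 || nb > 10) {
    mird_stop("exact enumeration supports group sizes up to 10",
              "mirdose_invalid_argument")
  }
  pooled <- c(group_a, group_b)
  r <- rank(pooled)  # midranks for ties
  u_from_idx <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_from_idx(seq_len(na))
  centre <- na * nb / 2
  dev_obs <- abs(u_obs - centre)
  combos <- utils::combn(na + nb, na)
  devs <- abs(apply(combos, 2, u_from_idx) - centre)
  mean(devs >= dev_obs - 1e-9)
}

#' Publication-style wide biodistribution report
#'
#' Reshapes a group summary into the wide layout of a biodistribution table:
#' organ rows, one column per (group, time) cell formatted "mean ± sem",
#' optionally followed by exact rank-sum p-value columns comparing two groups
#' at each shared time point (requires per-animal data).
#'
#' @param measurements Per-animal `biodist` data.
#' @param path Optional output file (delimited text); `NULL` returns the
#'   data.frame only.
#' @param compare Optional character vector of two group_ids to test against
#'   each other at every shared time point.
#' @param sep Field separator for the written file.
#' @param digits Rounding for the formatted cells.
#' @return The wide report data.frame, invisibly if written to `path`.
#' @export
biodist_report <- function(measurements, path = NULL, compare = NULL,
                           sep = ",", digits = 1) {
  s <- summarize_biodist(measurements)
  organs <- unique(s$organ)
  cols <- unique(s[, c("group_id", "time_h")])
  cols <- cols[order(cols$group_id, cols$time_h), ]
  out <- data.frame(organ = organs, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cols))) {
    g <- cols$group_id[i]; t <- cols$time_h[i]
    cell <- vapply(organs, function(o) {
      row <- s[s$group_id == g & s$organ == o & s$time_h == t, ]
      if (nrow(row) == 0) return(NA_character_)
      sprintf("%.*f ± %.*f", digits, row$mean, digits, row$sem)
    }, character(1))
    out[[sprintf("%s_%gh", g, t)]] <- cell
  }
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2)
    a <- measurements[measurements$group_id == compare[1], ]
    b <- measurements[measurements$group_id == compare[2], ]
    shared_t <- intersect(unique(a$time_h), unique(b$time_h))
    for (t in sort(shared_t)) {
      pcol <- vapply(organs, function(o) {
        va <- a$pct_id_per_g[a$organ == o & a$time_h == t]
        vb <- b$pct_id_per_g[b$organ == o & b$time_h == t]
        if (length(va) == 0 || length(vb) == 0) return(NA_real_)
        rank_sum_exact(va, vb)
      }, numeric(1))
      out[[sprintf("p_%s_vs_%s_%gh", compare[1], compare[2], t)]] <- round(pcol, 4)
    }
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
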