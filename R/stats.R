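# Group statistics: paired t-tests, Pearson correlations, Shapiro-Wilk
# normality checks, population summary statistics, per-second
# Bonferroni-corrected tests, and the per-subject summary-table layout.

#' Paired-samples t-test
#'
#' Classical paired t on the within-subject differences, df = n - 1.
#'
#' @param x,y Per-subject values for the two conditions, equal length
#'   `>= 2`.
#' @return A one-row tibble: `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps)
    stop("t undefined: all paired differences are identical")
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean(d))
}

#' Pearson correlation with exact t-transform p-value
#'
#' @param x,y Numeric vectors, equal length `>= 3`, non-constant.
#' @return A one-row tibble: `r`, `p` (two-sided, from the t transform
#'   with n - 2 df), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return A one-row tibble: `W`, `p`.
#' @export
normality_check <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("normality check undefined for constant input")
  ht <- stats::shapiro.test(x)
  tibble::tibble(W = unname(ht$statistic), p = ht$p.value)
}

#' Mean and population standard deviation
#'
#' The spread uses the population divisor N (not N - 1); this is the
#' convention of the reference tables' "SDT" rows.
#'
#' @param x Numeric vector, `n >= 1`.
#' @return A one-row tibble: `mean`, `sd_pop`, `n`.
#' @export
summary_stats <- function(x) {
  if (length(x) < 1) stop("empty input")
  tibble::tibble(mean = mean(x),
                 sd_pop = sqrt(mean((x - mean(x))^2)),
                 n = length(x))
}

#' Per-second paired tests with Bonferroni correction
#'
#' Runs a paired t-test across subjects at every time stamp of two
#' aligned per-subject TBR series and Bonferroni-corrects over the number
#' of seconds tested (corrected p = raw p x m, capped at 1).
#'
#' @param series A tibble with columns `subject`, `time`, `condition`,
#'   `tbr`, containing both conditions at identical time stamps.
#' @param conditions The two condition labels to compare (order gives the
#'   sign of t).
#' @param alpha_family Family-wise threshold on the corrected p (default
#'   0.01).
#' @return A tibble with one row per second: `time`, `t`, `df`, `p_raw`,
#'   `p_corrected`, `significant`.
#' @export
bonferroni_per_second <- function(series, conditions = c("Attention", "Inattention"),
                                  alpha_family = 0.01) {
  need <- c("subject", "time", "condition", "tbr")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  wide <- series |>
    dplyr::filter(.data$condition %in% conditions) |>
    tidyr::pivot_wider(id_cols = c("subject", "time"),
                       names_from = "condition", values_from = "tbr")
  if (!all(conditions %in% names(wide)) || anyNA(wide[conditions]))
    stop("misaligned series: conditions missing at some subject/time")
  times <- sort(unique(wide$time))
  m <- length(times)
  purrr::map(times, function(tt) {
    sub <- wide[wide$time == tt, ]
    ht <- paired_t(sub[[conditions[1]]], sub[[conditions[2]]])
    tibble::tibble(
      time = tt, t = ht$t, df = ht$df, p_raw = ht$p,
      p_corrected = pmin(1, ht$p * m),
      significant = pmin(1, ht$p * m) < alpha_family
    )
  }) |> purrr::list_rbind()
}

#' Per-subject summary table
#'
#' Builds the reference-table layout: one row per subject with a metric
#' pair per condition, followed by `Mean` and `SDT` (population SD) rows
#' and per-condition `r` / `p` rows from the Pearson correlation between
#' the two metrics.
#'
#' @param indices A tibble with columns `subject`, `condition`, and the
#'   two metric columns.
#' @param metrics Character pair, e.g. `c("erd", "ami")` or
#'   `c("erd", "tbr")`.
#' @param conditions Condition order for the column blocks.
#' @return A tibble in table layout: `subject` plus
#'   `<metric>_<condition>` value columns; summary rows labelled `Mean`,
#'   `SDT`, `r`, `p` (r/p stored under the first metric column of each
#'   condition block, `NA` elsewhere). Carries the tidy per-subject data
#'   in the `"indices"` attribute.
#' @export
build_summary_table <- function(indices, metrics = c("erd", "ami"),
                                conditions = c("Attention", "Inattention")) {
  stopifnot(all(c("subject", "condition", metrics) %in% names(indices)),
            length(metrics) == 2)
  wide <- indices |>
    dplyr::select(dplyr::all_of(c("subject", "condition", metrics))) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = dplyr::all_of(metrics))
  cols <- as.vector(outer(metrics, conditions, paste, sep = "_"))
  if (!all(cols %in% names(wide)))
    stop("missing subjects or conditions for the requested metrics")
  if (anyNA(wide[cols])) stop("incomplete per-subject values")
  wide <- wide[, c("subject", cols)]
  wide$subject <- as.character(wide$subject)

  mrow <- srow <- rrow <- prow <- stats::setNames(
    as.list(rep(NA_real_, length(cols))), cols)
  for (cc in cols) {
    st <- summary_stats(wide[[cc]])
    mrow[[cc]] <- st$mean
    srow[[cc]] <- st$sd_pop
  }
  for (cnd in conditions) {
    pair <- paste(metrics, cnd, sep = "_")
    slot <- pair[1]
    if (nrow(wide) >= 3 &&
        stats::sd(wide[[pair[1]]]) > 0 && stats::sd(wide[[pair[2]]]) > 0) {
      ct <- pearson_r(wide[[pair[1]]], wide[[pair[2]]])
      rrow[[slot]] <- ct$r
      prow[[slot]] <- ct$p
    }
  }
  summary_rows <- dplyr::bind_rows(
    tibble::as_tibble(c(list(subject = "Mean"), mrow)),
    tibble::as_tibble(c(list(subject = "SDT"), srow)),
    tibble::as_tibble(c(list(subject = "r"), rrow)),
    tibble::as_tibble(c(list(subject = "p"), prow))
  )
  out <- dplyr::bind_rows(wide, summary_rows)
  attr(out, "indices") <- indices
  attr(out, "metrics") <- metrics
  class(out) <- c("summary_table", class(out))
  out
}
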