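# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ERSP map into a long tibble
#'
#' @param x An [ersp()] map.
#' @param ... Unused.
#' @return Tibble with `freq`, `time`, `db`, `channel`, `condition`.
#' @export
tidy.ersp_map <- function(x, ...) {
  tibble::tibble(
    freq = rep(x$freq, times = length(x$time)),
    time = rep(x$time, each = length(x$freq)),
    db = as.vector(x$values),
    channel = x$channel, condition = x$condition
  )
}

#' @rdname tidy.ersp_map
#' @export
glance.ersp_map <- function(x, ...) {
  tibble::tibble(
    channel = x$channel, condition = x$condition, n_trials = x$n_trials,
    n_freq = length(x$freq), n_time = length(x$time),
    win = x$win, step = x$step, wavelet = x$wavelet
  )
}

#' Tidy a cluster-permutation result
#'
#' One row per formed cluster with its member bins or electrodes.
#'
#' @param x A `cluster_result` from [cluster_perm_tf()] or
#'   [cluster_perm_channels()].
#' @param ... Unused.
#' @return The cluster tibble, with a `members` list-column (bin
#'   coordinates or electrode names).
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- x$clusters
  out$members <- if (x$space == "electrodes") {
    purrr::map(x$members, \(ix) x$electrodes[ix])
  } else {
    nf <- length(x$freq)
    purrr::map(x$members, function(ix) {
      tibble::tibble(freq = x$freq[(ix - 1L) %% nf + 1L],
                     time = x$time[(ix - 1L) %/% nf + 1L])
    })
  }
  out
}

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    space = x$space, n_perm = x$n_perm,
    alpha_form = x$alpha_form, alpha_cluster = x$alpha_cluster,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    max_abs_mass = if (nrow(x$clusters)) max(abs(x$clusters$mass)) else 0,
    null_q95 = unname(stats::quantile(x$null, 0.95))
  )
}

#' Tidy a summary table back to per-subject rows
#'
#' @param x A [build_summary_table()] result.
#' @param ... Unused.
#' @return The tidy per-subject index tibble the table was built from.
#' @export
tidy.summary_table <- function(x, ...) attr(x, "indices")

#' @rdname tidy.summary_table
#' @export
glance.summary_table <- function(x, ...) {
  metrics <- attr(x, "metrics")
  vals <- x[x$subject %in% c("Mean", "SDT", "r", "p"), ]
  out <- tibble::tibble(.rows = 1)
  for (cc in setdiff(names(x), "subject")) {
    out[[paste0("mean_", cc)]] <- vals[[cc]][vals$subject == "Mean"]
    out[[paste0("sdt_", cc)]] <- vals[[cc]][vals$subject == "SDT"]
  }
  rrow <- vals[vals$subject == "r", -1]
  prow <- vals[vals$subject == "p", -1]
  for (cc in names(rrow)[!is.na(unlist(rrow))]) {
    cnd <- sub(paste0("^", metrics[1], "_"), "", cc)
    out[[paste0("r_", cnd)]] <- rrow[[cc]]
    out[[paste0("p_", cnd)]] <- prow[[cc]]
  }
  out
}
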