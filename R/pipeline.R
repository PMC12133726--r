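# End-to-end orchestration: configuration, cohort preprocessing, offline
# report bundle (maps, curves, topographies, tables, cluster statistics),
# simulated-online monitor, and scalp topographies.

#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run. `synth` holds the
#' [synth_config()] arguments when `source = "synthetic"`; with
#' `source = "edf"`, `edf_dir` names a directory of `.edf` files with
#' event sidecars.
#'
#' @param source `"synthetic"` or `"edf"`.
#' @param synth Named list of [synth_config()] arguments (must include
#'   `seed`).
#' @param edf_dir Directory of EDF recordings (when `source = "edf"`).
#' @param fs_target Analysis sampling rate after resampling, Hz.
#' @param bandpass Band-pass edges, Hz.
#' @param epoch_window,baseline_window Epoch and baseline spans, s.
#' @param bands Named list with `theta`, `alpha`, `beta` ranges in Hz.
#' @param erd_window Imagery window for the ERD mean, s.
#' @param erd_channel,ami_electrode,tbr_channel Channels of interest.
#' @param n_perm,alpha_form,alpha_cluster Cluster-test settings.
#' @param stat_seed Seed for balancing and permutations.
#' @param topo_channels Channels for the electrode-space analysis
#'   (default: all generated channels).
#' @param output_dir Optional directory; when set, [run_offline()] writes
#'   TSV tables, a JSON statistics bundle and the resolved YAML config
#'   there.
#' @return A validated `run_config` list.
#' @export
run_config <- function(source = c("synthetic", "edf"),
                       synth = list(seed = 1),
                       edf_dir = NULL,
                       fs_target = 200,
                       bandpass = c(1, 30),
                       epoch_window = c(-2, 7),
                       baseline_window = c(-1, 0),
                       bands = list(theta = c(4, 8), alpha = c(8, 13),
                                    beta = c(13, 30)),
                       erd_window = c(1, 5),
                       erd_channel = "Cz",
                       ami_electrode = "F4",
                       tbr_channel = "Cz",
                       n_perm = 1000,
                       alpha_form = 0.05,
                       alpha_cluster = 0.05,
                       stat_seed = 1,
                       topo_channels = NULL,
                       output_dir = NULL) {
  source <- match.arg(source)
  if (source == "edf" && is.null(edf_dir))
    stop("edf_dir required when source = 'edf'")
  cfg <- list(source = source, synth = synth, edf_dir = edf_dir,
              fs_target = fs_target, bandpass = bandpass,
              epoch_window = epoch_window, baseline_window = baseline_window,
              bands = bands, erd_window = erd_window,
              erd_channel = erd_channel, ami_electrode = ami_electrode,
              tbr_channel = tbr_channel, n_perm = n_perm,
              alpha_form = alpha_form, alpha_cluster = alpha_cluster,
              stat_seed = stat_seed, topo_channels = topo_channels,
              output_dir = output_dir)
  if (source == "synthetic") {
    synth_cfg <- do.call(synth_config, cfg$synth)   # validates early
    chans <- synth_cfg$channel_labels
  } else chans <- NULL
  for (ch in c(erd_channel, ami_electrode, tbr_channel))
    if (!is.null(chans) && !ch %in% chans)
      stop("channel of interest not in montage: ", ch)
  stopifnot(bandpass[1] < bandpass[2],
            epoch_window[1] < epoch_window[2],
            erd_window[1] < erd_window[2])
  if (baseline_window[1] < epoch_window[1] ||
      baseline_window[2] > epoch_window[2])
    stop("baseline window outside the epoch window")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config()`
#'   arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("bandpass", "epoch_window", "baseline_window", "erd_window"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- as.numeric(vals[[nm]])
  if (!is.null(vals$bands))
    vals$bands <- lapply(vals$bands, as.numeric)
  do.call(run_config, vals)
}

#' Preprocess a cohort of recordings
#'
#' Applies the standard chain per recording: resample to `fs_target`,
#' zero-phase band-pass, epoch around the Select cues, baseline-correct.
#'
#' @param recordings List of [raw_recording()] objects.
#' @param config A [run_config()].
#' @return A list of `trial_epochs`, one per recording.
#' @export
preprocess_cohort <- function(recordings, config) {
  stopifnot(inherits(config, "run_config"))
  purrr::map(recordings, function(raw) {
    raw |>
      resample_recording(config$fs_target) |>
      bandpass_recording(config$bandpass[1], config$bandpass[2]) |>
      epoch_trials(config$epoch_window, config$baseline_window) |>
      baseline_correct()
  })
}

# cohort recordings from the configured source
.load_cohort <- function(config) {
  if (config$source == "synthetic") {
    generate_cohort(do.call(synth_config, config$synth))
  } else {
    paths <- sort(list.files(config$edf_dir, pattern = "\\.edf$",
                             full.names = TRUE))
    if (length(paths) == 0) stop("no EDF files in ", config$edf_dir)
    list(recordings = purrr::map(paths, read_edf), truth = NULL)
  }
}

#' Per-subject index battery over a cohort
#'
#' @param epochs_list List of `trial_epochs` (one per subject).
#' @param config A [run_config()].
#' @return Tibble with `subject`, `condition`, `erd`, `ami`, `tbr`.
#' @export
cohort_indices <- function(epochs_list, config) {
  purrr::imap(epochs_list, function(ep, i) {
    subject_indices(ep, subject = i, erd_channel = config$erd_channel,
                    ami_electrode = config$ami_electrode,
                    tbr_channel = config$tbr_channel,
                    seed = config$stat_seed,
                    tf_range = c(-1, config$erd_window[2]))
  }) |> purrr::list_rbind()
}

#' Per-subject condition-mean TBR series over a cohort
#'
#' @inheritParams cohort_indices
#' @param range Time span for the 1-s windows (default `c(0, 5)`).
#' @return Tibble with `subject`, `time`, `condition`, `tbr`.
#' @export
cohort_tbr_series <- function(epochs_list, config, range = c(0, 5)) {
  purrr::imap(epochs_list, function(ep, i) {
    s <- tbr_offline_series(ep, config$tbr_channel, range = range,
                            theta = config$bands$theta,
                            beta = config$bands$beta)
    s$subject <- i
    s
  }) |> purrr::list_rbind()
}

#' Offline end-to-end analysis
#'
#' Runs generate/load, preprocess, spectral analysis, indices and
#' statistics, returning a report bundle; deterministic under the
#' configured seeds. With `config$output_dir` set, tables are written as
#' TSV, all statistics as JSON, and the resolved configuration as YAML.
#'
#' The bundle contains: grand-average ERSP maps per condition and the
#' cluster-masked difference map; frequency-/time-domain energy curves;
#' per-electrode AMI/ERD topography values and the electrode-space
#' cluster test; per-subject index and TBR tables; the reference-style
#' summary tables; and paired-test/normality/per-second statistics.
#'
#' @param config A [run_config()].
#' @return A named list (report bundle), invisibly classed
#'   `offline_report`.
#' @export
run_offline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- .load_cohort(config)
  epochs_list <- preprocess_cohort(cohort$recordings, config)
  conds <- c("Attention", "Inattention")

  usable <- vapply(epochs_list,
                   \(ep) all(conds %in% ep$labels), logical(1))
  if (!all(usable))
    warning(sprintf("%d subject(s) lack a condition and are excluded from paired statistics",
                    sum(!usable)))

  tf_range <- c(-1, config$erd_window[2])
  maps <- purrr::map(epochs_list[usable], function(ep) {
    purrr::map(stats::setNames(conds, conds),
               \(cnd) ersp(ep, config$erd_channel, cnd, tf_range = tf_range))
  })
  grand <- purrr::map(stats::setNames(conds, conds), function(cnd) {
    ms <- purrr::map(maps, cnd)
    avg <- ms[[1]]
    avg$values <- Reduce(`+`, purrr::map(ms, "values")) / length(ms)
    avg$n_trials <- sum(vapply(ms, \(m) m$n_trials, numeric(1)))
    avg$condition <- paste0(cnd, " (grand average)")
    avg
  })
  clu_tf <- if (sum(usable) >= 2)
    cluster_perm_tf(purrr::map(maps, "Attention"),
                    purrr::map(maps, "Inattention"),
                    n_perm = config$n_perm, alpha_form = config$alpha_form,
                    alpha_cluster = config$alpha_cluster,
                    seed = config$stat_seed) else NULL

  curves <- list(
    frequency = energy_curve(purrr::map(maps, "Attention"), "over_time",
                             window = config$erd_window) |>
      dplyr::mutate(condition = "Attention") |>
      dplyr::bind_rows(
        energy_curve(purrr::map(maps, "Inattention"), "over_time",
                     window = config$erd_window) |>
          dplyr::mutate(condition = "Inattention")),
    time = energy_curve(purrr::map(maps, "Attention"), "over_frequency",
                        band = config$bands$alpha) |>
      dplyr::mutate(condition = "Attention") |>
      dplyr::bind_rows(
        energy_curve(purrr::map(maps, "Inattention"), "over_frequency",
                     band = config$bands$alpha) |>
          dplyr::mutate(condition = "Inattention"))
  )

  indices <- cohort_indices(epochs_list[usable], config)
  series <- cohort_tbr_series(epochs_list[usable], config)

  topo_chans <- config$topo_channels %||% epochs_list[[1]]$channel_labels
  topo <- .electrode_values(epochs_list[usable], topo_chans, config)
  clu_ch <- if (sum(usable) >= 2) {
    erd_w <- topo$per_subject |>
      tidyr::pivot_wider(id_cols = c("subject", "condition"),
                         names_from = "electrode", values_from = "erd")
    a <- as.matrix(erd_w[erd_w$condition == "Attention", topo_chans])
    b <- as.matrix(erd_w[erd_w$condition == "Inattention", topo_chans])
    cluster_perm_channels(a, b, n_perm = config$n_perm,
                          alpha_form = config$alpha_form,
                          alpha_cluster = config$alpha_cluster,
                          seed = config$stat_seed)
  } else NULL

  tests <- .paired_battery(indices, series)
  tables <- list(
    erd_ami = build_summary_table(indices, c("erd", "ami")),
    erd_tbr = build_summary_table(indices, c("erd", "tbr"))
  )

  report <- list(
    config = config, truth = cohort$truth,
    ersp = grand, cluster_tf = clu_tf,
    energy_curves = curves,
    indices = indices, tbr_series = series,
    topography = topo$mean, cluster_channels = clu_ch,
    tables = tables, tests = tests
  )
  class(report) <- "offline_report"
  if (!is.null(config$output_dir)) .write_report(report, config$output_dir)
  invisible(report)
}

# per-subject, per-electrode AMI and ERD values plus their cohort means
.electrode_values <- function(epochs_list, channels, config) {
  per <- purrr::imap(epochs_list, function(ep, i) {
    purrr::map(channels, function(ch) {
      am <- subject_ami(ep, ch, seed = config$stat_seed)$ami
      purrr::map(c("Attention", "Inattention"), function(cnd) {
        m <- ersp(ep, ch, cnd, tf_range = c(-1, config$erd_window[2]))
        tibble::tibble(subject = i, electrode = ch, condition = cnd,
                       erd = erd(m, config$bands$alpha, config$erd_window),
                       ami = am)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  mean_tbl <- per |>
    dplyr::group_by(.data$electrode, .data$condition) |>
    dplyr::summarise(erd = mean(.data$erd), ami = mean(.data$ami),
                     .groups = "drop")
  list(per_subject = per, mean = mean_tbl)
}

# paired tests, normality checks and the per-second Bonferroni table
.paired_battery <- function(indices, series) {
  wide <- indices |>
    tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                       values_from = c("erd", "tbr"))
  out <- list()
  if (nrow(wide) >= 2) {
    out$erd_paired <- paired_t(wide$erd_Attention, wide$erd_Inattention)
    out$tbr_paired <- paired_t(wide$tbr_Attention, wide$tbr_Inattention)
    if (nrow(wide) >= 3)
      out$normality <- dplyr::bind_rows(
        dplyr::mutate(normality_check(wide$erd_Attention - wide$erd_Inattention),
                      metric = "erd_diff"),
        dplyr::mutate(normality_check(wide$tbr_Attention - wide$tbr_Inattention),
                      metric = "tbr_diff"))
    out$per_second <- bonferroni_per_second(series)
  }
  out
}

.write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(report$indices, "indices.tsv")
  wt(report$tbr_series, "tbr_series.tsv")
  wt(report$topography, "topography.tsv")
  wt(as.data.frame(report$tables$erd_ami), "table_erd_ami.tsv")
  wt(as.data.frame(report$tables$erd_tbr), "table_erd_tbr.tsv")
  for (nm in names(report$ersp)) {
    m <- report$ersp[[nm]]
    wt(tidy(m), paste0("ersp_", sub(" .*", "", nm), ".tsv"))
  }
  stats_out <- list(
    tests = lapply(report$tests, \(x) if (is.data.frame(x)) as.list(x) else x),
    cluster_tf = if (!is.null(report$cluster_tf))
      .cluster_json(report$cluster_tf),
    cluster_channels = if (!is.null(report$cluster_channels))
      .cluster_json(report$cluster_channels)
  )
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$output_dir <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config_resolved.yaml"))
  invisible(dir)
}

.cluster_json <- function(res) {
  list(space = res$space, n_perm = res$n_perm, seed = res$seed,
       alpha_form = res$alpha_form, alpha_cluster = res$alpha_cluster,
       clusters = as.list(res$clusters),
       members = res$members,
       null_quantile_95 = unname(stats::quantile(res$null, 0.95)))
}

#' Simulated-online per-second analysis
#'
#' Replays each subject's trials as 1-s buffers through [tbr_online()]
#' (no look-ahead), averages per condition within subject, then runs
#' per-second paired t-tests with Bonferroni correction across subjects.
#' With a single subject the group tests are skipped with a notice.
#'
#' @param config A [run_config()].
#' @param epochs_list Optional pre-computed list of `trial_epochs`
#'   (skips generation/preprocessing, e.g. to replay the offline cohort).
#' @param range Replay span in seconds (default `c(0, 5)`: stamps 1-5 s).
#' @return A list: `series` (per subject/condition/second TBR),
#'   `mean_curves` (condition means), `tests` (per-second table or
#'   `NULL`).
#' @export
run_online <- function(config, epochs_list = NULL, range = c(0, 5)) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(epochs_list)) {
    cohort <- .load_cohort(config)
    epochs_list <- preprocess_cohort(cohort$recordings, config)
  }
  series <- purrr::imap(epochs_list, function(ep, i) {
    per_trial <- purrr::map(seq_along(ep$labels), function(k) {
      buf <- epoch_buffers(ep, k, config$tbr_channel, range)
      s <- tbr_online(buf, ep$fs, t0 = range[1],
                      theta = config$bands$theta, beta = config$bands$beta)
      s$trial <- k
      s$condition <- ep$labels[k]
      s
    }) |> purrr::list_rbind()
    per_trial |>
      dplyr::group_by(.data$time, .data$condition) |>
      dplyr::summarise(tbr = mean(.data$tbr), .groups = "drop") |>
      dplyr::mutate(subject = i)
  }) |> purrr::list_rbind()
  mean_curves <- series |>
    dplyr::group_by(.data$time, .data$condition) |>
    dplyr::summarise(tbr = mean(.data$tbr), .groups = "drop")
  tests <- if (length(unique(series$subject)) >= 2 &&
                 all(c("Attention", "Inattention") %in% series$condition)) {
    complete <- series |>
      dplyr::count(.data$subject) |>
      dplyr::filter(.data$n == max(.data$n)) |>
      dplyr::pull(.data$subject)
    bonferroni_per_second(series[series$subject %in% complete, ])
  } else {
    message("fewer than 2 subjects with both conditions: per-second t-tests skipped")
    NULL
  }
  list(series = series, mean_curves = mean_curves, tests = tests)
}

#' Scalp topography of per-electrode values
#'
#' Attaches scalars to the flattened 10/20 coordinates and interpolates
#' them onto a rendering grid (inverse-distance weighting inside the head
#' outline). The raw per-electrode values are always kept alongside the
#' grid.
#'
#' @param values Named numeric vector, or a tibble with `electrode` and
#'   `value` columns.
#' @param montage Montage tibble (default [montage_1020()]).
#' @param grid_n Grid resolution per axis.
#' @return A `topo_map`: `values` tibble (electrode, x, y, value) and
#'   `grid` tibble (x, y, value) for rendering.
#' @export
topography <- function(values, montage = montage_1020(), grid_n = 60) {
  if (is.numeric(values) && !is.null(names(values)))
    values <- tibble::tibble(electrode = names(values), value = unname(values))
  stopifnot(all(c("electrode", "value") %in% names(values)))
  miss <- setdiff(values$electrode, montage$channel)
  if (length(miss) > 0)
    stop("no montage coordinate for electrode(s): ",
         paste(miss, collapse = ", "))
  pts <- dplyr::inner_join(values, montage,
                           by = c(electrode = "channel"))
  ax <- seq(-1.1, 1.1, length.out = grid_n)
  grid <- expand.grid(x = ax, y = ax)
  d2 <- outer(grid$x, pts$x, "-")^2 + outer(grid$y, pts$y, "-")^2
  w <- 1 / (d2 + 1e-6)
  z <- as.vector(w %*% pts$value / rowSums(w))
  z[grid$x^2 + grid$y^2 > 1.1^2] <- NA
  structure(
    list(values = pts, grid = tibble::tibble(x = grid$x, y = grid$y,
                                             value = z)),
    class = "topo_map"
  )
}
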