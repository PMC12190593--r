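# End-to-end orchestration: configuration -> recordings -> long-format
# feature table -> networks -> comparisons -> report. Stage outputs are
# files, so every stage can be re-run and inspected independently; a
# run-manifest records the config hash, seed and per-stage timings.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "pacnet_out",
    bands = list(delta = c(0.5, 4), gamma = c(30, 50)),
    n_bins = 18L,
    welch = list(segment_s = 2, overlap = 0.5, window_a = 0.46, scale = 1),
    network = list(thresholds = list(delta = 0.32, gamma = 0.56),
                   density_range = c(0.05, 0.45), absolute = FALSE),
    alpha = 0.05,
    p_adjust = "none",
    reference_channels = NULL,
    synthetic = NULL,
    inputs = NULL,
    comparisons = NULL
  )
}

merge_known <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(defaults, user)
}

#' Validate and normalize a study configuration
#'
#' Accepts a YAML/JSON path or a named list, fills defaults, and rejects
#' unknown keys. The configuration drives [run_study()] and the command-line
#' interface.
#'
#' Top-level keys: `seed`, `out_dir`, `bands` (named list of `c(f_lo, f_hi)`),
#' `n_bins`, `welch` (`segment_s`, `overlap`, `window_a`, `scale`),
#' `network` (`thresholds` per band, `density_range`, `absolute`), `alpha`,
#' `p_adjust`, `reference_channels`, `synthetic` (arguments of
#' [generator_spec()] plus `n_subjects_per_group`, `groups`, `states`),
#' `inputs` (list of `path`, `subject_id`, `group`, `state`, `fs`),
#' `comparisons` (list of `type` = `"states"`/`"groups"`, `feature`, `band`,
#' `a`, `b`; NULL auto-generates the study's standard contrasts).
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A validated `study_config` list.
#' @export
study_config <- function(config = list()) {
  if (inherits(config, "study_config")) return(config)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$bands) && !length(config$bands)) {
    stop("config must define at least one band", call. = FALSE)
  }
  cfg <- merge_known(default_config(), config, "top level")
  cfg$welch <- merge_known(default_config()$welch,
                           as.list(cfg$welch), "welch")
  net_defaults <- default_config()$network
  cfg$network <- merge_known(net_defaults, as.list(cfg$network), "network")
  for (b in names(cfg$bands)) {
    e <- as.numeric(cfg$bands[[b]])
    if (length(e) != 2L || !all(is.finite(e)) || e[1] <= 0 || e[2] <= e[1]) {
      stop("band '", b, "' must be c(f_lo, f_hi) with 0 < f_lo < f_hi",
           call. = FALSE)
    }
  }
  if (!length(cfg$bands)) stop("config must define at least one band", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  if (cfg$welch$overlap < 0 || cfg$welch$overlap >= 1) {
    stop("welch overlap must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(cfg$synthetic)) {
    syn <- as.list(cfg$synthetic)
    extra <- list(n_subjects_per_group = syn$n_subjects_per_group %||% 12L,
                  groups = syn$groups %||% c("wm", "tdcs", "sham"),
                  states = syn$states %||% c("pre_rest", "task", "post_rest"))
    syn$n_subjects_per_group <- NULL; syn$groups <- NULL; syn$states <- NULL
    spec_args <- merge_known(formals_defaults(generator_spec), syn, "synthetic")
    if (is.null(spec_args$seed)) spec_args$seed <- cfg$seed
    cfg$synthetic <- c(list(spec = do.call(generator_spec, spec_args)), extra)
  }
  structure(cfg, class = c("study_config", "list"))
}

formals_defaults <- function(fn) {
  f <- formals(fn)
  lapply(f[!vapply(f, is.symbol, TRUE)], eval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_bands <- function(cfg) {
  lapply(names(cfg$bands), function(b) band(b, cfg$bands[[b]][1], cfg$bands[[b]][2]))
}

#' Extract the full feature table from a set of recordings
#'
#' For every recording: per-channel modulation index (delta phase, gamma
#' amplitude, or the first two configured bands), per-channel band power in
#' dB for each configured band, and per-channel degree and clustering from
#' the band-filtered correlation network binarized at the configured
#' threshold. Results are stacked into the long study table.
#'
#' @param recordings List of `eeg_recording` objects.
#' @param config A [study_config()] (or anything coercible).
#' @param include Which feature families to compute; any subset of
#'   `c("mi", "band_power", "network")`.
#' @return A tibble with columns `subject_id`, `group`, `state`, `channel`,
#'   `feature_name`, `band`, `value`; keys are unique and values finite.
#' @export
extract_features <- function(recordings, config = study_config(),
                             include = c("mi", "band_power", "network")) {
  cfg <- study_config(config)
  include <- match.arg(include, several.ok = TRUE)
  bands <- config_bands(cfg)
  if (length(bands) < 2L) stop("need two bands (phase and amplitude)", call. = FALSE)
  phase_band <- bands[[1L]]; amp_band <- bands[[2L]]
  table <- purrr::map_dfr(recordings, function(rec) {
    meta <- tibble::tibble(subject_id = rec$subject_id, group = rec$group,
                           state = rec$state)
    parts <- list()
    if ("mi" %in% include) {
      parts$mi <- channel_mi(rec, phase_band, amp_band, n_bins = cfg$n_bins) |>
        dplyr::select("channel", "feature_name", "band", "value")
    }
    if ("band_power" %in% include) {
      parts$pow <- band_power_table(rec, bands,
                                    segment_length = round(cfg$welch$segment_s * rec$fs),
                                    overlap = cfg$welch$overlap,
                                    window_a = cfg$welch$window_a,
                                    scale = cfg$welch$scale)
    }
    if ("network" %in% include) {
      parts$nets <- purrr::map_dfr(bands, function(b) {
        th <- cfg$network$thresholds[[b$name]]
        if (is.null(th)) return(tibble::tibble())
        filt <- bandpass(rec, b)
        net <- binarize(correlation_matrix(filt), th, cfg$network$absolute)
        dplyr::filter(network_features(net), .data$channel != "whole_brain")
      })
    }
    tidyr::crossing(meta, dplyr::bind_rows(parts))
  })
  dup <- table |>
    dplyr::count(.data$subject_id, .data$state, .data$channel,
                 .data$feature_name, .data$band) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) stop("duplicate feature-table keys", call. = FALSE)
  if (!all(is.finite(table$value))) stop("non-finite feature values", call. = FALSE)
  table
}

default_comparisons <- function(table) {
  feats <- dplyr::distinct(table, .data$feature_name, .data$band)
  out <- list()
  states <- unique(table$state)
  if (all(c("pre_rest", "task") %in% states)) {
    out <- c(out, purrr::pmap(feats, function(feature_name, band) {
      list(type = "states", feature = feature_name, band = band,
           a = "pre_rest", b = "task")
    }))
  }
  if (all(c("sham", "tdcs") %in% table$group) && "task" %in% states) {
    out <- c(out, purrr::pmap(feats, function(feature_name, band) {
      list(type = "groups", feature = feature_name, band = band,
           a = "sham", b = "tdcs")
    }))
  }
  out
}

run_comparisons <- function(table, cfg) {
  specs <- cfg$comparisons %||% default_comparisons(table)
  purrr::map_dfr(specs, function(cmp) {
    if (cmp$type == "states") {
      compare_states(table, cmp$feature, cmp$band, c(cmp$a, cmp$b),
                     alpha = cfg$alpha, p_adjust = cfg$p_adjust)
    } else if (cmp$type == "groups") {
      compare_groups(table, cmp$feature, cmp$band, c(cmp$a, cmp$b),
                     state = cmp$state %||% "task",
                     alpha = cfg$alpha, p_adjust = cfg$p_adjust)
    } else {
      stop("unknown comparison type '", cmp$type, "'", call. = FALSE)
    }
  })
}

stage_log <- function(stage, t0) {
  message(sprintf("[pacnet] %-12s %7.2f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run a full study from a configuration
#'
#' Ingests recordings (from the `synthetic` generator block or from the
#' `inputs` file list), extracts the feature table, builds per-band network
#' edge lists, runs the configured comparisons and writes everything under
#' `out_dir`: `features.csv`, `networks/`, `comparisons.csv`, `report.txt`,
#' `run_manifest.json` (and `manifest.csv` for synthetic studies). The run
#' is deterministic given the config and seed. On any stage failure the
#' partially written output directory is removed.
#'
#' @param config A [study_config()], list, or YAML path.
#' @param out_dir Optional override of the config's `out_dir`.
#' @return Invisibly, a list with `features`, `comparisons`, `out_dir`.
#' @export
run_study <- function(config, out_dir = NULL) {
  cfg <- study_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  created <- !dir.exists(cfg$out_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- as.numeric(Sys.time())
  timings <- list()

  tryCatch({
    set.seed(cfg$seed)
    t0 <- as.numeric(Sys.time())
    if (!is.null(cfg$synthetic)) {
      study <- gen_study(cfg$synthetic$spec,
                         n_subjects_per_group = cfg$synthetic$n_subjects_per_group,
                         groups = cfg$synthetic$groups,
                         states = cfg$synthetic$states)
      recordings <- study$recordings
      readr::write_csv(study$manifest, file.path(cfg$out_dir, "manifest.csv"))
    } else if (!is.null(cfg$inputs)) {
      recordings <- purrr::map(cfg$inputs, function(inp) {
        rec <- read_recording(inp$path, fs = inp$fs, subject_id = inp$subject_id,
                              group = inp$group, state = inp$state)
        if (!is.null(cfg$reference_channels)) {
          rec <- rereference(rec, cfg$reference_channels)
        }
        rec
      })
    } else {
      stop("config needs either a 'synthetic' block or 'inputs'", call. = FALSE)
    }
    timings$ingest <- as.numeric(Sys.time()) - t0
    stage_log("ingest", t0)

    t0 <- as.numeric(Sys.time())
    features <- extract_features(recordings, cfg)
    write_feature_table(features, file.path(cfg$out_dir, "features.csv"))
    timings$features <- as.numeric(Sys.time()) - t0
    stage_log("features", t0)

    t0 <- as.numeric(Sys.time())
    net_dir <- file.path(cfg$out_dir, "networks")
    dir.create(net_dir, showWarnings = FALSE)
    bands <- config_bands(cfg)
    for (rec in recordings) {
      for (b in bands) {
        th <- cfg$network$thresholds[[b$name]]
        if (is.null(th)) next
        net <- binarize(correlation_matrix(bandpass(rec, b)), th,
                        cfg$network$absolute)
        edge_list(net, file.path(net_dir, sprintf("%s_%s_%s_edges.csv",
                                                  rec$subject_id, rec$state,
                                                  b$name)))
      }
    }
    timings$networks <- as.numeric(Sys.time()) - t0
    stage_log("networks", t0)

    t0 <- as.numeric(Sys.time())
    comparisons <- run_comparisons(features, cfg)
    readr::write_csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"))
    report <- c(
      sprintf("pacnet study report (seed %d, alpha %g)", cfg$seed, cfg$alpha),
      "",
      vapply(seq_len(nrow(comparisons[comparisons$level == "whole_brain_mean", ])),
             function(i) {
               format_comparison(comparisons[comparisons$level == "whole_brain_mean", ][i, ])
             }, "")
    )
    writeLines(report, file.path(cfg$out_dir, "report.txt"))
    timings$compare <- as.numeric(Sys.time()) - t0
    stage_log("compare", t0)

    manifest <- list(
      config_hash = rlang::hash(unclass(cfg)),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("pacnet")),
      n_recordings = length(recordings),
      timings_s = lapply(timings, round, 2),
      total_s = round(as.numeric(Sys.time()) - t_start, 2)
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(features = features, comparisons = comparisons,
                   out_dir = cfg$out_dir))
  }, error = function(e) {
    if (created) unlink(cfg$out_dir, recursive = TRUE)
    stop(e)
  })
}
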