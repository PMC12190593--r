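# Paired nonparametric comparisons over the long-format study table.
#
# The signed-rank statistic's exact null distribution is built by dynamic
# programming over the (mid-)ranks - the generating polynomial
# prod_i (1 + x^{2 r_i}) / 2 - which stays exact under tied absolute
# differences, where the tabulated signrank distribution does not apply.
# Above 25 pairs the normal approximation with tie and continuity
# corrections is used. Zero differences are dropped, as in the classical
# Wilcoxon procedure.

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of symmetric location difference between paired samples.
#' Zero differences are dropped before ranking. The exact distribution is
#' used for up to 25 non-zero pairs (valid under tied ranks, via dynamic
#' programming over the doubled mid-ranks); above that a normal
#' approximation with tie correction and 0.5 continuity correction is
#' applied.
#'
#' @param a,b Equal-length numeric vectors of paired observations; at least 5
#'   non-zero differences are recommended for a meaningful test.
#' @return List with `statistic` (W, the positive-rank sum), `p_value`
#'   (two-sided), `n_pairs` (non-zero differences used), `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5)) # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_pairs = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of 2W by convolution over doubled mid-ranks
    probs <- 1
    for (ri in as.integer(round(2 * r))) {
      probs <- 0.5 * (c(probs, numeric(ri)) + c(numeric(ri), probs))
    }
    w2 <- as.integer(round(2 * W))
    p <- min(1, 2 * min(sum(probs[seq_len(w2 + 1L)]),
                        sum(probs[(w2 + 1L):length(probs)])))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = W, p_value = p, n_pairs = n, method = method)
}

comparison_row <- function(feature, band, level, channel, cond_a, cond_b,
                           va, vb, alpha, test, paired = TRUE) {
  res <- if (paired) {
    wilcoxon_signed_rank(va, vb)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = NULL))
    p <- wt$p.value
    if (is.na(p)) p <- 1          # fully degenerate samples carry no evidence
    list(statistic = unname(wt$statistic), p_value = p,
         n_pairs = min(length(va), length(vb)), method = "rank_sum")
  }
  tibble::tibble(
    feature_name = feature, band = band, level = level, channel = channel,
    condition_a = cond_a, condition_b = cond_b, test = test,
    n_pairs = res$n_pairs, statistic = res$statistic, p_value = res$p_value,
    mean_a = mean(va), sd_a = stats::sd(va),
    mean_b = mean(vb), sd_b = stats::sd(vb),
    significant = res$p_value < alpha
  )
}

#' Compare two states within subjects
#'
#' For a chosen feature and band, runs a paired Wilcoxon signed-rank test per
#' channel (pairs are subjects) plus a whole-brain-mean comparison in which
#' each subject contributes the mean over channels. Subjects missing either
#' state are excluded with a warning. Summaries are reported as mean and
#' sample standard deviation per condition.
#'
#' @param table Long-format study table (see [extract_features()]).
#' @param feature Feature name, e.g. `"mi"`, `"band_power_db"`, `"degree"`.
#' @param band Band label, e.g. `"delta-gamma"`, `"delta"`, `"gamma"`.
#' @param states Length-2 character: condition A and condition B.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust Optional multiple-testing correction for the per-channel
#'   p-values (any method of [stats::p.adjust()], e.g. `"BH"`). Default
#'   `"none"`: the study reports raw p-values across nodes.
#' @return A tibble, one row per channel plus one `whole_brain_mean` row.
#' @export
compare_states <- function(table, feature, band, states = c("pre_rest", "task"),
                           alpha = 0.05, p_adjust = "none") {
  stopifnot(length(states) == 2L)
  df <- dplyr::filter(table, .data$feature_name == feature, .data$band == !!band,
                      .data$state %in% states, .data$channel != "whole_brain")
  if (!nrow(df)) stop("no rows for feature '", feature, "' band '", band, "'",
                      call. = FALSE)
  complete <- df |>
    dplyr::distinct(.data$subject_id, .data$state) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == 2L) |>
    dplyr::pull(.data$subject_id)
  dropped <- setdiff(unique(df$subject_id), complete)
  if (length(dropped)) {
    warning("excluding subjects missing a state: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(complete) < 2L) {
    stop("need at least 2 subjects with both states", call. = FALSE)
  }
  df <- dplyr::filter(df, .data$subject_id %in% complete)

  wide <- df |>
    dplyr::select("subject_id", "channel", "state", "value") |>
    tidyr::pivot_wider(names_from = "state", values_from = "value") |>
    dplyr::arrange(.data$subject_id)
  channels <- unique(df$channel)
  per_channel <- purrr::map_dfr(channels, function(ch) {
    sub <- dplyr::filter(wide, .data$channel == ch)
    comparison_row(feature, band, "per_channel", ch, states[1], states[2],
                   sub[[states[1]]], sub[[states[2]]], alpha, "signed_rank")
  })
  if (p_adjust != "none") {
    per_channel$p_value <- stats::p.adjust(per_channel$p_value, p_adjust)
    per_channel$significant <- per_channel$p_value < alpha
  }
  means <- wide |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(states), mean), .groups = "drop")
  whole <- comparison_row(feature, band, "whole_brain_mean", "whole_brain",
                          states[1], states[2],
                          means[[states[1]]], means[[states[2]]],
                          alpha, "signed_rank")
  dplyr::bind_rows(per_channel, whole)
}

#' Compare two groups of subjects
#'
#' Mirrors the study's group contrast on one state (default the task state).
#' The whole-brain contrast pairs the per-channel group means across
#' channels and applies the signed-rank test over those channel pairs; this
#' pairing-by-channel of two independent groups is flagged in the `test`
#' column (`"signed_rank_channels"`). Per-channel subject-level contrasts
#' are additionally reported with an unpaired rank-sum test
#' (`test = "rank_sum"`). The reported whole-brain means and standard
#' deviations are over subjects' channel means.
#'
#' @param table Long-format study table.
#' @param feature,band As in [compare_states()].
#' @param groups Length-2 character: group A and group B (e.g.
#'   `c("sham", "tdcs")`).
#' @param state State to compare within, default `"task"`.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust Per-channel p-value correction method, default `"none"`.
#' @return A tibble, one rank-sum row per channel plus one paired-by-channel
#'   `whole_brain_mean` row.
#' @export
compare_groups <- function(table, feature, band, groups = c("sham", "tdcs"),
                           state = "task", alpha = 0.05, p_adjust = "none") {
  stopifnot(length(groups) == 2L)
  df <- dplyr::filter(table, .data$feature_name == feature, .data$band == !!band,
                      .data$group %in% groups, .data$state == !!state,
                      .data$channel != "whole_brain")
  if (!nrow(df)) stop("no rows for feature '", feature, "' band '", band, "'",
                      call. = FALSE)
  if (!all(groups %in% df$group)) stop("both groups must be present", call. = FALSE)
  ch_a <- sort(unique(df$channel[df$group == groups[1]]))
  ch_b <- sort(unique(df$channel[df$group == groups[2]]))
  if (!identical(ch_a, ch_b)) {
    stop("channel sets differ between groups", call. = FALSE)
  }

  per_channel <- purrr::map_dfr(ch_a, function(ch) {
    sub <- dplyr::filter(df, .data$channel == ch)
    comparison_row(feature, band, "per_channel", ch, groups[1], groups[2],
                   sub$value[sub$group == groups[1]],
                   sub$value[sub$group == groups[2]],
                   alpha, "rank_sum", paired = FALSE)
  })
  if (p_adjust != "none") {
    per_channel$p_value <- stats::p.adjust(per_channel$p_value, p_adjust)
    per_channel$significant <- per_channel$p_value < alpha
  }

  ch_means <- df |>
    dplyr::group_by(.data$group, .data$channel) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "value") |>
    dplyr::arrange(.data$channel)
  subj_means <- df |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  whole <- comparison_row(feature, band, "whole_brain_mean", "whole_brain",
                          groups[1], groups[2],
                          ch_means[[groups[1]]], ch_means[[groups[2]]],
                          alpha, "signed_rank_channels")
  # report subject-level dispersion, not channel-mean dispersion
  whole$mean_a <- mean(subj_means$value[subj_means$group == groups[1]])
  whole$sd_a <- stats::sd(subj_means$value[subj_means$group == groups[1]])
  whole$mean_b <- mean(subj_means$value[subj_means$group == groups[2]])
  whole$sd_b <- stats::sd(subj_means$value[subj_means$group == groups[2]])
  dplyr::bind_rows(per_channel, whole)
}

#' Format a comparison row in the study's reporting style
#'
#' @param row One row of a comparison tibble.
#' @return A string like `"(a: m ± s; b: m ± s; p = ...)"`.
#' @export
format_comparison <- function(row) {
  sprintf("%s [%s, %s]: (%s: %.4g ± %.4g; %s: %.4g ± %.4g; p = %.3g)%s",
          row$feature_name, row$band, row$channel,
          row$condition_a, row$mean_a, row$sd_a,
          row$condition_b, row$mean_b, row$sd_b,
          row$p_value, if (isTRUE(row$significant)) " *" else "")
}
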