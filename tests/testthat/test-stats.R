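test_that("five uniformly positive differences give the textbook p", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$method, "exact")
})

test_that("identical samples give p = 1 with a warning", {
  expect_warning(res <- wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$n_pairs, 0L)
})

test_that("exact p-values match full sign-pattern enumeration for n <= 10", {
  set.seed(51)
  for (n in 5:10) {
    for (rep in 1:5) {
      a <- rnorm(n); b <- rnorm(n)
      res <- wilcoxon_signed_rank(a, b)
      expect_equal(res$p_value, enum_signed_rank_p(a - b), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
  # tied absolute differences stay exact (mid-rank enumeration)
  for (rep in 1:10) {
    d <- sample(c(-3, -2, -1, 1, 1, 2, 2, 3, 4), 8)
    res <- wilcoxon_signed_rank(d, numeric(8))
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("exact branch agrees with the reference implementation", {
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  set.seed(53)
  a <- round(rnorm(30), 1); b <- round(rnorm(30), 1)
  keep <- a != b
  res <- wilcoxon_signed_rank(a[keep], b[keep])
  expect_equal(res$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(a[keep], b[keep], paired = TRUE,
                                      correct = TRUE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

# small deterministic feature table: 6 subjects x 2 states x 3 channels
toy_table <- function(shift = 0, seed = 54) {
  set.seed(seed)
  tidyr::crossing(subject_id = sprintf("s%d", 1:6), group = "wm",
                  state = c("pre_rest", "task"),
                  channel = c("C1", "C2", "C3"),
                  feature_name = "mi", band = "delta-gamma") |>
    dplyr::mutate(value = rnorm(dplyr::n(), sd = 0.1) +
                    ifelse(state == "task", shift, 0))
}

test_that("state comparison detects a known shift and reports summaries", {
  tab <- toy_table(shift = 1)
  res <- compare_states(tab, "mi", "delta-gamma")
  expect_equal(nrow(res), 4)           # 3 channels + whole-brain mean
  wb <- dplyr::filter(res, level == "whole_brain_mean")
  expect_lt(wb$p_value, 0.05)
  expect_true(wb$significant)
  expect_gt(wb$mean_b, wb$mean_a)
  # summaries reproduce arithmetic on the table exactly
  task_means <- tab |>
    dplyr::filter(state == "task") |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = mean(value))
  expect_equal(wb$mean_b, mean(task_means$m))
  expect_equal(wb$sd_b, sd(task_means$m))
  txt <- format_comparison(wb)
  expect_match(txt, "pre_rest")
  expect_match(txt, "\\*$")
})

test_that("state comparison enforces pairing preconditions", {
  tab <- toy_table()
  expect_error(compare_states(dplyr::filter(tab, subject_id == "s1"),
                              "mi", "delta-gamma"), "at least 2")
  incomplete <- dplyr::filter(tab, !(subject_id == "s2" & state == "task"))
  expect_warning(res <- compare_states(incomplete, "mi", "delta-gamma"), "s2")
  expect_equal(unique(res$n_pairs), 5L)
  expect_error(compare_states(tab, "nosuch", "delta-gamma"), "no rows")
})

test_that("group comparison pairs channels and labels its tests", {
  set.seed(55)
  tab <- tidyr::crossing(subject_id = sprintf("g%d", 1:12),
                         state = "task", channel = c("C1", "C2", "C3", "C4", "C5"),
                         feature_name = "band_power_db", band = "gamma") |>
    dplyr::mutate(group = ifelse(subject_id %in% sprintf("g%d", 1:6),
                                 "sham", "tdcs"),
                  value = rnorm(dplyr::n()) + ifelse(group == "tdcs", 2, 0))
  res <- compare_groups(tab, "band_power_db", "gamma")
  expect_equal(nrow(res), 6)
  wb <- dplyr::filter(res, level == "whole_brain_mean")
  expect_equal(wb$test, "signed_rank_channels")
  expect_equal(wb$n_pairs, 5L)         # pairs are channels
  expect_gt(wb$mean_b, wb$mean_a)
  expect_true(all(res$test[res$level == "per_channel"] == "rank_sum"))

  disjoint <- dplyr::mutate(tab, channel = ifelse(group == "sham",
                                                  paste0("L", channel), channel))
  expect_error(compare_groups(disjoint, "band_power_db", "gamma"), "differ")
})

test_that("per-channel p-values can be BH adjusted", {
  tab <- toy_table(shift = 0.05)
  raw <- compare_states(tab, "mi", "delta-gamma")
  adj <- compare_states(tab, "mi", "delta-gamma", p_adjust = "BH")
  pc_raw <- raw$p_value[raw$level == "per_channel"]
  pc_adj <- adj$p_value[adj$level == "per_channel"]
  expect_equal(pc_adj, p.adjust(pc_raw, "BH"))
})
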