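test_that("generator spec validates its fields", {
  expect_error(generator_spec(chi = 1.2), "chi")
  expect_error(generator_spec(f_amp = 1), "exceed")
  expect_error(generator_spec(f_amp = 600), "Nyquist")
  expect_error(generator_spec(a_gamma = -1), "non-negative")
  expect_error(generator_spec(mixing = 1), "mixing")
  expect_error(generator_spec(tdcs_chi_mult = 0), "positive")
})

test_that("uncoupled noiseless channels have a flat gamma envelope", {
  spec <- reduced_spec(n_channels = 1, chi = 0, noise_scale = 0,
                       freq_drift = 0, seed = 61)
  x <- gen_coupled_channel(spec)$signal
  amp <- analytic_signal(bandpass(make_rec(rbind(x), "A"), gamma_band())$data[1, ])$amplitude
  int <- 2000:3000
  expect_lt(sd(amp[int]) / mean(amp[int]), 0.01)
})

test_that("fully coupled noiseless channels null the envelope at the trough", {
  # chi = 1, periodic modulator: envelope = (1 + sin(phi))/2 dips to ~0
  spec <- reduced_spec(n_channels = 1, chi = 1, noise_scale = 0,
                       freq_drift = 0, seed = 62)
  ch <- gen_coupled_channel(spec)
  t <- seq.int(0, length(ch$signal) - 1) / spec$fs
  slow_phase <- (2 * pi * spec$f_phase * t + ch$phi0 + pi) %% (2 * pi) - pi
  amp <- analytic_signal(bandpass(make_rec(rbind(ch$signal), "A"),
                                  gamma_band())$data[1, ])$amplitude
  int <- 2000:3000
  trough <- int[abs(slow_phase[int] + pi / 2) < 0.1]
  peak <- int[abs(slow_phase[int] - pi / 2) < 0.1]
  expect_lt(mean(amp[trough]), 0.05 * mean(amp[peak]))
})

test_that("identical seeds reproduce identical signals and studies", {
  spec <- reduced_spec(seed = 63)
  expect_identical(gen_coupled_channel(spec)$signal,
                   gen_coupled_channel(spec)$signal)
  s1 <- gen_study(spec, 2, groups = "wm", states = c("pre_rest", "task"))
  s2 <- gen_study(spec, 2, groups = "wm", states = c("pre_rest", "task"))
  expect_identical(s1$recordings[[3]]$data, s2$recordings[[3]]$data)
  expect_identical(s1$manifest, s2$manifest)
})

test_that("study bookkeeping matches the requested design", {
  spec <- reduced_spec(duration_s = 10, seed = 64)
  st <- gen_study(spec, 2, groups = c("sham", "tdcs"),
                  states = c("pre_rest", "task"))
  expect_length(st$recordings, 2 * 2 * 2)
  expect_equal(nrow(st$manifest), 2 * 2 * 2 * 4)
  rec <- st$recordings[["tdcs01_task"]]
  expect_equal(rec$group, "tdcs")
  expect_equal(rec$state, "task")
  expect_equal(dim(rec), c(4L, 2500L))
  man <- dplyr::filter(st$manifest, subject_id == "tdcs01", state == "task")
  # multipliers recorded in the ground truth
  expect_equal(unique(man$chi), min(1, 0.4 * 2 * 0.8))
  expect_equal(unique(man$a_delta), 10 * 0.9)
  expect_equal(unique(man$a_gamma), 22 * 1.15)
  sham <- dplyr::filter(st$manifest, subject_id == "sham01", state == "pre_rest")
  expect_equal(unique(sham$chi), 0.4)
})

test_that("latent communities induce block-structured correlations", {
  spec <- reduced_spec(n_channels = 8, seed = 65)
  st <- gen_study(spec, 1, groups = "wm", states = "task")
  rec <- st$recordings[[1]]
  comm <- st$manifest$community
  cm <- correlation_matrix(rec)
  same <- outer(comm, comm, "==") & upper.tri(cm$r)
  diff <- outer(comm, comm, "!=") & upper.tri(cm$r)
  expect_gte(mean(cm$r[same]) - mean(cm$r[diff]), 0.2)
  # at the selected threshold, within-community connectivity dominates
  th <- suppressWarnings(select_threshold(cm))
  net <- binarize(cm, th)
  a <- net$adjacency
  expect_gt(mean(a[same]), mean(a[diff]))
})

test_that("generated spectra place power in the configured bands", {
  spec <- reduced_spec(n_channels = 1, duration_s = 40, seed = 66)
  x <- gen_coupled_channel(spec)$signal
  psd <- welch_psd(x, spec$fs)
  delta_db <- band_power_db(psd, delta_band())
  gamma_db <- band_power_db(psd, gamma_band())
  floor_db <- band_power_db(psd, band("floor", 10, 20))
  expect_gte(delta_db, floor_db + 10)
  expect_gte(gamma_db, floor_db + 10)
})

test_that("written studies reload identically and reproduce byte-for-byte", {
  spec <- reduced_spec(duration_s = 5, seed = 67)
  st <- gen_study(spec, 1, groups = "wm", states = "task")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(st, d1); write_study(st, d2)
  expect_identical(readLines(file.path(d1, "wm01_task.csv")),
                   readLines(file.path(d2, "wm01_task.csv")))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  back <- read_study(d1)
  expect_identical(back$recordings[[1]]$data, st$recordings[[1]]$data)
  expect_equal(back$recordings[[1]]$group, "wm")
})

test_that("task multiplier raises measured MI on most channels", {
  spec <- reduced_spec(n_channels = 6, seed = 68)
  st <- gen_study(spec, 1, groups = "wm", states = c("pre_rest", "task"))
  mi_rest <- channel_mi(st$recordings[["wm01_pre_rest"]])$value
  mi_task <- channel_mi(st$recordings[["wm01_task"]])$value
  expect_gte(mean(mi_task > mi_rest), 5 / 6)
})
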