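# Synthetic-session generator: concentration profiles, waveform synthesis,
# cohort structure, seed determinism, and the dose-effect laws.

test_that("concentration profile has one reading per minute and honors phases", {
  cfg <- generatorConfig(session_minutes = 120)
  prof <- generateConcentrationProfile(cfg, patient_seed = 11)
  expect_length(prof@et_sevo, 120)
  expect_equal(diff(prof@timestamps), rep(60, 119))
  expect_true(all(prof@et_sevo >= 0))
  # induction rises, emergence falls below the maintenance plateau
  expect_lt(prof@et_sevo[1], prof@et_sevo[10])
  expect_lt(prof@et_sevo[120], prof@et_sevo[110])
})

test_that("degenerate profile (no ramp, no decay, zero SD) is constant", {
  cfg <- generatorConfig(concentration_profile = list(
    induction_minutes = 0, emergence_minutes = 0,
    maintenance_mean = 2.0, maintenance_sd = 0))
  prof <- generateConcentrationProfile(cfg, patient_seed = 1)
  expect_equal(prof@et_sevo, rep(2.0, 120))
})

test_that("profiles are seed-deterministic and distinct across seeds", {
  cfg <- generatorConfig()
  a <- generateConcentrationProfile(cfg, patient_seed = 3)
  b <- generateConcentrationProfile(cfg, patient_seed = 3)
  c <- generateConcentrationProfile(cfg, patient_seed = 4)
  expect_identical(a@et_sevo, b@et_sevo)
  expect_false(identical(a@et_sevo, c@et_sevo))
})

test_that("too-short sessions are rejected", {
  expect_error(generateConcentrationProfile(
    generatorConfig(session_minutes = 5), 1), "session_minutes")
})

test_that("noiseless canonical trials peak at the components' nominal latencies", {
  cfg <- noiselessConfig()
  ul <- synthesizeTrial("left_ulnar", "CP4-Fpz", 0, cfg)
  t_ms <- trialTimes(ul)
  i_min <- which.min(ul@samples)
  expect_equal(t_ms[i_min], 20)                      # global minimum: N20
  after <- seq(i_min + 1, length(ul@samples))
  expect_equal(t_ms[after[which.max(ul@samples[after])]], 30)  # P30
  tb <- synthesizeTrial("left_post_tibial", "CPz-Fpz", 0, cfg)
  t_ms <- trialTimes(tb)
  i_max <- which.max(tb@samples)
  expect_equal(t_ms[i_max], 37)                      # P37
  after <- seq(i_max + 1, length(tb@samples))
  expect_equal(t_ms[after[which.min(tb@samples[after])]], 45)  # N45
})

test_that("dose effect follows the generator's closed form", {
  cfg <- noiselessConfig(amp_atten_k = 0.3, lat_shift_k = 1.5)
  t0 <- synthesizeTrial("left_ulnar", "CP4-Fpz", 0, cfg)
  t2 <- synthesizeTrial("left_ulnar", "CP4-Fpz", 2, cfg)
  d0 <- detectEvokedResponse(t0)
  d2 <- detectEvokedResponse(t2)
  # amplitudes shrink by exp(-k_A * c) = exp(-0.6); latencies shift +3 ms
  expect_equal(d2[["amp_valley"]] / d0[["amp_valley"]], exp(-0.6),
               tolerance = 1e-6)
  expect_equal(d2[["lat_valley"]] - d0[["lat_valley"]], 3)
  expect_equal(d2[["lat_peak"]] - d0[["lat_peak"]], 3)
})

test_that("noise-free amplitude decreases and latency increases with dose", {
  cfg <- noiselessConfig()
  channels <- list(c("left_ulnar", "CP4-Fpz"), c("left_ulnar", "CS5-Fpz"),
                   c("right_post_tibial", "CPz-Fpz"))
  for (ch in channels) {
    det <- sapply(c(0, 1, 2), function(cc)
      detectEvokedResponse(synthesizeTrial(ch[1], ch[2], cc, cfg)))
    expect_true(all(diff(abs(det["amp_valley", ])) < 0),
                label = paste(ch, collapse = "/"))
    expect_true(all(diff(abs(det["amp_peak", ])) < 0))
    expect_true(all(diff(det["lat_valley", ]) > 0))
    expect_true(all(diff(det["lat_peak", ]) > 0))
  }
})

test_that("cohort structure: sessions, channel streams, trial counts", {
  coh <- tinyCohort(n_patients = 3, trials_per_nerve = 8)
  expect_length(coh, 3)
  trs <- sessionTrials(coh[[1]])
  key <- vapply(trs, function(x) paste(x@nerve, x@montage), character(1))
  expect_length(unique(key), 12)                 # 4 nerves x 3 montages
  expect_true(all(table(key) == 8))              # trials_per_nerve each
  expect_s4_class(sessionAnesthesia(coh[[1]]), "AnesthesiaSeries")
  expect_true(all(vapply(trs, function(x)
    x@timestamp >= 0 && x@timestamp <= 120 * 60, logical(1))))
})

test_that("cohort generation is bit-identical under the same config", {
  cfg <- generatorConfig(n_patients = 3, trials_per_nerve = 4, seed = 9L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("invalid generator inputs are rejected", {
  expect_error(synthesizeTrial("left_ulnar", "CPz-Fpz", 0, generatorConfig()),
               "unknown nerve/montage")
  expect_error(synthesizeTrial("left_ulnar", "CP4-Fpz", -1, generatorConfig()),
               "concentration")
  expect_error(generateCohort(generatorConfig(n_patients = 2)), "n_patients")
  expect_error(generatorConfig(window_ms = 60), "window_ms")
  expect_error(generatorConfig(amp_atten_k = -1), "amp_atten_k")
})

test_that("component templates match polarity naming and physiologic windows", {
  for (cls in c("cortical_ulnar", "subcortical_ulnar", "tibial")) {
    tpl <- componentTemplates(cls)
    expect_equal(tpl$polarity, ifelse(startsWith(tpl$name, "N"), -1, 1))
    w <- evokedWindows(cls)
    for (side in names(w)) {
      comp <- tpl[tpl$name == w[[side]]$name, ]
      expect_gte(comp$base_latency, w[[side]]$start)
      expect_lte(comp$base_latency, w[[side]]$end)
    }
  }
})
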