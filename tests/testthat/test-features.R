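# Waveform feature extraction: evoked detection, phase-space-curve area,
# time-frequency peaks, PCA scores, and the 11/33/132 bookkeeping.

test_that("evoked detection is translation- and scale-equivariant", {
  cfg <- noiselessConfig()
  tr <- synthesizeTrial("left_ulnar", "CP4-Fpz", 0, cfg)
  d0 <- detectEvokedResponse(tr)
  # shift the waveform +2 ms (10 samples at 5 kHz)
  shifted <- makeTrial(c(rep(0, 10), head(tr@samples, -10)))
  d1 <- detectEvokedResponse(shifted)
  expect_equal(d1[["lat_valley"]], d0[["lat_valley"]] + 2)
  expect_equal(d1[["lat_peak"]], d0[["lat_peak"]] + 2)
  expect_equal(d1[["amp_valley"]], d0[["amp_valley"]])
  # scale x2: amplitudes double, latencies unchanged
  d2 <- detectEvokedResponse(makeTrial(tr@samples * 2))
  expect_equal(d2[["amp_valley"]], 2 * d0[["amp_valley"]])
  expect_equal(d2[["amp_peak"]], 2 * d0[["amp_peak"]])
  expect_equal(d2[["lat_valley"]], d0[["lat_valley"]])
  expect_error(
    detectEvokedResponse(tr, windows = list(
      pos = list(name = "P", start = 150, end = 160),
      neg = list(name = "N", start = 15, end = 25))),
    "outside the sampled range")
})

test_that("psc area: degenerate zero, quadratic scaling, sinusoid closed form", {
  expect_equal(pscArea(makeTrial(rep(0, 400))), 0)
  set.seed(7)
  w <- rnorm(400)
  a1 <- pscArea(makeTrial(w))
  expect_equal(pscArea(makeTrial(3 * w)), 9 * a1, tolerance = 1e-10)
  # sinusoid, delay = quarter period: the projected curve is a circle of
  # radius A traversed once when the retained points span one full period
  fs <- 1000; f0 <- 10; A <- 1.7
  tt <- (0:149) / fs                       # 150 ms: 1.5 periods
  tone <- makeTrial(A * sin(2 * pi * f0 * tt), sample_rate = fs)
  area <- pscArea(tone, delay_ms = 25)     # quarter period = 25 ms
  expect_equal(area, pi * A^2, tolerance = 0.01)
  expect_error(pscArea(makeTrial(rep(0, 400)), delay_ms = 50), "delay")
})

test_that("psc area agrees with an independent polygon-area oracle", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    w <- rnorm(n)
    tr <- makeTrial(w, sample_rate = 1000)
    tau <- 2                                # 2 ms = 2 samples at 1 kHz
    m <- n - 2 * tau
    x <- w[1:m]; y <- w[(1 + tau):(m + tau)]
    expect_equal(pscArea(tr, delay_ms = 2),
                 abs(pracma::polyarea(x, y)), tolerance = 1e-12)
  }
})

test_that("time-frequency peak identifies a known tone and burst time", {
  fs <- 5000
  tt <- (0:499) / fs
  tone <- makeTrial(sin(2 * pi * 100 * tt))
  tfa <- tfaFeatures(tone)
  expect_lte(abs(tfa[["tfa_peak_freq"]] - 100), 50)   # one 50 Hz bin
  # 10 ms burst of a 200 Hz tone centered at 30 ms, silence elsewhere
  burst <- ifelse(abs(tt - 0.030) <= 0.005, sin(2 * pi * 200 * tt), 0)
  tfb <- tfaFeatures(makeTrial(burst))
  expect_lte(abs(tfb[["tfa_peak_time"]] - 30), 10)    # one 10 ms hop
  expect_warning(tfz <- tfaFeatures(makeTrial(rep(0, 500))), "zero")
  expect_equal(unname(tfz), c(10, 0, 0))
})

test_that("pca scores: degenerate, rank-1, permutation equivariance", {
  flat <- matrix(1, 6, 50)
  pz <- pcaScores(flat)
  expect_true(pz$degenerate)
  expect_equal(pz$scores, matrix(0, 6, 3,
                                 dimnames = list(NULL, c("pc1", "pc2", "pc3"))))
  # rank-1 outer product: pc1 explains 100% of variance
  set.seed(3)
  r1 <- outer(rnorm(8), rnorm(50))
  p1 <- pcaScores(r1)
  expect_equal(p1$cum_variance[1], 1, tolerance = 1e-12)
  # permuting trials permutes scores identically
  set.seed(4)
  m <- matrix(rnorm(10 * 40), 10, 40)
  perm <- sample(10)
  pa <- pcaScores(m)
  pb <- pcaScores(m[perm, ])
  expect_equal(pb$scores, pa$scores[perm, ], tolerance = 1e-8)
  expect_equal(pb$cum_variance, pa$cum_variance)
  expect_error(pcaScores(m[1:3, ]), "more trials")
})

test_that("feature bookkeeping is 11 per channel, 33 per nerve, 132 per patient", {
  ft <- tinyFeatureTable()
  cols <- intersect(featureColumns(), names(ft))
  expect_length(cols, 132)
  for (nv in monitoredNerves()) {
    expect_length(featureColumns(nv), 33)
    for (mg in nerveMontages(nv)) {
      per_channel <- grep(paste0("^", nv, "\\.", mg, "\\."), cols,
                          value = TRUE)
      expect_length(per_channel, 11)
    }
  }
  # per-nerve rows carry that nerve's 33 features and NA elsewhere
  lu <- ft[ft$nerve == "left_ulnar", ]
  expect_true(all(!is.na(lu[, featureColumns("left_ulnar")])))
  expect_true(all(is.na(lu[, featureColumns("right_ulnar")])))
  expect_false(anyNA(ft$et_sevo_pct))
})

test_that("assembly fails loudly when a channel is missing", {
  coh <- tinyCohort()
  synced <- synchronizeTrials(coh[[1]])
  drop <- vapply(synced, function(x)
    x$trial@nerve == "left_ulnar" && x$trial@montage == "CS5-Fpz",
    logical(1))
  broken <- synced[!drop]
  expect_error(assembleFeatureTable(list(P01 = broken)), "CS5-Fpz")
})

test_that("latency features stay inside their search windows", {
  ft <- tinyFeatureTable()
  for (nv in monitoredNerves()) {
    rows <- ft[ft$nerve == nv, ]
    for (mg in nerveMontages(nv)) {
      w <- evokedWindows(channelClass(nv, mg))
      lp <- rows[[paste(nv, mg, "lat_peak", sep = ".")]]
      lv <- rows[[paste(nv, mg, "lat_valley", sep = ".")]]
      expect_true(all(lp >= w$pos$start & lp <= w$pos$end))
      expect_true(all(lv >= w$neg$start & lv <= w$neg$end))
    }
  }
})
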