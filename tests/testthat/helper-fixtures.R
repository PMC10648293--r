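# Shared fixtures, built in code. The tiny cohort is cached per option set
# so test files can reuse it without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

noiselessConfig <- function(...) {
  generatorConfig(noise_sd = 0, pink_noise_sd = 0, ...)
}

tinyCohort <- function(n_patients = 3, trials_per_nerve = 8, seed = 42L, ...) {
  key <- paste(n_patients, trials_per_nerve, seed, ...)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- generatorConfig(n_patients = n_patients,
                           trials_per_nerve = trials_per_nerve,
                           seed = seed, ...)
    .fixture_cache[[key]] <- generateCohort(cfg)
  }
  .fixture_cache[[key]]
}

tinyFeatureTable <- function(n_patients = 3, trials_per_nerve = 8,
                             seed = 42L) {
  key <- paste("ft", n_patients, trials_per_nerve, seed)
  if (is.null(.fixture_cache[[key]])) {
    coh <- tinyCohort(n_patients, trials_per_nerve, seed)
    synced <- lapply(coh, synchronizeTrials)
    names(synced) <- vapply(coh, patientId, character(1))
    .fixture_cache[[key]] <- assembleFeatureTable(synced)
  }
  .fixture_cache[[key]]
}

# Independent brute-force greedy MRMR oracle: recomputes every MI term
# afresh at each step; shares only the MI estimator with the implementation.
bruteForceGreedy <- function(X, y, k) {
  feats <- names(X)
  rel <- sapply(feats, function(f) mutualInformation(X[[f]], y))
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(feats, sel)
    sc <- sapply(cand, function(f) {
      if (length(sel) == 0) return(rel[[f]])
      red <- mean(sapply(sel, function(s)
        mutualInformation(X[[f]], X[[s]])))
      rel[[f]] / (red + 1e-12)
    })
    sel <- c(sel, cand[which.max(sc)])
  }
  sel
}

# Wrap an arbitrary waveform in a valid trial object (ulnar cortical slot
# by default; the channel label is irrelevant to the numeric operations
# under test).
makeTrial <- function(samples, sample_rate = 5000, nerve = "left_ulnar",
                      montage = "CP4-Fpz", timestamp = 0) {
  SSEPTrial("fixture", nerve, montage, timestamp, samples, sample_rate)
}
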