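# Five-category waveform feature extraction. Each recording channel yields
# 11 features per trial: phase-space-curve area (1), evoked latency
# peak/valley (2), evoked amplitude peak/valley (2), time-frequency peak
# frequency/power/time (3), and the first three principal-component scores
# (3). Three channels per nerve give 33 per nerve; four nerves give 132 per
# patient.

.FEATURE_NAMES <- c("psc_area", "lat_peak", "lat_valley", "amp_peak",
                    "amp_valley", "tfa_peak_freq", "tfa_peak_power",
                    "tfa_peak_time", "pc1", "pc2", "pc3")

#' Evoked-component search windows
#'
#' Latency search windows (ms post-stimulus) around each channel class's
#' nominal component latencies. The component names encode polarity and
#' nominal latency (N20 = negative deflection near 20 ms, etc.); the window
#' widths are analysis configuration, wide enough to track dose-driven
#' latency prolongation.
#'
#' @param class channel class, see [channelClass()]
#' @return list with elements `pos` and `neg`, each
#'   `list(name, start, end)` in ms
#' @export
evokedWindows <- function(class = c("cortical_ulnar", "subcortical_ulnar",
                                    "tibial")) {
  class <- match.arg(class)
  switch(class,
    cortical_ulnar = list(
      neg = list(name = "N20", start = 15, end = 25),
      pos = list(name = "P30", start = 25, end = 40)),
    subcortical_ulnar = list(
      neg = list(name = "N13", start = 10, end = 16),
      pos = list(name = "P14", start = 11, end = 18)),
    tibial = list(
      pos = list(name = "P37", start = 30, end = 45),
      neg = list(name = "N45", start = 40, end = 55))
  )
}

#' Detect evoked-response latency and amplitude
#'
#' Peak = argmax of the waveform inside the positive component's window;
#' valley = argmin inside the negative component's window; amplitudes are
#' the waveform values at those latencies. Ties break toward the earlier
#' sample.
#'
#' @param trial an [SSEPTrial-class]
#' @param windows window set from [evokedWindows()]; defaults to the
#'   trial's channel class
#' @return named numeric: `lat_peak`, `amp_peak`, `lat_valley`,
#'   `amp_valley` (ms / uV)
#' @export
detectEvokedResponse <- function(trial,
                                 windows = evokedWindows(
                                   channelClass(trial@nerve, trial@montage))) {
  t_ms <- trialTimes(trial)
  pick <- function(w, fun) {
    idx <- which(t_ms >= w$start & t_ms <= w$end)
    if (length(idx) == 0)
      stop("window [", w$start, ", ", w$end,
           "] ms lies outside the sampled range")
    j <- idx[fun(trial@samples[idx])]
    c(lat = t_ms[j], amp = trial@samples[j])
  }
  pk <- pick(windows$pos, which.max)
  vl <- pick(windows$neg, which.min)
  c(lat_peak = unname(pk["lat"]), amp_peak = unname(pk["amp"]),
    lat_valley = unname(vl["lat"]), amp_valley = unname(vl["amp"]))
}

#' Phase-space-curve area of a waveform
#'
#' Builds the 3-dimensional time-delay embedding
#' \eqn{[x(t), x(t+\tau), x(t+2\tau)]}, projects the trajectory onto its
#' first two embedding coordinates, closes the projected polygon, and
#' returns the absolute shoelace area. The area scales with the square of
#' the waveform amplitude; a pure sinusoid with \eqn{\tau} = quarter period
#' traces a circle of area \eqn{\pi A^2} per traversal.
#'
#' @param trial an [SSEPTrial-class]
#' @param delay_ms embedding delay \eqn{\tau} in ms (> 0)
#' @param dim embedding dimension (default 3)
#' @return area in uV^2
#' @export
pscArea <- function(trial, delay_ms = 2, dim = 3) {
  if (delay_ms <= 0) stop("delay_ms must be > 0")
  n <- length(trial@samples)
  tau <- as.integer(round(delay_ms * trial@sample_rate / 1000))
  if (tau < 1) stop("delay_ms shorter than one sample period")
  m <- n - (dim - 1) * tau
  if (m < 3)
    stop("delay too large: embedding needs delay_ms < trial duration/",
         dim - 1)
  x <- trial@samples[seq_len(m)]
  y <- trial@samples[seq_len(m) + tau]
  nxt <- c(seq_len(m)[-1], 1L)       # close the polygon
  0.5 * abs(sum(x * y[nxt] - x[nxt] * y))
}

#' Time-frequency peak features of a waveform
#'
#' Computes a Hann-windowed magnitude-squared short-time spectrogram and
#' returns the frequency, power, and time-bin center of the global in-band
#' maximum. An all-zero signal yields the documented degenerate output
#' (lowest in-band frequency, power 0, time 0) with a warning.
#'
#' @param trial an [SSEPTrial-class]
#' @param band analysis band in Hz, inside (0, sample_rate/2)
#' @param window_ms STFT window length, ms
#' @param overlap fractional window overlap
#' @return named numeric: `tfa_peak_freq` (Hz), `tfa_peak_power`,
#'   `tfa_peak_time` (ms)
#' @export
tfaFeatures <- function(trial, band = c(10, 500), window_ms = 20,
                        overlap = 0.5) {
  fs <- trial@sample_rate
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie inside (0, sample_rate/2)")
  nwin <- as.integer(round(window_ms / 1000 * fs))
  if (length(trial@samples) < nwin)
    stop("trial shorter than one STFT window")
  if (all(trial@samples == 0)) {
    warning("all-zero signal: degenerate time-frequency output")
    return(c(tfa_peak_freq = band[1], tfa_peak_power = 0, tfa_peak_time = 0))
  }
  sg <- signal::specgram(trial@samples, n = nwin, Fs = fs,
                         window = signal::hanning(nwin),
                         overlap = as.integer(round(nwin * overlap)))
  P <- abs(sg$S)^2
  inband <- sg$f >= band[1] & sg$f <= band[2]
  Pb <- P[inband, , drop = FALSE]
  fb <- sg$f[inband]
  # sg$t marks the first sample of each window; convert to window centers
  centers_ms <- (sg$t - 1 / fs + (nwin - 1) / (2 * fs)) * 1000
  idx <- which(Pb == max(Pb), arr.ind = TRUE)[1, ]   # ties: lowest index
  c(tfa_peak_freq = fb[idx[1]], tfa_peak_power = max(Pb),
    tfa_peak_time = centers_ms[idx[2]])
}

#' Principal-component scores of one channel's trial matrix
#'
#' Mean-centers the trial-by-sample matrix across trials and returns each
#' trial's scores on the first `n_components` principal components, with
#' each component's sign fixed so that its largest-magnitude loading is
#' positive, plus the cumulative variance fraction. An all-identical trial
#' matrix is degenerate: zero scores and undefined variance fractions.
#'
#' @param trial_matrix numeric matrix, one row per trial, equal-length rows
#' @param n_components number of components (default 3)
#' @return list with `scores` (trials x n_components), `cum_variance`
#'   (cumulative fraction per component), `degenerate` flag
#' @export
pcaScores <- function(trial_matrix, n_components = 3) {
  trial_matrix <- as.matrix(trial_matrix)
  if (nrow(trial_matrix) <= n_components)
    stop("need more trials (", nrow(trial_matrix), ") than components (",
         n_components, ")")
  ctr <- scale(trial_matrix, center = TRUE, scale = FALSE)
  totvar <- sum(apply(ctr, 2, var))
  if (totvar == 0) {
    return(list(scores = matrix(0, nrow(trial_matrix), n_components,
                                dimnames = list(NULL, paste0("pc", seq_len(n_components)))),
                cum_variance = rep(NA_real_, n_components),
                degenerate = TRUE))
  }
  pc <- prcomp(trial_matrix, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$rotation))
  scores <- matrix(0, nrow(trial_matrix), n_components)
  for (j in seq_len(ncomp)) {
    s <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    if (s == 0) s <- 1
    scores[, j] <- pc$x[, j] * s
  }
  colnames(scores) <- paste0("pc", seq_len(n_components))
  vfrac <- pc$sdev^2 / sum(pc$sdev^2)
  cumv <- cumsum(vfrac)[seq_len(n_components)]
  cumv[is.na(cumv)] <- 1        # fewer PCs than requested: all variance in
  list(scores = scores, cum_variance = cumv, degenerate = FALSE)
}

#' Assemble the trials-by-features table
#'
#' Computes all 11 per-channel features for every synchronized trial of
#' every patient and lays them out in the fixed 132-column universe
#' (4 nerves x 3 montages x 11 features), columns named
#' `<nerve>.<montage>.<feature>`. One row per stimulation event of one
#' nerve: the three montages of a nerve share stimulation events (matched
#' by time order), so a row carries that nerve's 33 features and `NA` for
#' the other nerves' columns. The final column `et_sevo_pct` is the
#' synchronized concentration, the regression target.
#'
#' @param synced_by_patient named list: patient id -> output of
#'   [synchronizeTrials()]
#' @param psc_delay_ms,tfa_band,tfa_window_ms analysis parameters passed to
#'   [pscArea()] and [tfaFeatures()]
#' @return data.frame with columns patient_id, nerve, event, timestamp_s,
#'   the 132 feature columns, and et_sevo_pct
#' @export
assembleFeatureTable <- function(synced_by_patient, psc_delay_ms = 2,
                                 tfa_band = c(10, 500), tfa_window_ms = 20) {
  stopifnot(is.list(synced_by_patient), !is.null(names(synced_by_patient)))
  all_cols <- featureColumns()
  rows <- list()
  for (pid in names(synced_by_patient)) {
    synced <- synced_by_patient[[pid]]
    trs <- lapply(synced, `[[`, "trial")
    conc <- vapply(synced, `[[`, numeric(1), "concentration")
    key_nerve <- vapply(trs, slot, character(1), name = "nerve")
    key_mont <- vapply(trs, slot, character(1), name = "montage")
    for (nv in intersect(.NERVES, unique(key_nerve))) {
      mlists <- lapply(.MONTAGES[[nv]], function(mg) which(
        key_nerve == nv & key_mont == mg))
      names(mlists) <- .MONTAGES[[nv]]
      counts <- lengths(mlists)
      if (any(counts == 0))
        stop("patient ", pid, ", nerve ", nv, ": missing channel ",
             paste(names(mlists)[counts == 0], collapse = ", "))
      if (length(unique(counts)) != 1)
        stop("patient ", pid, ", nerve ", nv,
             ": unequal trial counts across montages")
      n_ev <- counts[[1]]
      nerve_rows <- as.data.frame(
        matrix(NA_real_, n_ev, length(all_cols)), optional = TRUE)
      names(nerve_rows) <- all_cols
      for (mg in .MONTAGES[[nv]]) {
        idx <- mlists[[mg]]
        mat <- do.call(rbind, lapply(trs[idx], slot, name = "samples"))
        pca <- pcaScores(mat, 3)
        for (e in seq_len(n_ev)) {
          tr <- trs[[idx[e]]]
          ev <- detectEvokedResponse(tr)
          tfa <- tfaFeatures(tr, band = tfa_band, window_ms = tfa_window_ms)
          vals <- c(psc_area = pscArea(tr, delay_ms = psc_delay_ms),
                    ev, tfa,
                    pc1 = unname(pca$scores[e, 1]),
                    pc2 = unname(pca$scores[e, 2]),
                    pc3 = unname(pca$scores[e, 3]))
          nerve_rows[e, paste(nv, mg, names(vals), sep = ".")] <-
            unname(vals)
        }
      }
      first_idx <- mlists[[1]]
      meta <- data.frame(
        patient_id = pid, nerve = nv, event = seq_len(n_ev),
        timestamp_s = vapply(trs[first_idx], slot, numeric(1),
                             name = "timestamp"),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(
        meta, nerve_rows, et_sevo_pct = conc[first_idx])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualified feature column names
#'
#' @param nerve optionally restrict to one nerve (33 columns); default all
#'   four nerves (132 columns)
#' @return character vector of `<nerve>.<montage>.<feature>` names
#' @export
featureColumns <- function(nerve = NULL) {
  nerves <- if (is.null(nerve)) .NERVES else match.arg(nerve, .NERVES)
  unlist(lapply(nerves, function(nv)
    unlist(lapply(.MONTAGES[[nv]], function(mg)
      paste(nv, mg, .FEATURE_NAMES, sep = ".")))))
}
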