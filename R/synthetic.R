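# Synthetic SSEP session generator. Waveforms are sums of Gaussian bumps,
# one per named evoked component, with a multiplicative-exponential
# amplitude attenuation and a linear latency prolongation in the end-tidal
# sevoflurane concentration c:
#   w(t; c) = sum_i  p_i * A_i * exp(-k_A c) * exp(-(t - L_i - k_L c)^2 / (2 s_i^2))
#             + white noise + 1/f noise
# Gaussian bumps give closed-form peak locations and scale laws, which the
# test oracles exploit.

#' Default evoked-component templates for a channel class
#'
#' Cortical ulnar channels carry N20/P30, the subcortical (CS5-Fpz) ulnar
#' channel N13/P14, and all posterior-tibial channels P37/N45. The polarity
#' follows the component's leading letter (N negative, P positive); base
#' latencies are the nominal post-stimulus latencies the component is named
#' after. Amplitudes and widths are generator choices at realistic scalp
#' scales (a couple of microvolts, a few milliseconds).
#'
#' @param class one of `"cortical_ulnar"`, `"subcortical_ulnar"`, `"tibial"`
#' @return data.frame with columns name, polarity, base_latency (ms),
#'   base_amplitude (uV), width (ms)
#' @export
componentTemplates <- function(class = c("cortical_ulnar", "subcortical_ulnar",
                                         "tibial")) {
  class <- match.arg(class)
  tpl <- switch(class,
    cortical_ulnar = data.frame(
      name = c("N20", "P30"), polarity = c(-1, 1),
      base_latency = c(20, 30), base_amplitude = c(2.0, 1.5),
      width = c(2.5, 3.0)),
    subcortical_ulnar = data.frame(
      name = c("N13", "P14"), polarity = c(-1, 1),
      base_latency = c(13, 14), base_amplitude = c(1.2, 1.0),
      width = c(1.0, 1.0)),
    tibial = data.frame(
      name = c("P37", "N45"), polarity = c(1, -1),
      base_latency = c(37, 45), base_amplitude = c(1.0, 0.7),
      width = c(2.0, 2.5))
  )
  stopifnot(all(tpl$width > 0),
            all(tpl$polarity == ifelse(startsWith(tpl$name, "N"), -1, 1)))
  tpl
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic-session generator. All randomness in
#' the generator flows from `seed`.
#'
#' @param n_patients number of patients in the cohort (>= 3)
#' @param trials_per_nerve stimulation trials per nerve (each produces one
#'   waveform on each of the nerve's three montages)
#' @param sample_rate waveform sampling rate, Hz
#' @param window_ms post-stimulus analysis window, ms (must contain the
#'   latest named component; >= 100 so the tibial N45 fits)
#' @param noise_sd white-noise standard deviation, uV
#' @param pink_noise_sd 1/f-noise standard deviation, uV
#' @param amp_atten_k amplitude attenuation coefficient k_A, per %
#' @param lat_shift_k latency prolongation coefficient k_L, ms per %
#' @param seed master integer seed
#' @param session_minutes session length in minutes (>= 10)
#' @param concentration_profile list with `induction_minutes`,
#'   `maintenance_mean` (%), `maintenance_sd` (%), `maintenance_ar`
#'   (AR(1) coefficient of maintenance fluctuation), `emergence_minutes`,
#'   `emergence_decay` (per-minute exponential decay rate)
#' @return a `GeneratorConfig` list
#' @export
generatorConfig <- function(n_patients = 10,
                            trials_per_nerve = 30,
                            sample_rate = 5000,
                            window_ms = 100,
                            noise_sd = 0.005,
                            pink_noise_sd = 0.005,
                            amp_atten_k = 0.3,
                            lat_shift_k = 0.8,
                            seed = 1L,
                            session_minutes = 120,
                            concentration_profile = list()) {
  prof <- utils::modifyList(list(
    induction_minutes = 10, maintenance_mean = 2.0, maintenance_sd = 0.25,
    maintenance_ar = 0.8, emergence_minutes = 10, emergence_decay = 0.35
  ), concentration_profile)
  cfg <- list(
    n_patients = as.integer(n_patients),
    trials_per_nerve = as.integer(trials_per_nerve),
    sample_rate = sample_rate, window_ms = window_ms,
    noise_sd = noise_sd, pink_noise_sd = pink_noise_sd,
    amp_atten_k = amp_atten_k, lat_shift_k = lat_shift_k,
    seed = as.integer(seed), session_minutes = session_minutes,
    concentration_profile = prof
  )
  if (cfg$sample_rate <= 0) stop("sample_rate must be positive")
  if (cfg$window_ms < 100)
    stop("window_ms must be >= 100 ms to contain the tibial N45 component")
  if (cfg$amp_atten_k < 0 || cfg$lat_shift_k < 0)
    stop("amp_atten_k and lat_shift_k must be >= 0")
  if (cfg$noise_sd < 0 || cfg$pink_noise_sd < 0)
    stop("noise levels must be >= 0")
  class(cfg) <- "GeneratorConfig"
  cfg
}

# Spectrally shaped 1/f ("pink") noise of length n, unit sd, drawn from the
# current RNG stream.
pinkNoise <- function(n) {
  w <- rnorm(n)
  X <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)              # two-sided frequency index
  sc <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(fft(X * sc, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Generate a per-minute end-tidal sevoflurane concentration profile
#'
#' Piecewise profile mirroring a surgical anesthetic course: a rising
#' induction ramp, a fluctuating maintenance plateau (AR(1) around the
#' maintenance mean), and an exponentially decaying emergence tail. One
#' reading per minute; all readings >= 0.
#'
#' @param cfg a [generatorConfig()]
#' @param patient_seed integer seed for this patient's profile
#' @return an [AnesthesiaSeries-class] with `session_minutes` readings
#' @examples
#' prof <- generateConcentrationProfile(generatorConfig(), patient_seed = 7)
#' @export
generateConcentrationProfile <- function(cfg, patient_seed) {
  if (cfg$session_minutes < 10)
    stop("session_minutes must be >= 10")
  p <- cfg$concentration_profile
  m <- as.integer(round(cfg$session_minutes))
  withr::with_seed(as.integer(patient_seed), {
    mi <- min(p$induction_minutes, m)
    me <- min(p$emergence_minutes, m - mi)
    mm <- m - mi - me
    conc <- numeric(m)
    # induction: linear ramp from 0 toward the maintenance mean
    if (mi > 0) conc[seq_len(mi)] <- p$maintenance_mean * (seq_len(mi) / mi)
    # maintenance: AR(1) fluctuation with stationary sd maintenance_sd
    level <- p$maintenance_mean
    if (mm > 0) {
      x <- numeric(mm)
      innov_sd <- p$maintenance_sd * sqrt(1 - p$maintenance_ar^2)
      prev <- rnorm(1, 0, p$maintenance_sd)
      for (j in seq_len(mm)) {
        x[j] <- p$maintenance_mean + prev
        prev <- p$maintenance_ar * prev + rnorm(1, 0, innov_sd)
      }
      conc[mi + seq_len(mm)] <- x
      level <- x[mm]
    }
    # emergence: exponential decay from the last maintenance level
    if (me > 0)
      conc[mi + mm + seq_len(me)] <- level * exp(-p$emergence_decay * seq_len(me))
    AnesthesiaSeries(timestamps = (seq_len(m) - 1) * 60,
                     et_sevo = pmax(conc, 0))
  })
}

#' Synthesize one SSEP trial waveform at a given concentration
#'
#' The deterministic part of the waveform is the sum of the channel class's
#' Gaussian component bumps, each attenuated by `exp(-amp_atten_k * c)` and
#' delayed by `lat_shift_k * c` ms. White and 1/f noise (if configured
#' nonzero) are drawn from the current RNG stream, so seed management is the
#' caller's (normally [generateCohort()]'s) responsibility.
#'
#' @param nerve,montage nerve identifier and montage string (validated)
#' @param concentration end-tidal sevoflurane concentration c, % (>= 0)
#' @param cfg a [generatorConfig()]
#' @param trial_id,timestamp trial identifier and session time (s)
#' @return an [SSEPTrial-class]
#' @examples
#' cfg <- generatorConfig(noise_sd = 0, pink_noise_sd = 0)
#' tr <- synthesizeTrial("left_ulnar", "CP4-Fpz", 0, cfg)
#' @export
synthesizeTrial <- function(nerve, montage, concentration, cfg,
                            trial_id = "trial", timestamp = 0) {
  if (concentration < 0) stop("concentration must be >= 0")
  cls <- channelClass(nerve, montage)   # errors on unknown pairing
  tpl <- componentTemplates(cls)
  n <- as.integer(round(cfg$sample_rate * cfg$window_ms / 1000))
  t_ms <- (seq_len(n) - 1) / cfg$sample_rate * 1000
  atten <- exp(-cfg$amp_atten_k * concentration)
  shift <- cfg$lat_shift_k * concentration
  w <- numeric(n)
  for (i in seq_len(nrow(tpl))) {
    ctr <- tpl$base_latency[i] + shift
    w <- w + tpl$polarity[i] * tpl$base_amplitude[i] * atten *
      exp(-(t_ms - ctr)^2 / (2 * tpl$width[i]^2))
  }
  if (cfg$noise_sd > 0) w <- w + rnorm(n, 0, cfg$noise_sd)
  if (cfg$pink_noise_sd > 0) w <- w + cfg$pink_noise_sd * pinkNoise(n)
  SSEPTrial(trial_id, nerve, montage, timestamp, w, cfg$sample_rate)
}

#' Generate a synthetic patient cohort
#'
#' For each patient: a concentration profile, demographics, and
#' `trials_per_nerve` stimulation trials per nerve, time-stamped on a
#' jittered even grid across the session. Each stimulation trial yields one
#' waveform per montage (three channels per nerve), synthesized at the
#' concentration interpolated from the patient's profile at the trial time.
#' Bit-identical output under identical configuration.
#'
#' @param cfg a [generatorConfig()]
#' @return list of [PatientSession-class] objects
#' @export
generateCohort <- function(cfg) {
  if (cfg$n_patients < 3) stop("n_patients must be >= 3")
  lapply(seq_len(cfg$n_patients), function(i) {
    pseed <- cfg$seed * 1000L + i
    anest <- generateConcentrationProfile(cfg, pseed)
    withr::with_seed(pseed + 500000L, {
      age <- round(runif(1, 49, 74))
      sex <- sample(c("M", "F"), 1, prob = c(0.7, 0.3))
      sess_s <- cfg$session_minutes * 60
      spacing <- sess_s / cfg$trials_per_nerve
      trials <- list()
      for (nv in .NERVES) {
        ts <- sort(pmin(pmax(
          (seq_len(cfg$trials_per_nerve) - 0.5) * spacing +
            runif(cfg$trials_per_nerve, -0.3, 0.3) * spacing, 0), sess_s))
        conc <- approx(anest@timestamps, anest@et_sevo, xout = ts,
                       rule = 2)$y
        for (mg in .MONTAGES[[nv]]) {
          for (j in seq_len(cfg$trials_per_nerve)) {
            trials[[length(trials) + 1L]] <- synthesizeTrial(
              nv, mg, conc[j], cfg,
              trial_id = sprintf("P%02d_%s_%s_%03d", i, nv, mg, j),
              timestamp = ts[j])
          }
        }
      }
      PatientSession(sprintf("P%02d", i), age, sex, trials, anest)
    })
  })
}
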