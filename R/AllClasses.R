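#' SSEPTrial: one stimulation-locked SSEP waveform
#'
#' A single averaged evoked-response waveform (microvolts against
#' milliseconds post-stimulus) with its nerve, recording montage and
#' timestamp within the surgical session.
#'
#' @slot trial_id character trial identifier
#' @slot nerve one of [monitoredNerves()]
#' @slot montage montage string, member of the nerve's allowed set
#' @slot timestamp seconds since session start
#' @slot samples numeric waveform samples (microvolts)
#' @slot sample_rate sampling rate in Hz
#' @export
setClass("SSEPTrial", representation(
  trial_id = "character",
  nerve = "character",
  montage = "character",
  timestamp = "numeric",
  samples = "numeric",
  sample_rate = "numeric"
))

setValidity("SSEPTrial", function(object) {
  msg <- character()
  if (!object@nerve %in% .NERVES) {
    msg <- c(msg, paste0("nerve: unknown nerve '", object@nerve, "'"))
  } else if (!object@montage %in% .MONTAGES[[object@nerve]]) {
    msg <- c(msg, paste0("montage: '", object@montage,
                         "' not allowed for nerve '", object@nerve, "'"))
  }
  if (length(object@timestamp) != 1 || object@timestamp < 0)
    msg <- c(msg, "timestamp: must be a single value >= 0")
  if (length(object@sample_rate) != 1 || object@sample_rate <= 0)
    msg <- c(msg, "sample_rate: must be a single positive value")
  if (length(object@samples) < 2 || anyNA(object@samples))
    msg <- c(msg, "samples: must be a numeric vector without NA")
  if (length(msg)) msg else TRUE
})

#' AnesthesiaSeries: per-minute end-tidal sevoflurane concentration
#'
#' @slot timestamps seconds since session start, strictly increasing
#'   (nominally 60 s apart)
#' @slot et_sevo end-tidal sevoflurane concentration (volume %), each >= 0
#' @export
setClass("AnesthesiaSeries", representation(
  timestamps = "numeric",
  et_sevo = "numeric"
))

setValidity("AnesthesiaSeries", function(object) {
  msg <- character()
  if (length(object@timestamps) != length(object@et_sevo))
    msg <- c(msg, "timestamps/et_sevo: lengths differ")
  if (length(object@timestamps) > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps: must be strictly increasing")
  if (anyNA(object@et_sevo) || any(object@et_sevo < 0))
    msg <- c(msg, "et_sevo: all readings must be >= 0 and non-missing")
  if (length(msg)) msg else TRUE
})

#' PatientSession: all trials and the anesthesia record of one surgery
#'
#' @slot patient_id character patient identifier
#' @slot age years
#' @slot sex "M" or "F"
#' @slot trials list of [SSEPTrial-class] objects
#' @slot anesthesia an [AnesthesiaSeries-class]
#' @export
setClass("PatientSession", representation(
  patient_id = "character",
  age = "numeric",
  sex = "character",
  trials = "list",
  anesthesia = "AnesthesiaSeries"
))

setValidity("PatientSession", function(object) {
  msg <- character()
  if (!object@sex %in% c("M", "F"))
    msg <- c(msg, "sex: must be 'M' or 'F'")
  ok <- vapply(object@trials, is, logical(1), class2 = "SSEPTrial")
  if (!all(ok)) msg <- c(msg, "trials: all elements must be SSEPTrial")
  if (all(ok) && length(object@trials)) {
    seen <- unique(data.frame(
      nerve = vapply(object@trials, slot, character(1), name = "nerve"),
      montage = vapply(object@trials, slot, character(1), name = "montage")
    ))
    for (nv in .NERVES) {
      have <- seen$montage[seen$nerve == nv]
      miss <- setdiff(.MONTAGES[[nv]], have)
      if (length(miss))
        msg <- c(msg, paste0("trials: nerve '", nv, "' missing montage(s) ",
                             paste(miss, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SSEPTrial
#'
#' @param trial_id character identifier
#' @param nerve,montage nerve and montage (validated against the registry)
#' @param timestamp seconds since session start
#' @param samples numeric waveform (microvolts)
#' @param sample_rate Hz
#' @return an [SSEPTrial-class] object
#' @export
SSEPTrial <- function(trial_id, nerve, montage, timestamp, samples, sample_rate) {
  new("SSEPTrial", trial_id = as.character(trial_id), nerve = nerve,
      montage = montage, timestamp = as.numeric(timestamp),
      samples = as.numeric(samples), sample_rate = as.numeric(sample_rate))
}

#' Construct an AnesthesiaSeries
#'
#' @param timestamps seconds since session start, strictly increasing
#' @param et_sevo concentrations (%), same length
#' @return an [AnesthesiaSeries-class] object
#' @export
AnesthesiaSeries <- function(timestamps, et_sevo) {
  new("AnesthesiaSeries", timestamps = as.numeric(timestamps),
      et_sevo = as.numeric(et_sevo))
}

#' Construct a PatientSession
#'
#' @param patient_id character identifier
#' @param age years
#' @param sex "M" or "F"
#' @param trials list of [SSEPTrial-class]
#' @param anesthesia an [AnesthesiaSeries-class]
#' @return a [PatientSession-class] object
#' @export
PatientSession <- function(patient_id, age, sex, trials, anesthesia) {
  new("PatientSession", patient_id = as.character(patient_id),
      age = as.numeric(age), sex = sex, trials = trials,
      anesthesia = anesthesia)
}

#' @describeIn SSEPTrial-class waveform time axis in ms post-stimulus
#' @param trial an [SSEPTrial-class]
#' @export
trialTimes <- function(trial) {
  (seq_along(trial@samples) - 1) / trial@sample_rate * 1000
}

#' Accessors for session objects
#'
#' `sessionTrials()` returns the trial list, `sessionAnesthesia()` the
#' anesthesia series, `patientId()` the identifier.
#'
#' @param session a [PatientSession-class]
#' @return the corresponding slot value
#' @export
sessionTrials <- function(session) session@trials

#' @rdname sessionTrials
#' @export
sessionAnesthesia <- function(session) session@anesthesia

#' @rdname sessionTrials
#' @export
patientId <- function(session) session@patient_id

setMethod("show", "SSEPTrial", function(object) {
  cat(sprintf(
    "SSEPTrial '%s' [%s %s] t=%.1fs, %d samples @ %g Hz\n",
    object@trial_id, object@nerve, object@montage, object@timestamp,
    length(object@samples), object@sample_rate))
})

setMethod("show", "AnesthesiaSeries", function(object) {
  n <- length(object@et_sevo)
  cat(sprintf(
    "AnesthesiaSeries: %d readings, et sevo %.2f-%.2f%% over %.0f min\n",
    n, if (n) min(object@et_sevo) else NA, if (n) max(object@et_sevo) else NA,
    if (n) diff(range(object@timestamps)) / 60 else 0))
})

setMethod("show", "PatientSession", function(object) {
  cat(sprintf(
    "PatientSession '%s' (%s, %g y): %d trials, %d anesthesia readings\n",
    object@patient_id, object@sex, object@age, length(object@trials),
    length(object@anesthesia@et_sevo)))
})
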