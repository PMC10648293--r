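# Session persistence. The on-disk session format is a small documented
# JSON dialect (schema_version, patient block, anesthesia block, channels
# array of trial arrays); anesthesia series alone travel as two-column CSV
# (timestamp_s, et_sevo_pct).

.SCHEMA_VERSION <- "1.0"

#' Write / read a patient session as JSON
#'
#' `writeSession()` serializes a [PatientSession-class] to the package's
#' JSON session dialect; `readSession()` parses and validates it, raising a
#' schema error naming the offending field when the file violates the data
#' model (unknown montage, missing channel, non-monotone anesthesia
#' timestamps, malformed sample arrays). Write-then-read is the identity on
#' the data model.
#'
#' @param session a [PatientSession-class]
#' @param path file path
#' @return `readSession()` returns a [PatientSession-class];
#'   `writeSession()` invisibly returns `path`.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "PatientSession"))
  chan_key <- vapply(session@trials, function(tr)
    paste(tr@nerve, tr@montage, sep = "|"), character(1))
  channels <- lapply(split(seq_along(chan_key), chan_key), function(idx) {
    first <- session@trials[[idx[1]]]
    list(
      nerve = first@nerve, montage = first@montage,
      sample_rate = first@sample_rate,
      trials = lapply(idx, function(k) {
        tr <- session@trials[[k]]
        list(trial_id = tr@trial_id, timestamp_s = tr@timestamp,
             samples_uv = tr@samples)
      })
    )
  })
  doc <- list(
    schema_version = .SCHEMA_VERSION,
    patient = list(id = session@patient_id, age = session@age,
                   sex = session@sex),
    anesthesia = list(timestamps_s = session@anesthesia@timestamps,
                      et_sevo_pct = session@anesthesia@et_sevo),
    channels = unname(channels)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != .SCHEMA_VERSION)
    stop("schema_version: expected '", .SCHEMA_VERSION, "', got '",
         doc$schema_version, "'")
  an <- tryCatch(
    AnesthesiaSeries(doc$anesthesia$timestamps_s, doc$anesthesia$et_sevo_pct),
    error = function(e) stop("anesthesia: ", conditionMessage(e)))
  trials <- list()
  for (ci in seq_along(doc$channels)) {
    ch <- doc$channels[[ci]]
    for (ti in seq_along(ch$trials)) {
      tr <- ch$trials[[ti]]
      fieldpath <- sprintf("channels[%d]('%s','%s').trials[%d]",
                           ci, ch$nerve, ch$montage, ti)
      if (!is.numeric(unlist(tr$samples_uv)) || anyNA(unlist(tr$samples_uv)))
        stop(fieldpath, ".samples_uv: malformed sample array")
      trials[[length(trials) + 1L]] <- tryCatch(
        SSEPTrial(tr$trial_id, ch$nerve, ch$montage, tr$timestamp_s,
                  unlist(tr$samples_uv), ch$sample_rate),
        error = function(e) stop(fieldpath, ": ", conditionMessage(e)))
    }
  }
  tryCatch(
    PatientSession(doc$patient$id, doc$patient$age, doc$patient$sex,
                   trials, an),
    error = function(e) stop("session: ", conditionMessage(e)))
}

#' Write / read an anesthesia series as two-column CSV
#'
#' Columns `timestamp_s` and `et_sevo_pct`, one row per reading.
#'
#' @param series an [AnesthesiaSeries-class]
#' @param path file path
#' @return `readAnesthesiaCsv()` returns an [AnesthesiaSeries-class].
#' @export
writeAnesthesiaCsv <- function(series, path) {
  write.csv(data.frame(timestamp_s = series@timestamps,
                       et_sevo_pct = series@et_sevo),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnesthesiaCsv
#' @export
readAnesthesiaCsv <- function(path) {
  df <- read.csv(path)
  if (!all(c("timestamp_s", "et_sevo_pct") %in% names(df)))
    stop("anesthesia CSV must have columns timestamp_s, et_sevo_pct")
  AnesthesiaSeries(df$timestamp_s, df$et_sevo_pct)
}

#' Synchronize SSEP trials with concentration readings
#'
#' Matches each trial to the nearest-in-time end-tidal reading. Trials whose
#' nearest reading is farther than `tolerance` seconds are excluded (and
#' counted in the `n_excluded` attribute and a message). Ties exactly midway
#' between two readings resolve to the earlier reading. The matched
#' concentration is always a verbatim member of the series — no
#' interpolation. Output is sorted by trial timestamp.
#'
#' @param session a [PatientSession-class]
#' @param tolerance maximum |trial time - reading time| in seconds
#' @return a list of synced trials, each a list with elements `trial`
#'   ([SSEPTrial-class]) and `concentration` (%); attribute `n_excluded`
#'   counts dropped trials.
#' @export
synchronizeTrials <- function(session, tolerance = 60) {
  ts_r <- session@anesthesia@timestamps
  if (length(ts_r) == 0) stop("anesthesia series is empty")
  conc <- session@anesthesia@et_sevo
  out <- list()
  n_excl <- 0L
  ord <- order(vapply(session@trials, slot, numeric(1), name = "timestamp"))
  for (tr in session@trials[ord]) {
    d <- abs(ts_r - tr@timestamp)
    j <- which.min(d)            # which.min takes the first (earlier) on ties
    if (d[j] <= tolerance) {
      out[[length(out) + 1L]] <- list(trial = tr, concentration = conc[j])
    } else {
      n_excl <- n_excl + 1L
    }
  }
  if (n_excl > 0)
    message(n_excl, " trial(s) excluded: no reading within ",
            tolerance, " s")
  attr(out, "n_excluded") <- n_excl
  out
}
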