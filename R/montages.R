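# Nerve/montage registry. Montage strings follow the active-reference
# electrode naming of the 10-20 system; CS5 is the subcortical lead at C5.

.NERVES <- c("left_ulnar", "right_ulnar", "left_post_tibial", "right_post_tibial")

.MONTAGES <- list(
  left_ulnar        = c("CP4-Fpz", "CP4-CP3", "CS5-Fpz"),
  right_ulnar       = c("CP3-Fpz", "CP3-CP4", "CS5-Fpz"),
  left_post_tibial  = c("CPz-Fpz", "CP3-CP4", "CP3-Fpz"),
  right_post_tibial = c("CPz-Fpz", "CP4-CP3", "CP4-Fpz")
)

#' Monitored nerves and their recording montages
#'
#' Four nerves are monitored per patient (left/right ulnar, left/right
#' posterior tibial); each is recorded on three fixed scalp montages. The
#' ulnar nerves carry two cortical channels plus the subcortical CS5-Fpz
#' channel; the posterior tibial nerves carry three cortical channels.
#'
#' @return `monitoredNerves()` returns the four nerve identifiers;
#'   `nerveMontages(nerve)` the three montage strings of one nerve.
#' @examples
#' monitoredNerves()
#' nerveMontages("left_ulnar")
#' @export
monitoredNerves <- function() .NERVES

#' @rdname monitoredNerves
#' @param nerve one of [monitoredNerves()]
#' @export
nerveMontages <- function(nerve) {
  nerve <- match.arg(nerve, .NERVES)
  .MONTAGES[[nerve]]
}

# Channel class determines which evoked components a montage carries:
# cortical ulnar -> N20/P30, subcortical ulnar (CS5-Fpz) -> N13/P14,
# all tibial montages -> P37/N45.
#' Channel class of a nerve/montage pair
#'
#' @param nerve nerve identifier
#' @param montage montage string, must belong to the nerve's montage set
#' @return `"cortical_ulnar"`, `"subcortical_ulnar"` or `"tibial"`
#' @export
channelClass <- function(nerve, montage) {
  nerve <- match.arg(nerve, .NERVES)
  if (!montage %in% .MONTAGES[[nerve]]) {
    stop("unknown nerve/montage pairing: ", nerve, " / ", montage,
         " (allowed: ", paste(.MONTAGES[[nerve]], collapse = ", "), ")")
  }
  if (grepl("tibial", nerve)) return("tibial")
  if (montage == "CS5-Fpz") return("subcortical_ulnar")
  "cortical_ulnar"
}
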