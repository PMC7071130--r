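#' Canonical 12-lead order
#'
#' All signal matrices in the package use the fixed row order
#' I, II, III, aVR, aVL, aVF, V1--V6. File readers reorder whatever channel
#' order they find into this one; Frank (vx/vy/vz) or other extra channels
#' are dropped.
#'
#' @return Character vector of the 12 canonical lead names.
#' @export
#' @examples
#' ecg_leads()
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# Case-insensitive match of arbitrary channel names to the canonical leads.
# Returns an integer vector: for each canonical lead, the index of the
# matching input channel (NA when absent).
match_leads <- function(names) {
  canon <- tolower(ecg_leads())
  match(canon, tolower(trimws(names)))
}
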