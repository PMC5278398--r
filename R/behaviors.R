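#' Behavior classes
#'
#' The six behavior classes sensed at the glasses hinges, in their fixed
#' label order: natural head movement (NHM, label 1), left chewing (LC, 2),
#' right chewing (RC, 3), left wink (LW, 4), right wink (RW, 5) and
#' talking (TK, 6).
#'
#' @return Character vector of the six class codes in label order.
#' @export
behavior_codes <- function() {
  c("NHM", "LC", "RC", "LW", "RW", "TK")
}

#' Integer label of a behavior code
#'
#' @param code character vector of class codes.
#' @return Integer labels in 1..6.
#' @export
behavior_label <- function(code) {
  idx <- match(code, behavior_codes())
  if (anyNA(idx)) {
    stop("unknown behavior code: ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Coerce labels to a factor over the six behavior classes
#'
#' @param x character vector of class codes.
#' @return Factor with levels in the fixed class order.
#' @export
behavior_factor <- function(x) {
  behavior_label(as.character(x)) # validates
  factor(as.character(x), levels = behavior_codes())
}

#' Food texture classes
#'
#' Chewing amplitude and burst irregularity depend on food texture. Three
#' regimes are modelled: bread (soft), potato chip (hard/crispy, largest
#' force amplitude), jelly (soft/tacky, smallest amplitude). The study
#' describes the textures qualitatively; the scalars here are the
#' generator's defaults.
#'
#' @param code one of `"bread"`, `"chip"`, `"jelly"`.
#' @param amplitude_scale positive multiplier on chewing force amplitude.
#' @param burst_irregularity nonnegative per-cycle amplitude jitter (as a
#'   coefficient of variation).
#' @return An object of class `texture_class`.
#' @export
texture_class <- function(code = c("bread", "chip", "jelly"),
                          amplitude_scale = NULL,
                          burst_irregularity = NULL) {
  code <- match.arg(code)
  defaults <- list(
    bread = c(amp = 1.0, irr = 0.20),
    chip  = c(amp = 1.3, irr = 0.35),
    jelly = c(amp = 0.7, irr = 0.15)
  )[[code]]
  if (is.null(amplitude_scale)) amplitude_scale <- unname(defaults["amp"])
  if (is.null(burst_irregularity)) burst_irregularity <- unname(defaults["irr"])
  stopifnot(amplitude_scale > 0, burst_irregularity >= 0)
  structure(list(code = code,
                 amplitude_scale = amplitude_scale,
                 burst_irregularity = burst_irregularity),
            class = "texture_class")
}
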