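#' MaqFACS action-unit vocabulary
#'
#' The 17 action units (AUs) coded in the macaque adaptation of the Facial
#' Action Coding System, together with the face region each movement acts
#' on. Three special codes are used in event streams but are never part of
#' the expressivity vocabulary: `AUX` (face out of sight; coding paused),
#' `AD50a` (feeding/mastication descriptor) and `AU43` (eyes closed;
#' excluded as sleep-related rather than communicative).
#'
#' @return A data.frame with columns `code` (character) and `region`
#'   (one of `"upper"`, `"lower"`, `"ears"`), 17 rows.
#' @export
#' @examples
#' v <- maqfacs_vocabulary()
#' nrow(v)           # 17
#' table(v$region)
maqfacs_vocabulary <- function() {
  data.frame(
    code = c("AU27", "AU9+10", "AU10", "AU16", "AU12", "AU25", "AU18i",
             "AU6", "AU8", "AU26", "AD181", "EAU2", "EAU3", "EAU1",
             "AU41", "AU1+2", "AU18ii"),
    region = c("lower", "lower", "lower", "lower", "lower", "lower",
               "lower", "upper", "lower", "lower", "lower", "ears",
               "ears", "ears", "upper", "upper", "lower"),
    stringsAsFactors = FALSE
  )
}

# Special codes that may appear in an event stream alongside the vocabulary.
.special_codes <- c("AUX", "AD50a", "AU43")

#' Default behavioural context labels
#'
#' Contexts in which facial behaviour is coded, used to nest expressivity
#' measures so unequal observation of contexts across individuals does not
#' bias the final scores.
#'
#' @return Character vector of context labels.
#' @export
default_contexts <- function() {
  c("affiliative_social", "aggressive_social",
    "affiliative_observer", "aggressive_observer",
    "low_vigilance", "high_vigilance")
}
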