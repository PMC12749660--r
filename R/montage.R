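#' Standard 10-20 montage used throughout the package
#'
#' Ordered channel names of the 21-electrode 10-20 gel-cap montage. Older
#' temporal names are the canonical form here; [canonical_labels()] maps the
#' modern synonyms (T7/T8/P7/P8) onto them.
#'
#' @return Character vector of 21 channel names.
#' @export
#' @examples
#' montage_1020()
montage_1020 <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "Oz", "O2")
}

# Modern 10-10 temporal names -> legacy 10-20 names.
.label_synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Canonicalize EEG channel labels
#'
#' Maps the modern temporal-chain names (T7, T8, P7, P8) to their legacy
#' 10-20 equivalents (T3, T4, T5, T6) and normalizes case, so recordings from
#' either naming convention align with [montage_1020()].
#'
#' @param labels Character vector of channel names.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' canonical_labels(c("T7", "Cz", "P8"))
canonical_labels <- function(labels) {
  stopifnot(is.character(labels))
  # normalize case: first letter(s) upper, trailing z lower (FZ -> Fz)
  norm <- vapply(labels, function(l) {
    l <- trimws(l)
    sub("Z$", "z", toupper(substr(l, 1, 1)) %strcat%
          toupper(substring(l, 2)))
  }, character(1), USE.NAMES = FALSE)
  norm <- sub("^FP", "Fp", norm)
  hit <- norm %in% names(.label_synonyms)
  norm[hit] <- .label_synonyms[norm[hit]]
  norm
}

`%strcat%` <- function(a, b) paste0(a, b)
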