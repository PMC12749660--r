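#' Canonical EEG frequency bands
#'
#' The seven analysis bands plus the full spectrum, as a tibble so band sets
#' can be filtered and piped into the preprocessing and connectivity stages.
#'
#' @param names Optional character vector restricting to a subset of band
#'   names (order preserved).
#' @return Tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
#' eeg_bands(c("delta", "alpha"))
eeg_bands <- function(names = NULL) {
  b <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "beta3",
             "gamma", "all"),
    lo = c(1, 3, 7, 12, 18, 24, 30, 1),
    hi = c(3, 7, 12, 18, 24, 30, 45, 45)
  )
  if (is.null(names)) return(b)
  unknown <- setdiff(names, b$band)
  if (length(unknown)) {
    abort_field("names", paste("unknown band(s):", paste(unknown, collapse = ", ")))
  }
  b[match(names, b$band), ]
}

#' Construct a single band specification
#'
#' @param name Band name (any label; canonical set in [eeg_bands()]).
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return One-row tibble with columns `band`, `lo`, `hi`.
#' @export
band_spec <- function(name, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo) {
    abort_field("lo/hi", "need 0 < lo < hi")
  }
  tibble::tibble(band = as.character(name), lo = lo, hi = hi)
}
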