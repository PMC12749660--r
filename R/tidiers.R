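#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for ordination results
#'
#' `tidy()` returns the embedded sample coordinates; `glance()` gives a
#' one-row summary of the eigenstructure.
#'
#' @param x A `gb_pcoa` object from [pcoa_ord()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy gb_pcoa
tidy.gb_pcoa <- function(x, ...) x$coordinates

#' @rdname tidy.gb_pcoa
#' @export
#' @method glance gb_pcoa
glance.gb_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_eig = sum(x$eigenvalues > 1e-10),
    n_negative_eig = sum(x$eigenvalues < -1e-10),
    explained_pc1 = x$explained[1],
    explained_pc2 = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}
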