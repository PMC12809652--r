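#' Construct a spectrum
#'
#' A spectrum pairs a strictly increasing wavenumber axis (cm^-1) with an
#' intensity vector of the same length, plus free-form provenance metadata
#' (sample id, processing stage, ...).
#'
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `axis`.
#' @param meta Named list of provenance labels.
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' s <- spectrum(400:500, rnorm(101))
#' length(s$intensity)
spectrum <- function(axis, intensity, meta = list()) {
  if (!is.numeric(axis) || !is.numeric(intensity)) {
    stop("axis and intensity must be numeric", call. = FALSE)
  }
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have equal length", call. = FALSE)
  }
  if (anyNA(axis) || anyNA(intensity) || any(!is.finite(axis)) || any(!is.finite(intensity))) {
    stop("axis and intensity must be finite", call. = FALSE)
  }
  if (length(axis) > 1L && any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing", call. = FALSE)
  }
  structure(list(axis = as.numeric(axis), intensity = as.numeric(intensity),
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, %.1f-%.1f cm^-1", length(x$axis),
              min(x$axis), max(x$axis)))
  if (!is.null(x$meta$stage)) cat(sprintf(" [stage: %s]", x$meta$stage))
  cat("\n")
  invisible(x)
}

check_common_axis <- function(s1, s2, what = "spectra") {
  if (length(s1$axis) != length(s2$axis) ||
      any(abs(s1$axis - s2$axis) > 1e-9)) {
    stop(sprintf("%s must share a common wavenumber axis", what), call. = FALSE)
  }
  invisible(TRUE)
}
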