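# Ratiometric color assignment: dyes with overlapping emission spectra are
# identified from the photon split between two spectral channels, either by
# thresholding the normalized ratio r = (I1 - I2)/(I1 + I2) or by refitting
# with each dye's fixed photon ratio and keeping the maximum-likelihood
# hypothesis.

#' Normalized photon ratio between the bright and dark channel
#'
#' @param I1 photons in the bright channel.
#' @param I2 photons in the dark channel.
#' @return `r = (I1 - I2) / (I1 + I2)`, in \[-1, 1\] for non-negative
#'   inputs; antisymmetric under channel swap.
#' @export
normalized_ratio <- function(I1, I2) {
  s <- I1 + I2
  if (any(s <= 0)) stop("undefined ratio: I1 + I2 must be positive")
  (I1 - I2) / s
}

#' Noiseless normalized ratio implied by a dye's photon ratio
#' @param r_dye the dye's I2/I1 ratio.
#' @export
ratio_from_dye <- function(r_dye) (1 - r_dye) / (1 + r_dye)

#' Default threshold boundaries for a dye ratio set
#'
#' Midpoints between the noiseless normalized ratios of adjacent dyes,
#' sorted ascending.
#'
#' @param ratios a [dye_ratio_set()] or numeric I2/I1 ratios.
#' @export
default_boundaries <- function(ratios) {
  if (is.data.frame(ratios)) ratios <- ratios$r
  rv <- sort(ratio_from_dye(ratios))
  (rv[-1] + rv[-length(rv)]) / 2
}

#' Classify a molecule by thresholding the normalized ratio
#'
#' Interval membership against sorted boundaries; dyes are indexed from
#' the highest-`r` interval (i.e. the brightest-channel-dominated dye is
#' dye 1). An optional rejection band around each boundary marks ambiguous
#' molecules as rejected. A ratio exactly on a boundary (bands disabled)
#' falls into the lower interval.
#'
#' @param r normalized ratio(s).
#' @param boundaries sorted ascending cut positions.
#' @param reject_halfwidth half-width of the rejection band (0 disables).
#' @return integer dye index (1 = highest ratio interval), `NA` for
#'   rejected molecules.
#' @export
classify_threshold <- function(r, boundaries, reject_halfwidth = 0) {
  stopifnot(!is.unsorted(boundaries))
  k <- length(boundaries) + 1L
  idx <- k - findInterval(r, boundaries, left.open = TRUE)
  if (reject_halfwidth > 0) {
    near <- vapply(r, function(ri)
      any(abs(ri - boundaries) <= reject_halfwidth), logical(1))
    idx[near] <- NA_integer_
  }
  idx
}

#' Maximum-likelihood color assignment from a fixed-ratio deviance table
#'
#' The winning dye minimizes the Poisson deviance; ties break to the first
#' dye. The confidence is the deviance margin to the runner-up. No
#' rejection band is needed.
#'
#' @param chi2_table matrix of per-molecule (rows) per-dye (columns)
#'   deviances, as returned by [fit_fixed_ratio()].
#' @return data.frame with `dye_index`, `dye` (column name), `margin`.
#' @export
classify_ml <- function(chi2_table) {
  chi2_table <- as.matrix(chi2_table)
  if (ncol(chi2_table) < 1 || nrow(chi2_table) < 1)
    stop("empty deviance table")
  idx <- apply(chi2_table, 1, which.min)
  margin <- vapply(seq_len(nrow(chi2_table)), function(r) {
    v <- sort(chi2_table[r, ])
    if (length(v) > 1) v[2] - v[1] else Inf
  }, numeric(1))
  data.frame(dye_index = idx,
             dye = colnames(chi2_table)[idx],
             margin = margin)
}
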