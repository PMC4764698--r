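#' Default recording montage
#'
#' Channel set used by the synthetic recording generator: the midline 10-20
#' sites spanning both analysis ROIs (AFz..Oz), representative lateral
#' frontal/central/parietal sites, the prefrontal pair that picks up blink
#' activity, and bipolar vertical/horizontal EOG channels. The anterior and
#' posterior ROI electrodes are always present.
#'
#' @return Character vector of channel labels; EOG channels carry the
#'   attribute `eog`.
#' @export
default_montage <- function() {
  ch <- c("Fp1", "Fp2", "AFz", "Fz", "F3", "F4", "FCz", "Cz", "C3", "C4",
          "CPz", "Pz", "P3", "P4", "POz", "Oz", "VEOG", "HEOG")
  attr(ch, "eog") <- c("VEOG", "HEOG")
  ch
}

#' Analysis regions of interest
#'
#' The two four-electrode midline ROIs on which difference waves are
#' quantified: anterior (AFz, Fz, FCz, Cz) for MMN and P3a, posterior (CPz,
#' Pz, POz, Oz) for P3b.
#'
#' @return Named list of electrode label vectors.
#' @export
roi_spec <- function() {
  list(anterior  = c("AFz", "Fz", "FCz", "Cz"),
       posterior = c("CPz", "Pz", "POz", "Oz"))
}

## Fixed scalp weight maps. Anterior components peak at FCz and fall off with
## distance; posterior (P3b) peaks at Pz. Each map is normalised so that the
## mean weight over its own ROI's four electrodes is exactly 1: a component's
## amplitude parameter is then on the same scale as the ROI-averaged values
## reported for it. Cross-ROI leakage is deliberately zero (idealised,
## non-overlapping topographies) so that each ROI measures only its own
## components.
topography_map <- function(which = c("anterior", "posterior", "blink"),
                           channels = default_montage()) {
  which <- match.arg(which)
  w <- setNames(numeric(length(channels)), channels)
  if (which == "anterior") {
    raw <- c(Fp1 = 0.50, Fp2 = 0.50, AFz = 0.90, Fz = 0.97, F3 = 0.70,
             F4 = 0.70, FCz = 1.00, Cz = 0.93, C3 = 0.55, C4 = 0.55)
    roi <- roi_spec()$anterior
  } else if (which == "posterior") {
    raw <- c(CPz = 0.85, Pz = 1.00, P3 = 0.70, P4 = 0.70, POz = 0.90,
             Oz = 0.65)
    roi <- roi_spec()$posterior
  } else {
    raw <- c(VEOG = 1.00, HEOG = 0.35, Fp1 = 0.40, Fp2 = 0.40, AFz = 0.40,
             Fz = 0.20, F3 = 0.20, F4 = 0.20)
    roi <- NULL
  }
  hit <- intersect(names(raw), channels)
  w[hit] <- raw[hit]
  if (!is.null(roi)) {
    if (!all(roi %in% channels))
      stop("configuration error: montage lacks ROI electrodes")
    w <- w / mean(w[roi])
  }
  w
}
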