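#' Classifier configuration for tight / loose / balanced groups
#'
#' Border-cell groups are categorised from two morphometric axes: the
#' protrusion area fraction (protrusion area / total group area) and the
#' supracellular cable discontinuity (broken rim length / total rim length).
#' A *tight* group has a protrusion area fraction below 10% and a cable
#' discontinuity of at most 8%; a *loose* group has a fraction above 25% and
#' a discontinuity of at least 25%; a *balanced* group sits between the two
#' on both axes (fraction in \[10%, 25%\], discontinuity strictly between 8%
#' and 25%). Combinations outside these bands (e.g. few protrusions but a
#' badly broken cable) are reported as `"unclassified"` rather than being
#' forced into a category.
#'
#' @param tight_max_protrusion_frac exclusive upper protrusion-area bound for
#'   "tight" (default 0.10).
#' @param tight_max_discontinuity inclusive upper cable-discontinuity bound
#'   for "tight" (default 0.08).
#' @param loose_min_protrusion_frac exclusive lower protrusion-area bound for
#'   "loose" (default 0.25).
#' @param loose_min_discontinuity inclusive lower cable-discontinuity bound
#'   for "loose" (default 0.25).
#' @return an object of class `classifier_config`.
#' @export
#' @examples
#' cfg <- classifier_config()
#' classify_group(0.05, 0.05, cfg)  # "tight"
classifier_config <- function(tight_max_protrusion_frac = 0.10,
                              tight_max_discontinuity = 0.08,
                              loose_min_protrusion_frac = 0.25,
                              loose_min_discontinuity = 0.25) {
  for (v in c(tight_max_protrusion_frac, tight_max_discontinuity,
              loose_min_protrusion_frac, loose_min_discontinuity))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("classifier thresholds must be single values in [0, 1]")
  if (tight_max_protrusion_frac >= loose_min_protrusion_frac ||
      tight_max_discontinuity >= loose_min_discontinuity)
    stop("tight bounds must lie below loose bounds on both axes")
  structure(list(tight_max_protrusion_frac = tight_max_protrusion_frac,
                 tight_max_discontinuity = tight_max_discontinuity,
                 loose_min_protrusion_frac = loose_min_protrusion_frac,
                 loose_min_discontinuity = loose_min_discontinuity),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("Border-cell group classifier\n")
  cat(sprintf("  tight:    frac < %.3g  and  disc <= %.3g\n",
              x$tight_max_protrusion_frac, x$tight_max_discontinuity))
  cat(sprintf("  loose:    frac > %.3g  and  disc >= %.3g\n",
              x$loose_min_protrusion_frac, x$loose_min_discontinuity))
  cat(sprintf("  balanced: %.3g <= frac <= %.3g  and  %.3g < disc < %.3g\n",
              x$tight_max_protrusion_frac, x$loose_min_protrusion_frac,
              x$tight_max_discontinuity, x$loose_min_discontinuity))
  invisible(x)
}

#' Classify a border-cell group as tight, loose, balanced or unclassified
#'
#' Vectorised over its first two arguments. The threshold inclusivities
#' follow the printed definitions exactly: tight requires
#' `frac < 0.10 & disc <= 0.08`; loose requires `frac > 0.25 & disc >= 0.25`;
#' balanced requires `0.10 <= frac <= 0.25 & 0.08 < disc < 0.25`. Every
#' other combination is `"unclassified"`.
#'
#' @param protrusion_area_fraction numeric in \[0, 1\].
#' @param cable_discontinuity numeric in \[0, 1\].
#' @param cfg a [classifier_config()].
#' @return character vector of categories.
#' @export
classify_group <- function(protrusion_area_fraction, cable_discontinuity,
                           cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  f <- protrusion_area_fraction
  d <- cable_discontinuity
  if (any(!is.finite(f)) || any(!is.finite(d)) ||
      any(f < 0 | f > 1) || any(d < 0 | d > 1))
    stop("protrusion_area_fraction and cable_discontinuity must be in [0, 1]")
  n <- max(length(f), length(d))
  f <- rep_len(f, n); d <- rep_len(d, n)
  out <- rep("unclassified", n)
  out[f < cfg$tight_max_protrusion_frac & d <= cfg$tight_max_discontinuity] <- "tight"
  out[f > cfg$loose_min_protrusion_frac & d >= cfg$loose_min_discontinuity] <- "loose"
  out[f >= cfg$tight_max_protrusion_frac & f <= cfg$loose_min_protrusion_frac &
      d >  cfg$tight_max_discontinuity  & d <  cfg$loose_min_discontinuity] <- "balanced"
  out
}
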