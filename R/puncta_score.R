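#' Tunable parameters of the punctate-localization score
#'
#' The score's defaults encode the published procedure: the baseline is
#' the mean intensity of the nuclear pixels ranking below the bottom 40%
#' cutoff (equivalently, excluding the brightest 60%), the detection
#' threshold is 1.5 times that baseline, and positivity is judged on the
#' mean of a pixel and the 8 pixels surrounding it.
#'
#' `baseline_mode` selects how the dim-pixel cutoff is derived:
#' \describe{
#'   \item{`"percentile"`}{(default) rank-based: the cutoff is the
#'     `ceiling(f * n)`-th smallest nuclear intensity, so the baseline
#'     averages the dimmest fraction `f` of pixels (those strictly below
#'     the cutoff).}
#'   \item{`"max_fraction"`}{the cutoff is `(1 - f)` times the maximum
#'     nuclear intensity (with the default `f = 0.4`, 60% of the max) —
#'     an alternative reading of "below the top 60% intensity".}
#' }
#' In either mode, if no pixel lies strictly below the cutoff (e.g. a
#' uniform nucleus), the baseline falls back to the mean of pixels at or
#' below the cutoff, which is never empty.
#'
#' @param baseline_fraction Fraction `f` in (0, 1] of dim pixels
#'   defining the baseline (default 0.40).
#' @param baseline_mode `"percentile"` or `"max_fraction"` (see above).
#' @param threshold_multiplier Multiplier `k > 0` applied to the
#'   baseline to obtain the detection threshold (default 1.5).
#' @param neighborhood_radius Chebyshev radius of the square averaging
#'   window; the default 1 gives the 3x3 window (a pixel and its 8
#'   neighbors). `0` compares single-pixel intensities.
#' @param strict_comparison If `TRUE` (default) a window mean must
#'   strictly exceed the threshold; if `FALSE`, equal means also count.
#' @return An object of class `puncta_params`.
#' @export
puncta_params <- function(baseline_fraction = 0.40,
                          baseline_mode = c("percentile", "max_fraction"),
                          threshold_multiplier = 1.5,
                          neighborhood_radius = 1L,
                          strict_comparison = TRUE) {
  baseline_mode <- match.arg(baseline_mode)
  if (!(baseline_fraction > 0 && baseline_fraction <= 1)) {
    stop("baseline_fraction must be in (0, 1]")
  }
  if (threshold_multiplier <= 0) stop("threshold_multiplier must be > 0")
  if (neighborhood_radius < 0) stop("neighborhood_radius must be >= 0")
  structure(
    list(baseline_fraction = as.numeric(baseline_fraction),
         baseline_mode = baseline_mode,
         threshold_multiplier = as.numeric(threshold_multiplier),
         neighborhood_radius = as.integer(neighborhood_radius),
         strict_comparison = isTRUE(strict_comparison)),
    class = "puncta_params"
  )
}

#' Dim-pixel cutoff of a nuclear intensity distribution
#'
#' In `"percentile"` mode the cutoff is the order statistic separating
#' the dimmest fraction `f` of pixels: the `m`-th smallest intensity
#' with `m = ceiling(f * n)`. In `"max_fraction"` mode it is
#' `(1 - f) * max(intensities)`.
#'
#' @param intensities Non-empty numeric vector of nuclear pixel
#'   intensities.
#' @param f Fraction in (0, 1].
#' @param mode `"percentile"` or `"max_fraction"`.
#' @return The cutoff intensity (scalar).
#' @examples
#' baseline_cutoff(1:10, 0.4)   # 4
#' @export
baseline_cutoff <- function(intensities, f = 0.40,
                            mode = c("percentile", "max_fraction")) {
  mode <- match.arg(mode)
  if (length(intensities) == 0L) stop("intensities must be non-empty")
  if (!(f > 0 && f <= 1)) stop("f must be in (0, 1]")
  if (mode == "percentile") {
    m <- ceiling(f * length(intensities))
    sort(intensities, method = "quick")[m]
  } else {
    (1 - f) * max(intensities)
  }
}

#' Baseline: mean intensity of the dim nuclear pixels
#'
#' The mean of intensities strictly below [baseline_cutoff()]. If that
#' set is empty (uniform or near-uniform nuclei), falls back to the mean
#' of intensities at or below the cutoff, which always exists. The
#' detection threshold is `threshold_multiplier` times this value.
#'
#' @inheritParams baseline_cutoff
#' @return The baseline intensity `B` (scalar).
#' @examples
#' baseline_mean(1:10, 0.4)        # mean(1:3) = 2
#' baseline_mean(rep(5, 3), 0.4)   # fallback: 5
#' @export
baseline_mean <- function(intensities, f = 0.40,
                          mode = c("percentile", "max_fraction")) {
  cutoff <- baseline_cutoff(intensities, f, mode)
  dim_px <- intensities[intensities < cutoff]
  if (length(dim_px) == 0L) dim_px <- intensities[intensities <= cutoff]
  mean(dim_px)
}

# Window sums and counts over the square (2r+1)^2 neighborhood,
# restricted to mask pixels. Computed by shifting the masked image, so
# boundary pixels simply average over fewer in-mask neighbors.
masked_window_means <- function(values, mask, radius) {
  h <- nrow(values)
  w <- ncol(values)
  vals <- values * mask
  wsum <- matrix(0, h, w)
  wcnt <- matrix(0, h, w)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      sr <- max(1, 1 - dr):min(h, h - dr)
      sc <- max(1, 1 - dc):min(w, w - dc)
      wsum[sr, sc] <- wsum[sr, sc] + vals[sr + dr, sc + dc]
      wcnt[sr, sc] <- wcnt[sr, sc] + mask[sr + dr, sc + dc]
    }
  }
  means <- wsum / pmax(wcnt, 1)
  means[wcnt == 0] <- NA_real_
  means
}

# Shared worker: threshold + neighborhood test on one region, on a
# cropped sub-image for speed.
score_region <- function(marker, region, params) {
  bbox <- region$bbox
  r <- params$neighborhood_radius
  r0 <- max(1L, bbox[1] - r); c0 <- max(1L, bbox[2] - r)
  r1 <- min(nrow(marker), bbox[3] + r); c1 <- min(ncol(marker), bbox[4] + r)
  sub <- marker[r0:r1, c0:c1, drop = FALSE]
  mask <- matrix(0, nrow(sub), ncol(sub))
  local_coords <- cbind(region$pixel_coords[, 1] - r0 + 1L,
                        region$pixel_coords[, 2] - c0 + 1L)
  mask[local_coords] <- 1

  intensities <- sub[local_coords]
  B <- baseline_mean(intensities, params$baseline_fraction,
                     params$baseline_mode)
  Tthr <- params$threshold_multiplier * B

  means <- masked_window_means(sub, mask, r)
  region_means <- means[local_coords]
  pos <- if (params$strict_comparison) region_means > Tthr else
    region_means >= Tthr
  pos[is.na(pos)] <- FALSE

  list(baseline = B, threshold = Tthr,
       positive_local = local_coords[pos, , drop = FALSE],
       positive_global = region$pixel_coords[pos, , drop = FALSE],
       positive_sum = sum(sub[local_coords[pos, , drop = FALSE]]),
       nucleus_mean = mean(intensities))
}

#' Positive pixels of one nucleus
#'
#' A nuclear pixel is positive when the mean marker intensity over its
#' square neighborhood (default 3x3: the pixel and the 8 pixels
#' surrounding it), restricted to pixels of the same nuclear region,
#' exceeds the adaptive threshold `k * B`. At the nuclear boundary the
#' window simply contains fewer pixels; intensities outside the region
#' never enter the mean.
#'
#' @param marker Numeric matrix, the marker channel.
#' @param region A `nucleus_region` (see [segment_nuclei()]).
#' @param params A [puncta_params()].
#' @return An n x 2 matrix of (row, col) coordinates of positive pixels,
#'   a subset of the region's pixel set.
#' @export
positive_pixels <- function(marker, region, params = puncta_params()) {
  check_region_in_image(marker, region)
  score_region(marker, region, params)$positive_global
}

check_region_in_image <- function(marker, region) {
  if (!is.matrix(marker) || !is.numeric(marker)) {
    stop("marker must be a 2-D numeric matrix")
  }
  if (region$area == 0L) stop("region is empty")
  pc <- region$pixel_coords
  if (min(pc) < 1L || max(pc[, 1]) > nrow(marker) ||
      max(pc[, 2]) > ncol(marker)) {
    stop("region lies outside the marker image bounds")
  }
  invisible(TRUE)
}

#' Punctate-localization score of one nucleus
#'
#' Computes the per-nucleus baseline `B` (mean of the dim nuclear
#' pixels), threshold `T = k * B`, the positive-pixel set (neighborhood
#' means above `T`), and the normalized localization score
#' `S = sum(intensity over positive pixels) / mean(nuclear intensity)`.
#' `S` is dimensionless and invariant under multiplying all nuclear
#' intensities by a positive constant; a nucleus with uniform intensity
#' scores 0. An all-zero nucleus (mean 0) is reported as `S = 0` with
#' `zero_mean = TRUE`.
#'
#' @inheritParams positive_pixels
#' @return A list of class `puncta_score_result`: `nucleus_label`,
#'   `area`, `baseline`, `threshold`, `positive_mask` (coordinate
#'   matrix), `positive_count`, `positive_sum`, `nucleus_mean`, `score`,
#'   `zero_mean`.
#' @examples
#' img <- matrix(1, 5, 5); img[3, 3] <- 100
#' reg <- structure(list(label = 1L,
#'                       pixel_coords = as.matrix(expand.grid(row = 1:5,
#'                                                            col = 1:5)),
#'                       area = 25L, bbox = c(1L, 1L, 5L, 5L),
#'                       touches_border = TRUE),
#'                  class = "nucleus_region")
#' res <- nucleus_score(img, reg)
#' res$score   # 108 / 4.96
#' @export
nucleus_score <- function(marker, region, params = puncta_params()) {
  check_region_in_image(marker, region)
  sr <- score_region(marker, region, params)
  zero_mean <- sr$nucleus_mean == 0
  if (zero_mean) {
    warning("nucleus ", region$label,
            " has zero mean intensity; score set to 0")
  }
  score <- if (zero_mean) 0 else sr$positive_sum / sr$nucleus_mean
  structure(
    list(nucleus_label = region$label,
         area = region$area,
         baseline = sr$baseline,
         threshold = sr$threshold,
         positive_mask = sr$positive_global,
         positive_count = nrow(sr$positive_global),
         positive_sum = sr$positive_sum,
         nucleus_mean = sr$nucleus_mean,
         score = score,
         zero_mean = zero_mean),
    class = "puncta_score_result"
  )
}

#' Score every nucleus of a two-channel field
#'
#' Segments the DAPI channel and applies [nucleus_score()] independently
#' to each resulting region of the marker channel.
#'
#' @param dapi Numeric matrix, the nuclear channel.
#' @param marker Numeric matrix, the marker channel (same shape).
#' @param seg_params A [segmentation_params()].
#' @param puncta_params_ A [puncta_params()].
#' @return A data.frame with one row per nucleus and columns
#'   `nucleus_label`, `area`, `baseline`, `threshold`, `positive_count`,
#'   `positive_sum`, `nucleus_mean`, `score`. Zero nuclei give a
#'   zero-row data.frame.
#' @examples
#' f <- generate_nucleus_field(synth_field_spec(
#'   image_height = 128, image_width = 128, n_nuclei = 3,
#'   nucleus_radius_range = c(8, 10), noise_sd = 0, seed = 2))
#' score_field(f$dapi, f$marker)$score
#' @export
score_field <- function(dapi, marker,
                        seg_params = segmentation_params(),
                        puncta_params_ = puncta_params()) {
  if (!identical(dim(dapi), dim(marker))) {
    stop("dapi and marker must have the same shape")
  }
  seg <- segment_nuclei(dapi, seg_params)
  rows <- lapply(seg$regions, function(reg) {
    res <- nucleus_score(marker, reg, puncta_params_)
    data.frame(nucleus_label = res$nucleus_label,
               area = res$area,
               baseline = res$baseline,
               threshold = res$threshold,
               positive_count = res$positive_count,
               positive_sum = res$positive_sum,
               nucleus_mean = res$nucleus_mean,
               score = res$score)
  })
  if (length(rows) == 0L) {
    return(data.frame(nucleus_label = integer(0), area = integer(0),
                      baseline = numeric(0), threshold = numeric(0),
                      positive_count = integer(0), positive_sum = numeric(0),
                      nucleus_mean = numeric(0), score = numeric(0)))
  }
  do.call(rbind, rows)
}
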