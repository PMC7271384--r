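#' Parameters for DAPI nucleus segmentation
#'
#' The default pipeline is standard DAPI practice: optional Gaussian
#' smoothing, a global Otsu threshold, hole filling, 8-connected
#' labeling, and a minimum-area filter; a distance-transform watershed
#' split of touching nuclei can be enabled. Every step is configurable.
#'
#' @param smoothing_sigma Gaussian smoothing sigma in pixels (`0` = no
#'   smoothing).
#' @param threshold_method `"otsu"` (global Otsu on the smoothed image)
#'   or `"fixed"`.
#' @param fixed_threshold Intensity threshold used when
#'   `threshold_method = "fixed"`.
#' @param min_area Minimum region area in pixels.
#' @param exclude_border Drop regions touching the image border.
#' @param split_touching Apply a watershed on the distance transform to
#'   split touching nuclei.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 50L,
                                exclude_border = FALSE,
                                split_touching = FALSE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(smoothing_sigma >= 0, min_area >= 1)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0)) {
    stop("threshold_method = \"fixed\" requires a non-negative fixed_threshold")
  }
  structure(
    list(smoothing_sigma = as.numeric(smoothing_sigma),
         threshold_method = threshold_method,
         fixed_threshold = if (is.null(fixed_threshold)) NULL else
           as.numeric(fixed_threshold),
         min_area = as.integer(min_area),
         exclude_border = isTRUE(exclude_border),
         split_touching = isTRUE(split_touching)),
    class = "segmentation_params"
  )
}

# 8-connected labeling of a binary mask. EBImage::bwlabel is
# 4-connected; diagonal-adjacent 4-components are merged afterwards
# with a union-find over the (small) label graph.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  union_pairs <- function(a, b) {
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  h <- nrow(lab); w <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {  # the two diagonal directions
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(h - 1L)
    c1 <- if (dc == 1L) seq_len(w - 1L) else 2L:w
    a <- lab[r1, c1]
    b <- lab[r1 + dr, c1 + dc]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) union_pairs(a[sel], b[sel])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

region_from_label <- function(label_map, lab) {
  coords <- which(label_map == lab, arr.ind = TRUE)
  colnames(coords) <- c("row", "col")
  bbox <- c(min(coords[, 1]), min(coords[, 2]),
            max(coords[, 1]), max(coords[, 2]))
  touches <- bbox[1] == 1L || bbox[2] == 1L ||
    bbox[3] == nrow(label_map) || bbox[4] == ncol(label_map)
  structure(
    list(label = as.integer(lab),
         pixel_coords = coords,
         area = nrow(coords),
         bbox = as.integer(bbox),
         touches_border = touches),
    class = "nucleus_region"
  )
}

#' Segment nuclei from a DAPI image
#'
#' Smooths, thresholds, fills holes and labels the DAPI channel, and
#' returns per-nucleus regions. Regions dropped by the area/border
#' filters are removed from the label map as well, and surviving labels
#' are renumbered consecutively, so the label map and region list stay
#' mutually consistent.
#'
#' @param dapi Numeric matrix, the nuclear channel (non-negative).
#' @param params A [segmentation_params()].
#' @return A list with `label_map` (integer matrix, background 0) and
#'   `regions` (list of `nucleus_region`, sorted by label). Each region
#'   holds `label`, `pixel_coords` (n x 2 matrix of 1-based row/col),
#'   `area`, `bbox` (inclusive `c(row_min, col_min, row_max, col_max)`)
#'   and `touches_border`.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:30, 20:30] <- 100
#' seg <- segment_nuclei(img, segmentation_params(smoothing_sigma = 0))
#' length(seg$regions)
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  if (!is.matrix(dapi) || !is.numeric(dapi)) {
    stop("dapi must be a 2-D numeric matrix")
  }
  if (any(dapi < 0)) stop("dapi must be non-negative")
  empty <- list(label_map = matrix(0L, nrow(dapi), ncol(dapi)),
                regions = list())
  peak <- max(dapi)
  if (peak == 0) return(empty)

  img <- dapi
  if (params$smoothing_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = params$smoothing_sigma))
  }
  thr <- if (params$threshold_method == "otsu") {
    rng <- range(img)
    if (rng[1] == rng[2]) return(empty)   # flat image, nothing to threshold
    EBImage::otsu(EBImage::Image(img / rng[2]), range = c(0, 1)) * rng[2]
  } else {
    params$fixed_threshold
  }
  mask <- img > thr
  if (!any(mask)) return(empty)
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1)))

  if (params$split_touching) {
    lab <- EBImage::watershed(EBImage::distmap(mask))
    lab <- matrix(as.integer(round(lab)), nrow(dapi), ncol(dapi))
  } else {
    lab <- label_components8(mask > 0)
  }

  keep <- integer(0)
  regions <- list()
  for (l in seq_len(max(lab))) {
    reg <- region_from_label(lab, l)
    if (reg$area < params$min_area) next
    if (params$exclude_border && reg$touches_border) next
    keep <- c(keep, l)
    regions[[length(regions) + 1L]] <- reg
  }
  # renumber surviving labels consecutively; clear dropped ones
  new_map <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) {
    reg <- regions[[i]]
    new_map[reg$pixel_coords] <- i
    regions[[i]]$label <- i
  }
  list(label_map = new_map, regions = regions)
}

#' Filter a region list by area and border contact
#'
#' Subsets a list of `nucleus_region` objects, preserving order and
#' labels. Unlike [segment_nuclei()] (which renumbers), this is a pure
#' filter for use on an existing segmentation.
#'
#' @param regions List of `nucleus_region` objects.
#' @param min_area Minimum area in pixels.
#' @param exclude_border Drop regions whose `touches_border` flag is set.
#' @param image_shape Optional `c(height, width)`; when given, border
#'   contact is recomputed against this shape instead of trusting the
#'   stored flag.
#' @return The filtered list.
#' @export
filter_regions <- function(regions, min_area = 1L, exclude_border = FALSE,
                           image_shape = NULL) {
  keep <- vapply(regions, function(reg) {
    if (reg$area < min_area) return(FALSE)
    if (exclude_border) {
      touches <- if (is.null(image_shape)) {
        reg$touches_border
      } else {
        reg$bbox[1] == 1L || reg$bbox[2] == 1L ||
          reg$bbox[3] == image_shape[1] || reg$bbox[4] == image_shape[2]
      }
      if (touches) return(FALSE)
    }
    TRUE
  }, logical(1))
  regions[keep]
}
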