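#' Specification of a synthetic two-channel microscopy field
#'
#' Bundles the parameters of the synthetic field generator. The defaults
#' describe a 512x512 field with 20 well-separated elliptical nuclei of
#' radius 12--18 px, so that three fields per condition comfortably
#' provide upwards of 57 scoreable cells, matching the scale at which
#' per-cell localization scores are pooled in practice.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius_range Length-2 numeric, min and max semi-axis
#'   length in pixels; each nucleus draws its two semi-axes independently
#'   and uniformly from this range.
#' @param nucleus_min_separation Minimum gap (pixels) between nuclei in
#'   addition to the sum of their larger semi-axes.
#' @param diffuse_level Marker-channel intensity inside nuclei before
#'   puncta and noise (the diffuse nuclear background).
#' @param dapi_level DAPI-channel intensity inside nuclei.
#' @param puncta_per_nucleus Number of puncta per nucleus: a single count
#'   or a length-2 range sampled uniformly per nucleus.
#' @param punctum_amplitude Peak intensity added above the diffuse level
#'   by each punctum.
#' @param punctum_sigma Gaussian width (pixels) of a punctum; `0` gives a
#'   single-pixel (delta) punctum.
#' @param punctum_min_separation Minimum center-to-center distance in
#'   pixels between puncta of the same nucleus.
#' @param noise_sd Standard deviation of additive Gaussian noise,
#'   truncated at zero (`noise_model = "gaussian"`).
#' @param noise_model `"gaussian"` (additive, truncated at 0) or
#'   `"poisson"` (each pixel drawn as Poisson with mean equal to its
#'   noise-free value).
#' @param seed Integer seed; the generator uses a single RNG stream
#'   seeded from this value.
#'
#' @return An object of class `synth_field_spec` (a validated list).
#' @seealso [generate_nucleus_field()]
#' @export
synth_field_spec <- function(image_height = 512L,
                             image_width = 512L,
                             n_nuclei = 20L,
                             nucleus_radius_range = c(12, 18),
                             nucleus_min_separation = 4,
                             diffuse_level = 40,
                             dapi_level = 120,
                             puncta_per_nucleus = 3L,
                             punctum_amplitude = 400,
                             punctum_sigma = 0,
                             punctum_min_separation = 7,
                             noise_sd = 4,
                             noise_model = c("gaussian", "poisson"),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    image_height >= 8, image_width >= 8,
    n_nuclei >= 0,
    length(nucleus_radius_range) == 2L,
    nucleus_radius_range[1] > 0,
    nucleus_radius_range[2] >= nucleus_radius_range[1],
    nucleus_min_separation >= 0,
    diffuse_level >= 0, dapi_level > 0,
    punctum_amplitude >= 0, punctum_sigma >= 0,
    punctum_min_separation >= 0, noise_sd >= 0,
    length(puncta_per_nucleus) %in% c(1L, 2L),
    all(puncta_per_nucleus >= 0)
  )
  structure(
    list(
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      n_nuclei = as.integer(n_nuclei),
      nucleus_radius_range = as.numeric(nucleus_radius_range),
      nucleus_min_separation = as.numeric(nucleus_min_separation),
      diffuse_level = as.numeric(diffuse_level),
      dapi_level = as.numeric(dapi_level),
      puncta_per_nucleus = as.integer(puncta_per_nucleus),
      punctum_amplitude = as.numeric(punctum_amplitude),
      punctum_sigma = as.numeric(punctum_sigma),
      punctum_min_separation = as.numeric(punctum_min_separation),
      noise_sd = as.numeric(noise_sd),
      noise_model = noise_model,
      seed = as.integer(seed)
    ),
    class = "synth_field_spec"
  )
}

# Pixels whose centers fall inside an axis-aligned ellipse, as an
# n x 2 matrix of (row, col) indices.
rasterize_ellipse <- function(center, semi_axes, image_height, image_width) {
  ry <- semi_axes[1]
  rx <- semi_axes[2]
  rows <- max(1L, floor(center[1] - ry)):min(image_height, ceiling(center[1] + ry))
  cols <- max(1L, floor(center[2] - rx)):min(image_width, ceiling(center[2] + rx))
  dr <- (rows - center[1]) / ry
  dc <- (cols - center[2]) / rx
  inside <- outer(dr^2, dc^2, `+`) <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

max_placement_retries <- 10000L

# Sample non-overlapping ellipse centers/semi-axes by rejection.
place_nuclei <- function(spec) {
  centers <- matrix(numeric(0), ncol = 2)
  axes <- matrix(numeric(0), ncol = 2)  # (ry, rx)
  retries <- 0L
  rr <- spec$nucleus_radius_range
  while (nrow(centers) < spec$n_nuclei) {
    ry <- stats::runif(1, rr[1], rr[2])
    rx <- stats::runif(1, rr[1], rr[2])
    rmax <- max(ry, rx)
    # keep the whole ellipse (plus a 1 px margin) inside the canvas
    cy <- stats::runif(1, ry + 2, spec$image_height - ry - 1)
    cx <- stats::runif(1, rx + 2, spec$image_width - rx - 1)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      rmax_prev <- pmax(axes[, 1], axes[, 2])
      ok <- all(d >= rmax + rmax_prev + spec$nucleus_min_separation)
    }
    if (ok) {
      centers <- rbind(centers, c(cy, cx))
      axes <- rbind(axes, c(ry, rx))
    } else {
      retries <- retries + 1L
      if (retries > max_placement_retries) {
        stop("nucleus placement failed after ", max_placement_retries,
             " retries: cannot satisfy nucleus_min_separation = ",
             spec$nucleus_min_separation, " with ", spec$n_nuclei,
             " nuclei on a ", spec$image_height, "x", spec$image_width,
             " canvas")
      }
    }
  }
  list(centers = centers, axes = axes)
}

# Sample punctum centers from the interior pixels of a nucleus mask
# (>= 1 px inside the boundary) respecting a minimum pairwise distance.
place_puncta <- function(interior, n_puncta, min_sep) {
  if (n_puncta == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  chosen <- matrix(numeric(0), ncol = 2)
  retries <- 0L
  while (nrow(chosen) < n_puncta) {
    cand <- interior[sample.int(nrow(interior), 1L), , drop = TRUE]
    ok <- TRUE
    if (nrow(chosen) > 0) {
      d <- sqrt((chosen[, 1] - cand[1])^2 + (chosen[, 2] - cand[2])^2)
      ok <- all(d >= min_sep)
    }
    if (ok) {
      chosen <- rbind(chosen, cand)
    } else {
      retries <- retries + 1L
      if (retries > max_placement_retries) {
        stop("punctum placement failed after ", max_placement_retries,
             " retries: cannot satisfy punctum_min_separation = ", min_sep,
             " with ", n_puncta, " puncta in a nucleus of ",
             nrow(interior), " interior pixels")
      }
      # a greedy partial set can block all remaining sites; restart it
      if (retries %% 1000L == 0L) chosen <- matrix(numeric(0), ncol = 2)
    }
  }
  storage.mode(chosen) <- "integer"
  colnames(chosen) <- c("row", "col")
  rownames(chosen) <- NULL
  chosen
}

# Interior pixels of a pixel set: those whose full 3x3 neighborhood lies
# inside the set (>= 1 px margin from the boundary).
interior_pixels <- function(coords, image_height, image_width) {
  key <- function(m) (m[, 1] - 1) * image_width + m[, 2]
  inside <- key(coords)
  keep <- rep(TRUE, nrow(coords))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shifted <- cbind(coords[, 1] + dr, coords[, 2] + dc)
      in_canvas <- shifted[, 1] >= 1 & shifted[, 1] <= image_height &
        shifted[, 2] >= 1 & shifted[, 2] <= image_width
      keep <- keep & in_canvas & (key(shifted) %in% inside)
    }
  }
  coords[keep, , drop = FALSE]
}

#' Generate a synthetic two-channel field with known puncta ground truth
#'
#' Simulates a DAPI channel (uniform nuclear intensity) and a marker
#' channel (diffuse nuclear background plus bright sub-nuclear puncta)
#' for a field of non-overlapping elliptical nuclei, with additive noise.
#' Every punctum's position and amplitude is recorded in the returned
#' truth object, so downstream detection can be validated exactly.
#'
#' Nuclei are placed by rejection sampling so that center distances
#' exceed the sum of the larger semi-axes plus
#' `nucleus_min_separation`; punctum centers are drawn from nuclear
#' pixels whose full 3x3 neighborhood lies inside the nucleus (at least
#' 1 px from the boundary) and at least `punctum_min_separation` apart.
#' Placement failure after 10,000 retries raises an error naming the
#' violated constraint.
#'
#' @param spec A [synth_field_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{dapi}{Numeric matrix, the nuclear channel.}
#'     \item{marker}{Numeric matrix, the marker channel.}
#'     \item{truth}{A `synth_field_truth` list: per-nucleus `label`,
#'       `center` (row, col), `semi_axes` (ry, rx), `area`
#'       (rasterized pixel count), `puncta` (matrix of punctum centers)
#'       and `amplitudes`; plus the global `diffuse_level`, `noise_sd`
#'       and `seed`.}
#'   }
#' @examples
#' f <- generate_nucleus_field(synth_field_spec(
#'   image_height = 128, image_width = 128, n_nuclei = 3,
#'   nucleus_radius_range = c(8, 10), noise_sd = 0, seed = 7))
#' dim(f$marker)
#' length(f$truth$nuclei)
#' @export
generate_nucleus_field <- function(spec) {
  stopifnot(inherits(spec, "synth_field_spec"))
  set.seed(spec$seed)
  h <- spec$image_height
  w <- spec$image_width

  dapi <- matrix(0, h, w)
  marker <- matrix(0, h, w)
  placement <- place_nuclei(spec)

  nuclei <- vector("list", spec$n_nuclei)
  for (i in seq_len(spec$n_nuclei)) {
    center <- placement$centers[i, ]
    semi_axes <- placement$axes[i, ]
    coords <- rasterize_ellipse(center, semi_axes, h, w)
    dapi[coords] <- spec$dapi_level
    marker[coords] <- spec$diffuse_level

    n_p <- if (length(spec$puncta_per_nucleus) == 2L) {
      sample(spec$puncta_per_nucleus[1]:spec$puncta_per_nucleus[2], 1L)
    } else {
      spec$puncta_per_nucleus
    }
    interior <- interior_pixels(coords, h, w)
    puncta <- place_puncta(interior, n_p, spec$punctum_min_separation)
    amplitudes <- rep(spec$punctum_amplitude, nrow(puncta))
    marker <- add_puncta(marker, puncta, amplitudes, spec$punctum_sigma)

    nuclei[[i]] <- list(
      label = i, center = center, semi_axes = semi_axes,
      area = nrow(coords), puncta = puncta, amplitudes = amplitudes
    )
  }

  dapi <- add_noise(dapi, spec)
  marker <- add_noise(marker, spec)

  truth <- structure(
    list(nuclei = nuclei, diffuse_level = spec$diffuse_level,
         noise_sd = spec$noise_sd, seed = spec$seed),
    class = "synth_field_truth"
  )
  list(dapi = dapi, marker = marker, truth = truth)
}

add_puncta <- function(marker, puncta, amplitudes, sigma) {
  if (nrow(puncta) == 0L) return(marker)
  h <- nrow(marker)
  w <- ncol(marker)
  if (sigma == 0) {
    for (j in seq_len(nrow(puncta))) {
      marker[puncta[j, 1], puncta[j, 2]] <-
        marker[puncta[j, 1], puncta[j, 2]] + amplitudes[j]
    }
    return(marker)
  }
  half <- ceiling(3 * sigma)
  off <- -half:half
  kernel <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  for (j in seq_len(nrow(puncta))) {
    rows <- puncta[j, 1] + off
    cols <- puncta[j, 2] + off
    rk <- which(rows >= 1 & rows <= h)
    ck <- which(cols >= 1 & cols <= w)
    marker[rows[rk], cols[ck]] <- marker[rows[rk], cols[ck]] +
      amplitudes[j] * kernel[rk, ck]
  }
  marker
}

add_noise <- function(img, spec) {
  if (spec$noise_model == "poisson") {
    matrix(stats::rpois(length(img), lambda = img), nrow(img), ncol(img))
  } else if (spec$noise_sd > 0) {
    pmax(img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                      nrow(img), ncol(img)), 0)
  } else {
    img
  }
}
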