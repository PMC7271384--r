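# Independent brute-force oracles used to validate the production code.
# These deliberately re-derive everything from first principles with
# naive per-pixel loops and set operations; keep them slow and obvious.

# A rectangular all-pixels nucleus region covering rows x cols.
rect_region <- function(rows, cols, label = 1L) {
  coords <- as.matrix(expand.grid(row = rows, col = cols))
  structure(
    list(label = label, pixel_coords = coords, area = nrow(coords),
         bbox = c(min(rows), min(cols), max(rows), max(cols)),
         touches_border = TRUE),
    class = "nucleus_region"
  )
}

# Naive double-loop re-implementation of the per-nucleus statistic.
oracle_score_region <- function(marker, region, f = 0.4, k = 1.5,
                                mode = "percentile", radius = 1L,
                                strict = TRUE) {
  pc <- region$pixel_coords
  in_region <- paste(pc[, 1], pc[, 2])
  ints <- marker[pc]
  cutoff <- if (mode == "percentile") {
    sort(ints)[ceiling(f * length(ints))]
  } else {
    (1 - f) * max(ints)
  }
  dim_px <- ints[ints < cutoff]
  if (length(dim_px) == 0) dim_px <- ints[ints <= cutoff]
  B <- mean(dim_px)
  Tthr <- k * B
  pos <- logical(nrow(pc))
  for (i in seq_len(nrow(pc))) {
    vals <- c()
    for (dr in -radius:radius) {
      for (dc in -radius:radius) {
        key <- paste(pc[i, 1] + dr, pc[i, 2] + dc)
        if (key %in% in_region) {
          vals <- c(vals, marker[pc[i, 1] + dr, pc[i, 2] + dc])
        }
      }
    }
    mu <- mean(vals)
    pos[i] <- if (strict) mu > Tthr else mu >= Tthr
  }
  positive <- pc[pos, , drop = FALSE]
  nuc_mean <- mean(ints)
  list(baseline = B, threshold = Tthr, positive = positive,
       score = if (nuc_mean == 0) 0 else sum(marker[positive]) / nuc_mean)
}

# Canonical string form of a coordinate set, for set-equality asserts.
coord_set <- function(m) sort(paste(m[, 1], m[, 2], sep = ","))

# Count 8-connected components of a coordinate set by breadth-first
# search (independent of the package's labeling code).
count_components8 <- function(coords) {
  if (nrow(coords) == 0) return(0L)
  keys <- paste(coords[, 1], coords[, 2])
  visited <- setNames(rep(FALSE, length(keys)), keys)
  n_comp <- 0L
  for (start in keys) {
    if (visited[[start]]) next
    n_comp <- n_comp + 1L
    queue <- start
    visited[[start]] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      rc <- as.integer(strsplit(cur, " ")[[1]])
      for (dr in -1:1) {
        for (dc in -1:1) {
          nb <- paste(rc[1] + dr, rc[2] + dc)
          if (!is.na(visited[nb]) && !visited[[nb]]) {
            visited[[nb]] <- TRUE
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  n_comp
}

# Student t CDF by direct numerical integration of the density written
# out in closed form (independent of R's pt).
oracle_t_cdf <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, -Inf, t, rel.tol = 1e-12)$value
}

# Small synthetic field used by several oracle-equivalence tests.
small_field_spec <- function(seed, puncta = c(0L, 3L), noise_sd = 3) {
  synth_field_spec(
    image_height = 64L, image_width = 64L, n_nuclei = 3L,
    nucleus_radius_range = c(6, 9), nucleus_min_separation = 3,
    diffuse_level = 40, dapi_level = 120,
    puncta_per_nucleus = puncta, punctum_amplitude = 400,
    punctum_sigma = 0, punctum_min_separation = 7,
    noise_sd = noise_sd, seed = seed
  )
}
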