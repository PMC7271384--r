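#' Read a single-plane grayscale TIFF as a numeric matrix
#'
#' Integer-typed TIFFs are returned losslessly as their raw integer
#' values (stored as doubles); float TIFFs are returned as stored.
#'
#' @param path Path to a TIFF file.
#' @return A 2-D non-negative numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # as.is returns raw integer values for integer TIFFs but is not
  # supported for float TIFFs, which readTIFF already returns as stored
  pages <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (length(pages) != 1L) {
    stop("expected a single-plane TIFF, got ", length(pages), " pages: ", path)
  }
  img <- pages[[1]]
  if (length(dim(img)) != 2L) {
    stop("expected a single-channel grayscale TIFF, got an array of shape ",
         paste(dim(img), collapse = "x"), " (RGB/multi-channel?): ", path)
  }
  storage.mode(img) <- "double"
  img
}

#' Write a numeric matrix as a single-plane TIFF
#'
#' `"uint16"` stores integer values 0..65535 losslessly via
#' [tiff::writeTIFF()]. `"float32"` stores IEEE single-precision floats
#' (values round-trip exactly up to float32 precision); this path
#' writes the strip directly because the tiff package writes integer
#' samples only, while [tiff::readTIFF()] reads float TIFFs natively.
#'
#' @param img 2-D non-negative numeric matrix.
#' @param path Output path.
#' @param format `"uint16"` (values must be integers in 0..65535) or
#'   `"float32"`.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, format = c("uint16", "float32")) {
  format <- match.arg(format)
  stopifnot(is.matrix(img), is.numeric(img), all(img >= 0))
  if (format == "uint16") {
    if (any(img != round(img)) || max(img) > 65535) {
      stop("uint16 output requires integer values in 0..65535; use float32")
    }
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    write_float32_tiff(img, path)
  }
  invisible(path)
}

# Minimal single-strip little-endian TIFF with SampleFormat = IEEE
# float32, uncompressed.
write_float32_tiff <- function(img, path) {
  h <- nrow(img)
  w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  data_bytes <- 4L * h * w
  ifd_offset <- data_offset + data_bytes

  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(42L, con, size = 2, endian = "little")      # TIFF magic
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")  # rows

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  SHORT <- 3L; LONG <- 4L
  writeBin(10L, con, size = 2, endian = "little")      # entry count
  entry(256, LONG, 1, w)            # ImageWidth
  entry(257, LONG, 1, h)            # ImageLength
  entry(258, SHORT, 1, 32)          # BitsPerSample
  entry(259, SHORT, 1, 1)           # Compression: none
  entry(262, SHORT, 1, 1)           # Photometric: BlackIsZero
  entry(273, LONG, 1, data_offset)  # StripOffsets
  entry(277, SHORT, 1, 1)           # SamplesPerPixel
  entry(278, LONG, 1, h)            # RowsPerStrip
  entry(279, LONG, 1, data_bytes)   # StripByteCounts
  entry(339, SHORT, 1, 3)           # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")       # no next IFD
  invisible(path)
}

# CSV writers that round-trip doubles exactly (17 significant digits).
write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a segmentation's region list as a data.frame
#'
#' @param regions List of `nucleus_region` objects.
#' @return Data.frame with columns `label`, `area`, `row_min`,
#'   `col_min`, `row_max`, `col_max`, `touches_border`.
#' @export
regions_as_table <- function(regions) {
  if (length(regions) == 0L) {
    return(data.frame(label = integer(0), area = integer(0),
                      row_min = integer(0), col_min = integer(0),
                      row_max = integer(0), col_max = integer(0),
                      touches_border = logical(0)))
  }
  do.call(rbind, lapply(regions, function(reg) {
    data.frame(label = reg$label, area = reg$area,
               row_min = reg$bbox[1], col_min = reg$bbox[2],
               row_max = reg$bbox[3], col_max = reg$bbox[4],
               touches_border = reg$touches_border)
  }))
}

run_config_schema <- list(
  top = c("seed", "out_dir", "field", "conditions", "segmentation",
          "puncta", "comparison"),
  field = c("image_height", "image_width", "n_nuclei",
            "nucleus_radius_range", "nucleus_min_separation",
            "diffuse_level", "dapi_level", "punctum_amplitude",
            "punctum_sigma", "punctum_min_separation", "noise_sd",
            "noise_model"),
  condition = c("name", "puncta_per_nucleus", "n_fields"),
  segmentation = c("smoothing_sigma", "threshold_method",
                   "fixed_threshold", "min_area", "exclude_border",
                   "split_touching"),
  puncta = c("baseline_fraction", "baseline_mode", "threshold_multiplier",
             "neighborhood_radius", "strict_comparison"),
  comparison = c("variant")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Validate a pipeline run configuration
#'
#' Checks a configuration (a list, or a path to a YAML file) against the
#' pipeline schema: unknown keys are rejected, enum-valued fields are
#' checked, and required fields (`seed`, `out_dir`, at least two
#' `conditions`) must be present. All analysis defaults (baseline
#' fraction 0.40, threshold multiplier 1.5, pseudocount 0.001, discard
#' 0.01, fold 2, alpha 0.05, cytokine fold 1.2) live in their owning
#' functions; the config only overrides them.
#'
#' @param config A list or a YAML file path.
#' @return The validated config list, invisibly on error-free input.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  check_keys(config, run_config_schema$top, "top level")
  if (is.null(config$seed)) stop("config requires a seed")
  if (is.null(config$out_dir)) stop("config requires out_dir")
  if (is.null(config$conditions) || length(config$conditions) < 2L) {
    stop("config requires at least two conditions")
  }
  if (!is.null(config$field)) {
    check_keys(config$field, run_config_schema$field, "field")
  }
  for (cond in config$conditions) {
    check_keys(cond, run_config_schema$condition, "conditions")
    if (is.null(cond$name)) stop("every condition requires a name")
  }
  if (!is.null(config$segmentation)) {
    check_keys(config$segmentation, run_config_schema$segmentation,
               "segmentation")
  }
  if (!is.null(config$puncta)) {
    check_keys(config$puncta, run_config_schema$puncta, "puncta")
    bm <- config$puncta$baseline_mode
    if (!is.null(bm) && !bm %in% c("percentile", "max_fraction")) {
      stop("invalid baseline_mode: ", bm)
    }
  }
  if (!is.null(config$comparison)) {
    check_keys(config$comparison, run_config_schema$comparison, "comparison")
    v <- config$comparison$variant
    if (!is.null(v) && !v %in% c("student", "welch")) {
      stop("invalid comparison variant: ", v)
    }
  }
  invisible(config)
}

#' Run the end-to-end synthetic two-condition pipeline
#'
#' Simulates the configured number of fields per condition, segments
#' each DAPI channel, scores every nucleus of the marker channel, pools
#' per-cell scores within each condition, and compares the conditions
#' with an unpaired two-tailed t test. Deterministic given the config
#' seed (field `i` of condition `j` uses seed
#' `seed * 1000 + j * 100 + i`).
#'
#' Writes to `out_dir`: one `<condition>_scores.csv` per condition,
#' `comparison.json`, and a provenance record (`config_used.yaml`,
#' `provenance.json` with the config file hash, package version and
#' seed).
#'
#' @param config A validated config list or YAML path (see
#'   [validate_run_config()]).
#' @return Invisibly, a list with per-condition score data.frames and
#'   the `group_comparison`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  seg_params <- do.call(segmentation_params,
                        as_list(config$segmentation))
  pp <- do.call(puncta_params, as_list(config$puncta))
  variant <- if (is.null(config$comparison$variant)) "student" else
    config$comparison$variant

  scores <- list()
  for (j in seq_along(config$conditions)) {
    cond <- config$conditions[[j]]
    n_fields <- if (is.null(cond$n_fields)) 3L else as.integer(cond$n_fields)
    per_field <- lapply(seq_len(n_fields), function(i) {
      args <- as_list(config$field)
      if (!is.null(cond$puncta_per_nucleus)) {
        args$puncta_per_nucleus <- cond$puncta_per_nucleus
      }
      args$seed <- as.integer(config$seed) * 1000L + j * 100L + i
      fld <- generate_nucleus_field(do.call(synth_field_spec, args))
      df <- score_field(fld$dapi, fld$marker, seg_params, pp)
      if (nrow(df) > 0) df$field <- i
      df
    })
    df <- do.call(rbind, per_field)
    scores[[cond$name]] <- df
    write_table_csv(df, file.path(config$out_dir,
                                  paste0(cond$name, "_scores.csv")))
  }

  cmp <- compare_groups(scores[[1]]$score, scores[[2]]$score,
                        variant = variant)
  jsonlite::write_json(unclass(cmp),
                       file.path(config$out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = I(17))

  cfg_path <- file.path(config$out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  provenance <- list(
    package = "nucpuncta",
    version = as.character(utils::packageVersion("nucpuncta")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    conditions = vapply(config$conditions, `[[`, character(1), "name")
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = I(17))

  invisible(list(scores = scores, comparison = cmp))
}

as_list <- function(x) if (is.null(x)) list() else x
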