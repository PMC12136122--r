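# Readers and writers for the standard on-disk forms: NIfTI volumes
# (exact float), multi-page TIFF volumes (normalized, scale in a sidecar),
# CSV surface tables, TIFF + CSV en face maps, flat key=value configs.

#' Write / read a volume as NIfTI
#'
#' Exact float storage of one 3-D array; voxel dimensions carry the
#' lateral (mm) and axial (um -> mm) spacing.
#'
#' @param vol 3-D array.
#' @param path Output `.nii` or `.nii.gz` path.
#' @param lateral_spacing_mm,axial_spacing_um Voxel spacing metadata.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, lateral_spacing_mm = 6 / 400,
                               axial_spacing_um = 3) {
  stopifnot(length(dim(vol)) == 3L)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(lateral_spacing_mm, lateral_spacing_mm,
                           axial_spacing_um / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  out <- array(as.numeric(img), dim(img))
  attr(out, "lateral_spacing_mm") <- pd[1]
  attr(out, "axial_spacing_um") <- pd[3] * 1000
  out
}

#' Write / read a volume as multi-page TIFF
#'
#' One page per z slice. TIFF float pages are restricted to `[0, 1]`, so
#' values are divided by a scale factor (the volume maximum) recorded in a
#' `<path>.scale.txt` sidecar and restored on read.
#'
#' @param vol 3-D array, non-negative.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(length(dim(vol)) == 3L, min(vol) >= 0)
  sc <- max(vol, 1e-12)
  pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(format(sc, digits = 17), paste0(path, ".scale.txt"))
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sc_file <- paste0(path, ".scale.txt")
  sc <- if (file.exists(sc_file)) as.numeric(readLines(sc_file)) else 1
  out <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]]
  out * sc
}

#' Write / read a surface set as CSV
#'
#' Long table with 0-based voxel indices: `x_index`, `y_index`, `ilm_z`,
#' `nflgcl_z`, `iplinl_z`.
#'
#' @param s A [surface_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surfaces_csv <- function(s, path) {
  stopifnot(inherits(s, "surface_set"))
  d <- dim(s$ilm_z)
  df <- data.frame(
    x_index = rep(seq_len(d[1]) - 1L, times = d[2]),
    y_index = rep(seq_len(d[2]) - 1L, each = d[1]),
    ilm_z = as.vector(s$ilm_z),
    nflgcl_z = as.vector(s$nflgcl_z),
    iplinl_z = as.vector(s$iplinl_z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surfaces_csv
#' @param axial_spacing_um,lateral_spacing_mm Spacing metadata to attach.
#' @export
read_surfaces_csv <- function(path, axial_spacing_um = 3,
                              lateral_spacing_mm = 6 / 400) {
  df <- utils::read.csv(path)
  nx <- max(df$x_index) + 1L
  ny <- max(df$y_index) + 1L
  o <- order(df$y_index, df$x_index)
  shape <- function(v) matrix(v[o], nx, ny)
  surface_set(shape(df$ilm_z), shape(df$nflgcl_z), shape(df$iplinl_z),
              axial_spacing_um = axial_spacing_um,
              lateral_spacing_mm = lateral_spacing_mm)
}

#' Write an en face map as CSV and TIFF
#'
#' The CSV holds exact values (one row per pixel, 0-based indices); the
#' TIFF is a normalized 32-bit float image for visual inspection.
#'
#' @param map An [enface_map()].
#' @param path_csv CSV output path (skipped if `NULL`).
#' @param path_tiff TIFF output path (skipped if `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_enface <- function(map, path_csv = NULL, path_tiff = NULL) {
  stopifnot(inherits(map, "enface_map"))
  if (!is.null(path_csv)) {
    d <- dim(map)
    df <- data.frame(
      x_index = rep(seq_len(d[1]) - 1L, times = d[2]),
      y_index = rep(seq_len(d[2]) - 1L, each = d[1]),
      value = as.vector(as_matrix(map)))
    utils::write.csv(df, path_csv, row.names = FALSE)
  }
  if (!is.null(path_tiff)) {
    m <- as_matrix(map)
    rng <- range(m)
    norm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    tiff::writeTIFF(norm, path_tiff, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(c(csv = path_csv, tiff = path_tiff))
}

#' @rdname write_enface
#' @param path_csv_in CSV path to read.
#' @param kind,lateral_spacing_mm Metadata for the rebuilt map.
#' @export
read_enface_csv <- function(path_csv_in, kind = "angiogram",
                            lateral_spacing_mm = 6 / 400) {
  df <- utils::read.csv(path_csv_in)
  nx <- max(df$x_index) + 1L
  ny <- max(df$y_index) + 1L
  o <- order(df$y_index, df$x_index)
  enface_map(matrix(df$value[o], nx, ny), kind = kind,
             lateral_spacing_mm = lateral_spacing_mm)
}

flatten_config <- function(x, prefix = character()) {
  out <- character()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.null(v)) next
    if (inherits(v, "plexus_spec") || (is.list(v) && !is.null(names(v))) ||
        (is.atomic(v) && !is.null(names(v)))) {
      out <- c(out, flatten_config(as.list(unclass(v)), c(prefix, nm)))
    } else {
      out[key] <- paste(as.character(v), collapse = ",")
    }
  }
  out
}

#' Write / read a phantom configuration as a flat key=value file
#'
#' @param cfg A [phantom_config()].
#' @param path Output text path.
#' @return `path` invisibly (write); a `phantom_config` (read).
#' @export
write_phantom_config_file <- function(cfg, path) {
  stopifnot(inherits(cfg, "phantom_config"))
  fl <- flatten_config(unclass(cfg))
  writeLines(paste0(names(fl), "=", unname(fl)), path)
  invisible(path)
}

parse_scalar <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) num else {
    lg <- parts %in% c("TRUE", "FALSE")
    if (all(lg)) as.logical(parts) else parts
  }
}

#' @rdname write_phantom_config_file
#' @export
read_phantom_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  assign_path <- function(lst, keys, val) {
    if (length(keys) == 1L) {
      lst[[keys]] <- val
    } else {
      if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
      lst[[keys[1]]] <- assign_path(lst[[keys[1]]], keys[-1], val)
    }
    lst
  }
  nested <- list()
  for (p in kv) {
    keys <- strsplit(p[1], ".", fixed = TRUE)[[1]]
    val <- parse_scalar(paste(p[-1], collapse = "="))
    nested <- assign_path(nested, keys, val)
  }
  plex <- lapply(nested$plexuses, function(p)
    plexus_spec(p$name, layer = p$layer, center_frac = p$center_frac,
                spread_frac = p$spread_frac,
                areal_fraction = p$areal_fraction,
                radius_px = p$radius_px, trunc_lo = p$trunc_lo,
                trunc_hi = p$trunc_hi, orientation = p$orientation))
  phantom_config(
    grid_n = nested$grid_n, n_z = nested$n_z,
    lateral_size_mm = nested$lateral_size_mm,
    axial_spacing_um = nested$axial_spacing_um,
    seed = nested$seed,
    fovea_offset_mm = nested$fovea_offset_mm,
    pit = nested$pit,
    faz_radius_mm = nested$faz_radius_mm,
    merge_ring_mm = nested$merge_ring_mm,
    layers = nested$layers,
    plexuses = plex,
    tail = nested$tail,
    noise = nested$noise,
    flow_range = nested$flow_range,
    reflectance = unlist(nested$reflectance),
    gcl_fraction = nested$gcl_fraction,
    nflp_min_nfl_um = nested$nflp_min_nfl_um,
    gclp_coupling = nested$gclp_coupling,
    floater = nested$floater,
    jitter = nested$jitter)
}

#' Write phantom ground truth to disk
#'
#' Sidecar CSV (watershed fraction, FAZ center, coverage) plus the plexus
#' label volume as NIfTI.
#'
#' @param scene A `truth_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(scene, dir) {
  stopifnot(inherits(scene, "truth_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(
    key = c("true_watershed_fraction", "faz_center_x_px", "faz_center_y_px",
            paste0("coverage_", names(scene$coverage))),
    value = c(scene$true_watershed_fraction, scene$faz_center_px,
              unname(scene$coverage))),
    file.path(dir, "truth.csv"), row.names = FALSE)
  write_volume_nifti(scene$label, file.path(dir, "plexus_labels.nii.gz"))
  invisible(dir)
}
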