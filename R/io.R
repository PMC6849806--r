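#' Read a 3D volume from MetaImage or NIfTI
#'
#' Supports MetaImage (`.mhd` + raw file) and NIfTI (`.nii`, `.nii.gz`,
#' via RNifti).  Voxel spacing and origin are preserved.
#'
#' @param path file path.
#' @param labels read as a `label_volume`; a `<path>.labels.json` sidecar
#'   (written by [write_volume()]) restores the label map if present.
#' @return `image_volume` or `label_volume`.
#' @export
read_volume <- function(path, labels = FALSE) {
  ext <- tolower(tools::file_ext(sub("[.]gz$", "", path)))
  v <- if (ext == "mhd") read_mhd(path)
       else if (ext == "nii") read_nifti_vol(path)
       else stop("unsupported volume format: ", path)
  if (labels) {
    side <- paste0(path, ".labels.json")
    lm <- if (file.exists(side)) {
      x <- jsonlite::read_json(side, simplifyVector = TRUE)
      stats::setNames(as.integer(x$label_values), x$label_names)
    } else la_label_map()
    v <- label_volume(round(v$data), v$spacing, v$origin, label_map = lm)
  }
  v
}

#' Write a 3D volume as MetaImage or NIfTI
#'
#' Label volumes keep integer storage and get a `<path>.labels.json` sidecar
#' documenting the label map.
#'
#' @param vol `image_volume` or `label_volume`.
#' @param path output path (`.mhd`, `.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(sub("[.]gz$", "", path)))
  if (ext == "mhd") write_mhd(vol, path)
  else if (ext == "nii") write_nifti_vol(vol, path)
  else stop("unsupported volume format: ", path)
  if (inherits(vol, "label_volume")) {
    jsonlite::write_json(list(label_names = names(vol$label_map),
                              label_values = unname(vol$label_map)),
                         paste0(path, ".labels.json"), auto_unbox = FALSE)
  }
  invisible(path)
}

mhd_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mhd_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
               MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  type <- get("ElementType", "MET_FLOAT")
  if (!type %in% names(mhd_types)) stop("unsupported MetaImage type: ", type)
  datafile <- get("ElementDataFile")
  if (is.null(datafile) || datafile %in% c("LIST", "LOCAL"))
    stop("only single-file MetaImage volumes are supported")
  raw_path <- file.path(dirname(path), datafile)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  dat <- readBin(con, what = mhd_types[[type]], n = n,
                 size = mhd_sizes[[type]], signed = signed || mhd_sizes[[type]] > 2,
                 endian = "little")
  image_volume(array(as.numeric(dat), dims), spacing, origin)
}

write_mhd <- function(vol, path) {
  is_lab <- inherits(vol, "label_volume")
  type <- if (is_lab) "MET_SHORT" else "MET_FLOAT"
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(vol$origin, collapse = " ")),
           paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (is_lab) writeBin(as.integer(vol$data), con, size = 2, endian = "little")
  else writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

read_nifti_vol <- function(path) {
  im <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(im)[1:3]
  xf <- RNifti::xform(im)
  origin <- xf[1:3, 4] * c(-1, -1, 1)  # undo RAS flip applied on write
  image_volume(array(as.numeric(im), dim(im)[1:3]), spacing, origin)
}

write_nifti_vol <- function(vol, path) {
  arr <- vol$data
  if (inherits(vol, "label_volume")) storage.mode(arr) <- "integer"
  im <- RNifti::asNifti(arr)
  im <- RNifti::`pixdim<-`(im, vol$spacing)
  # NIfTI stores the grid in RAS world coordinates; our i/j axes are written
  # flipped (L/P) so the diagonal stays positive after the round trip
  aff <- diag(c(-vol$spacing[1], -vol$spacing[2], vol$spacing[3], 1))
  aff[1:3, 4] <- vol$origin * c(-1, -1, 1)
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Serialize a transform to JSON
#'
#' A documented plain-text representation: every transform type stores its
#' `type` tag and parameters (affine: translation/rotation/scale/center;
#' B-spline: lattice geometry and coefficients; displacement field: grid
#' geometry and vectors; composite: the ordered member list).
#'
#' @param t a `spatial_transform`.
#' @param path output JSON path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(transform_to_list(t), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

transform_to_list <- function(t) {
  if (inherits(t, "affine_transform"))
    list(type = "affine", translation = t$translation, rotation = t$rotation,
         scale = t$scale, center = t$center)
  else if (inherits(t, "bspline_transform"))
    list(type = "bspline", grid_spacing = t$grid_spacing,
         lattice_origin = t$lattice_origin, ncp = dim(t$coef)[1:3],
         coef = as.vector(t$coef))
  else if (inherits(t, "displacement_transform"))
    list(type = "displacement", shape = t$geom$shape,
         spacing = t$geom$spacing, origin = t$geom$origin,
         disp = as.vector(t$disp))
  else if (inherits(t, "composite_transform"))
    list(type = "composite", transforms = lapply(t$transforms, transform_to_list))
  else stop("unknown transform type")
}

#' Read a transform from JSON
#' @param path JSON path written by [write_transform()].
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE))
}

transform_from_list <- function(x) {
  switch(x$type,
    affine = affine_transform(x$translation, x$rotation, x$scale, x$center),
    bspline = bspline_transform(x$grid_spacing, x$lattice_origin,
                                coef = array(x$coef, c(x$ncp, 3L))),
    displacement = displacement_transform(
      grid_geometry(x$shape, x$spacing, x$origin),
      array(x$disp, c(x$shape, 3L))),
    composite = composite_transform(lapply(x$transforms, transform_from_list)),
    stop("unknown transform type: ", x$type))
}

#' Write / read a registration configuration as YAML
#' @param cfg a [registration_config()].
#' @param path YAML file path.
#' @export
write_registration_config <- function(cfg, path) {
  yaml::write_yaml(list(
    n_resolutions = cfg$n_resolutions,
    iterations_per_resolution = cfg$iterations_per_resolution,
    grid_spacing_mm = cfg$grid_spacing_mm,
    samples_per_iteration = cfg$samples_per_iteration,
    step_size_schedule = as.list(cfg$step_size_schedule),
    seed = cfg$seed,
    intensity_range = cfg$intensity_range,
    mi_bins = cfg$mi_bins), path)
  invisible(path)
}

#' @rdname write_registration_config
#' @export
read_registration_config <- function(path) {
  x <- yaml::read_yaml(path)
  registration_config(
    n_resolutions = x$n_resolutions,
    iterations_per_resolution = x$iterations_per_resolution,
    grid_spacing_mm = x$grid_spacing_mm,
    samples_per_iteration = x$samples_per_iteration,
    step_size_schedule = unlist(x$step_size_schedule),
    seed = x$seed,
    intensity_range = unlist(x$intensity_range),
    mi_bins = x$mi_bins)
}

#' Write a phantom atlas directory
#'
#' Materializes a synthetic atlas set as a ready-to-run directory: images
#' and labels (MetaImage), generating transforms (JSON) and the spec
#' (JSON).
#'
#' @param aset result of [make_atlas_set()].
#' @param dir output directory.
#' @param spec the [phantom_spec()] used (stored for provenance).
#' @export
write_atlas_dir <- function(aset, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_case <- function(case, stem) {
    write_volume(case$image, file.path(dir, paste0(stem, ".mhd")))
    write_volume(case$labels, file.path(dir, paste0(stem, "_labels.mhd")))
    write_transform(case$generating_transform,
                    file.path(dir, paste0(stem, "_warp.json")))
  }
  write_case(aset$target, "target")
  for (i in seq_along(aset$atlases))
    write_case(aset$atlases[[i]], sprintf("atlas%02d", i))
  if (!is.null(spec)) {
    s <- unclass(spec)
    s$intensities <- as.list(s$intensities)
    jsonlite::write_json(s, file.path(dir, "phantom_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
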