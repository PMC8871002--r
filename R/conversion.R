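#' Min-max pixel normalization to 8-bit
#'
#' Linearly rescales a matrix from `[source_min, source_max]` to
#' `[0, target_max]` (default 255) and rounds half-up to integers — the
#' classic `255 * mat2gray(x)` conversion used when exporting medical volumes
#' to 8-bit slice images.  By default the bounds are the matrix's own minimum
#' and maximum, so a label matrix containing {0, 1, 2} maps to {0, 128, 255}.
#' A constant matrix has no dynamic range; it maps to all zeros with a
#' warning.
#'
#' @param x numeric matrix (non-empty).
#' @param spec a [normalization_spec()]; `NA` bounds mean "use the matrix's
#'   own min/max".
#' @return integer matrix with values in `[0, target_max]`.
#' @examples
#' normalize_pixels(matrix(0:2, 1))   # 0 128 255
#' @export
normalize_pixels <- function(x, spec = normalization_spec()) {
  if (!is.matrix(x) || length(x) == 0L)
    stop("`x` must be a non-empty matrix", call. = FALSE)
  stopifnot(inherits(spec, "normalization_spec"))
  lo <- if (is.na(spec$source_min)) min(x) else spec$source_min
  hi <- if (is.na(spec$source_max)) max(x) else spec$source_max
  if (hi < lo) stop("`source_max` must be >= `source_min`", call. = FALSE)
  if (hi == lo) {
    warning("constant matrix: no dynamic range, returning all zeros",
            call. = FALSE)
    return(matrix(0L, nrow(x), ncol(x)))
  }
  y <- spec$target_max * (x - lo) / (hi - lo)
  y <- pmin(spec$target_max, pmax(0, y))
  matrix(as.integer(round_half_up(y)), nrow(x), ncol(x))
}

#' @rdname normalize_pixels
#' @param source_min,source_max rescaling bounds; `NA` = per-matrix min/max.
#' @param target_max top of the output range (8-bit: 255).
#' @export
normalization_spec <- function(source_min = NA_real_, source_max = NA_real_,
                               target_max = 255) {
  assert_scalar_num(target_max, "target_max", lower = 1)
  if (!is.na(source_min) && !is.na(source_max) && source_max <= source_min)
    stop("`source_max` must exceed `source_min`", call. = FALSE)
  structure(list(source_min = as.numeric(source_min),
                 source_max = as.numeric(source_max),
                 target_max = as.numeric(target_max)),
            class = "normalization_spec")
}

#' Remap label codes to training classes
#'
#' Delayed-enhancement masks encode background, LV cavity, normal
#' myocardium, infarction and no-reflow as 0..4; the segmentation task uses
#' three classes, so the pathology codes are folded into myocardium by
#' default: `{0->0, 1->1, 2->2, 3->2, 4->2}`.
#'
#' @param mask integer matrix of label codes.
#' @param mapping named integer vector, names = input codes, values = output
#'   classes.
#' @return integer matrix of classes.
#' @export
remap_labels <- function(mask, mapping = c(`0` = 0L, `1` = 1L, `2` = 2L,
                                           `3` = 2L, `4` = 2L)) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  codes <- as.integer(names(mapping))
  seen <- unique(as.vector(mask))
  bad <- setdiff(seen, codes)
  if (length(bad)) {
    cnt <- sum(mask %in% bad)
    stop(sprintf("mask contains %d pixel(s) with unmapped code(s): %s",
                 cnt, paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  lut <- integer(max(codes) + 1L)
  lut[codes + 1L] <- as.integer(mapping)
  matrix(lut[as.integer(mask) + 1L], nrow(mask), ncol(mask))
}

# index mapping for a resize from n_in to n_out samples,
# pixel-centre convention: src = (dst - 0.5) * n_in/n_out + 0.5
resize_coords <- function(n_in, n_out) {
  (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
}

resize_nearest <- function(x, target) {
  src_r <- pmin(nrow(x), pmax(1L, round_half_up(resize_coords(nrow(x), target[1]))))
  src_c <- pmin(ncol(x), pmax(1L, round_half_up(resize_coords(ncol(x), target[2]))))
  x[src_r, src_c, drop = FALSE]
}

resize_bilinear <- function(x, target) {
  # separable: weight matrices along each axis
  wmat <- function(n_in, n_out) {
    s <- resize_coords(n_in, n_out)
    i0 <- pmin(n_in, pmax(1L, floor(s)))
    i1 <- pmin(n_in, i0 + 1L)
    f <- pmin(1, pmax(0, s - i0))
    w <- matrix(0, n_out, n_in)
    w[cbind(seq_len(n_out), i0)] <- w[cbind(seq_len(n_out), i0)] + (1 - f)
    w[cbind(seq_len(n_out), i1)] <- w[cbind(seq_len(n_out), i1)] + f
    w
  }
  wmat(nrow(x), target[1]) %*% x %*% t(wmat(ncol(x), target[2]))
}

#' Resize an image/mask pair to the network input size
#'
#' Resamples the image with bilinear interpolation and the mask with
#' nearest-neighbour (so no new label values can appear).  A pair already at
#' the target size is returned unchanged.
#'
#' @param slice a `labeled_slice`.
#' @param target `c(height, width)`, default the network input 256 x 192.
#' @return a `labeled_slice` of the target size.
#' @export
resize_pair <- function(slice, target = c(256L, 192L)) {
  stopifnot(inherits(slice, "labeled_slice"))
  if (any(dim(slice$image) < 8L) || any(target < 8L))
    stop("resize_pair: dimensions must be at least 8 x 8", call. = FALSE)
  if (all(dim(slice$image) == target)) return(slice)
  img <- resize_bilinear(slice$image, target)
  img <- matrix(as.integer(pmin(255, pmax(0, round_half_up(img)))),
                target[1], target[2])
  slice$image <- img
  slice$mask <- resize_nearest(slice$mask, target)
  slice
}

#' Convert a labeled volume into 2D training slices
#'
#' Slices a 3D image (+ label) grid along its third axis and applies the
#' conversion chain per slice: min-max normalization to 8-bit
#' ([normalize_pixels()], computed per-slice), label remapping
#' ([remap_labels()]) and resizing to the network input size
#' ([resize_pair()]).
#'
#' @param volume a [volume_record()].
#' @param exclude_empty drop slices whose remapped mask contains no
#'   foreground pixel (all background); dropped slice indices are attached
#'   as attribute `"excluded"`.
#' @param target output slice size `c(height, width)`.
#' @param mapping label remapping passed to [remap_labels()].
#' @return list of `labeled_slice` objects.
#' @export
volume_to_slices <- function(volume, exclude_empty = FALSE,
                             target = c(256L, 192L),
                             mapping = c(`0` = 0L, `1` = 1L, `2` = 2L,
                                         `3` = 2L, `4` = 2L)) {
  stopifnot(inherits(volume, "volume_record"))
  nz <- dim(volume$voxels)[3]
  out <- vector("list", nz)
  excluded <- integer(0)
  for (k in seq_len(nz)) {
    img <- normalize_pixels(volume$voxels[, , k])
    msk <- if (!is.null(volume$labels))
      remap_labels(volume$labels[, , k], mapping)
    else matrix(0L, nrow(img), ncol(img))
    if (exclude_empty && all(msk == 0L)) {
      excluded <- c(excluded, k)
      next
    }
    sl <- structure(list(image = img, mask = msk,
                         patient_id = volume$patient_id,
                         slice_index = k - 1L, geometry = NULL),
                    class = "labeled_slice")
    out[[k]] <- resize_pair(sl, target)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(excluded))
    message(sprintf("volume_to_slices: excluded %d empty slice(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  attr(out, "excluded") <- excluded
  out
}

#' Bundle voxel and label grids as a volume record
#'
#' @param voxels 3D numeric array (rows x cols x slices); a matrix is
#'   promoted to a single-slice volume.
#' @param labels optional integer array of the same shape with codes 0..4.
#' @param patient_id identifier carried onto the slices.
#' @param voxel_spacing grid spacing in mm (metadata only).
#' @return an object of class `volume_record`.
#' @export
volume_record <- function(voxels, labels = NULL, patient_id = "case",
                          voxel_spacing = c(1, 1, 1)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) == 4L && dim(voxels)[4] == 1L)
    voxels <- array(voxels, dim(voxels)[1:3])
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (!is.null(labels)) {
    if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
    if (length(dim(labels)) == 4L && dim(labels)[4] == 1L)
      labels <- array(labels, dim(labels)[1:3])
    if (!identical(dim(labels), dim(voxels)))
      stop(sprintf("label grid %s does not match voxel grid %s",
                   paste(dim(labels), collapse = "x"),
                   paste(dim(voxels), collapse = "x")), call. = FALSE)
    if (!all(labels %in% 0:4))
      stop("labels must contain only codes 0..4", call. = FALSE)
    labels <- array(as.integer(labels), dim(labels))
  }
  structure(list(voxels = voxels, labels = labels,
                 patient_id = patient_id, voxel_spacing = voxel_spacing),
            class = "volume_record")
}

#' Read an image/label NIfTI pair as a volume record
#'
#' @param image_path path to the image volume (`.nii`/`.nii.gz`).
#' @param label_path optional path to the matching label volume.
#' @param patient_id identifier; defaults to the image file stem.
#' @return a [volume_record()].
#' @export
read_volume <- function(image_path, label_path = NULL, patient_id = NULL) {
  img <- read_nifti(image_path)
  lbl <- if (!is.null(label_path)) read_nifti(label_path)$data else NULL
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  volume_record(img$data, lbl, patient_id = patient_id,
                voxel_spacing = img$pixdim[1:3])
}

#' Write converted slices to disk
#'
#' @param slices list of `labeled_slice` objects.
#' @param dir output directory; images land in `images/`, masks in `masks/`,
#'   plus a `manifest.csv`.
#' @param format see [write_dataset()].
#' @return `dir`, invisibly.
#' @export
write_slices <- function(slices, dir, format = "auto") {
  ext <- gray_ext(format)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  has_mask <- any(vapply(slices, function(s) !is.null(s$mask), TRUE))
  if (has_mask)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  stems <- vapply(slices, function(s)
    sprintf("%s_s%02d", s$patient_id, s$slice_index), "")
  for (i in seq_along(slices)) {
    write_gray(slices[[i]]$image, file.path(dir, "images", paste0(stems[i], ext)))
    if (!is.null(slices[[i]]$mask))
      write_gray(slices[[i]]$mask, file.path(dir, "masks", paste0(stems[i], ext)))
  }
  write.csv(data.frame(stem = stems,
                       patient_id = vapply(slices, `[[`, "", "patient_id"),
                       slice_index = vapply(slices, `[[`, 0L, "slice_index")),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
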