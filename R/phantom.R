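#' Parameters for the synthetic short-axis phantom
#'
#' The phantom emulates the geometry and statistics a short-axis
#' delayed-enhancement slice presents to a segmentation network: a roughly
#' circular bright LV cavity (class 1) enclosed by an annular myocardium
#' (class 2) on a dark noisy background (class 0) that dominates the pixel
#' count.  It makes no attempt at MR physics; it exists so the conversion,
#' weighting, training and evaluation stages can be exercised end-to-end
#' without clinical data.
#'
#' Defaults target a 256 x 192 slice: cavity radius 12-26 px and wall
#' thickness 6-14 px span the range seen across basal-to-apical slices;
#' tissue means (background 30, cavity 200, myocardium 110 on the 8-bit
#' scale) give the bright-cavity/intermediate-wall/dark-background ordering
#' of contrast-enhanced short-axis images, and the per-tissue noise SDs
#' overlap the class intensity distributions enough that a global threshold
#' cannot separate them.  `apical_shrink` shrinks the cavity radius by that
#' fraction per slice position, mimicking the taper towards the apex.
#'
#' @param height,width slice size in pixels (defaults 256 x 192).
#' @param cavity_radius_range min/max cavity radius, px.
#' @param myo_thickness_range min/max myocardial wall thickness, px.
#' @param center_jitter max |offset| of the LV centre from the image centre, px.
#' @param intensity_means length-3 mean gray level (background, cavity,
#'   myocardium), 8-bit scale.
#' @param intensity_sds length-3 per-tissue Gaussian noise SD.
#' @param bias_amplitude amplitude of a smooth multiplicative bias field, as
#'   a fraction of the dynamic range (0 disables).
#' @param apical_shrink per-slice-index fractional cavity-radius shrink in
#'   `[0, 1)`; radius at slice index k is `r * (1 - apical_shrink)^k`.
#' @return an object of class `phantom_params`.
#' @examples
#' p <- phantom_params(height = 64, width = 48,
#'                     cavity_radius_range = c(6, 10),
#'                     myo_thickness_range = c(3, 5), center_jitter = 2)
#' s <- generate_phantom(p, seed = 1)
#' table(s$mask)
#' @export
phantom_params <- function(height = 256L, width = 192L,
                           cavity_radius_range = c(12, 26),
                           myo_thickness_range = c(6, 14),
                           center_jitter = 6,
                           intensity_means = c(30, 200, 110),
                           intensity_sds = c(15, 20, 18),
                           bias_amplitude = 0.05,
                           apical_shrink = 0.05) {
  p <- list(height = as.integer(height), width = as.integer(width),
            cavity_radius_range = as.numeric(cavity_radius_range),
            myo_thickness_range = as.numeric(myo_thickness_range),
            center_jitter = as.numeric(center_jitter),
            intensity_means = as.numeric(intensity_means),
            intensity_sds = as.numeric(intensity_sds),
            bias_amplitude = as.numeric(bias_amplitude),
            apical_shrink = as.numeric(apical_shrink))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  stopifnot(inherits(p, "phantom_params"))
  if (p$height < 8L || p$width < 8L)
    stop("phantom dimensions must be at least 8 x 8", call. = FALSE)
  if (length(p$cavity_radius_range) != 2L || any(p$cavity_radius_range <= 0) ||
      diff(p$cavity_radius_range) < 0)
    stop("`cavity_radius_range` must be two positive non-decreasing values",
         call. = FALSE)
  if (length(p$myo_thickness_range) != 2L || any(p$myo_thickness_range <= 0) ||
      diff(p$myo_thickness_range) < 0)
    stop("`myo_thickness_range` must be two positive non-decreasing values",
         call. = FALSE)
  reach <- max(p$cavity_radius_range) + max(p$myo_thickness_range) +
    abs(p$center_jitter)
  if (reach >= min(p$height, p$width) / 2)
    stop(sprintf(paste0("phantom anatomy does not fit: radius + thickness + ",
                        "jitter = %.1f px must stay below min(height, width)/2 = %.1f"),
                 reach, min(p$height, p$width) / 2), call. = FALSE)
  if (length(p$intensity_means) != 3L || any(p$intensity_means < 0 | p$intensity_means > 255))
    stop("`intensity_means` must be 3 values in [0, 255]", call. = FALSE)
  if (length(p$intensity_sds) != 3L || any(p$intensity_sds < 0))
    stop("`intensity_sds` must be 3 non-negative values", call. = FALSE)
  if (p$bias_amplitude < 0 || p$bias_amplitude >= 1)
    stop("`bias_amplitude` must lie in [0, 1)", call. = FALSE)
  if (p$apical_shrink < 0 || p$apical_shrink >= 1)
    stop("`apical_shrink` must lie in [0, 1)", call. = FALSE)
  invisible(p)
}

#' Generate one labeled phantom slice
#'
#' Draws geometry and noise from a seeded generator and returns a
#' `labeled_slice`: an 8-bit image and a class mask over codes 0 =
#' background, 1 = LV cavity, 2 = myocardium.  Identical `(params, seed,
#' slice_index)` produce byte-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param params a [phantom_params()] object.
#' @param seed integer seed for this slice.
#' @param patient_id identifier recorded on the slice.
#' @param slice_index 0-based position in the stack; combined with
#'   `apical_shrink` it tapers the cavity towards the apex.
#' @return a `labeled_slice`: list with `image` (integer matrix, 0..255),
#'   `mask` (integer matrix in `{0, 1, 2}`), `patient_id`, `slice_index`,
#'   and the drawn `geometry`.
#' @export
generate_phantom <- function(params, seed, patient_id = "phantom",
                             slice_index = 0L) {
  validate_phantom_params(params)
  assert_scalar_num(slice_index, "slice_index", lower = 0)
  with_seed(seed, {
    h <- params$height; w <- params$width
    r_cav <- runif(1, params$cavity_radius_range[1], params$cavity_radius_range[2])
    r_cav <- r_cav * (1 - params$apical_shrink)^slice_index
    thick <- runif(1, params$myo_thickness_range[1], params$myo_thickness_range[2])
    cy <- (h + 1) / 2 + runif(1, -params$center_jitter, params$center_jitter)
    cx <- (w + 1) / 2 + runif(1, -params$center_jitter, params$center_jitter)

    d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
    mask <- matrix(0L, h, w)
    mask[d <= r_cav + thick] <- 2L
    mask[d <= r_cav] <- 1L

    mu <- params$intensity_means[mask + 1L]
    sd <- params$intensity_sds[mask + 1L]
    img <- matrix(rnorm(h * w, mu, sd), h, w)
    if (params$bias_amplitude > 0) {
      ph <- runif(2, 0, 2 * pi)
      bias <- 1 + params$bias_amplitude *
        outer(sin(2 * pi * seq_len(h) / h + ph[1]),
              cos(2 * pi * seq_len(w) / w + ph[2]))
      img <- img * bias
    }
    img <- matrix(as.integer(pmin(255, pmax(0, round_half_up(img)))), h, w)
    structure(list(image = img, mask = mask,
                   patient_id = patient_id, slice_index = as.integer(slice_index),
                   geometry = list(cavity_radius = r_cav, myo_thickness = thick,
                                   center = c(cy, cx), seed = as.integer(seed))),
              class = "labeled_slice")
  })
}

#' Generate a partitioned phantom dataset
#'
#' Creates `n` phantom slices with per-slice seeds `seed + k` (k = 0..n-1),
#' grouped into synthetic patients of `slices_per_patient` slices whose
#' slice index drives the apical taper, and deterministically partitioned
#' into train/validation/test splits.
#'
#' @param n number of slices (>= 1).
#' @param params a [phantom_params()] object.
#' @param seed base seed; slice k uses `seed + k`.
#' @param split named fractions `c(train =, val =, test =)` summing to 1.
#'   Sizes are apportioned by largest remainder, then membership is assigned
#'   by a seeded shuffle.
#' @param slices_per_patient slices grouped under one synthetic patient id.
#' @return a `phantom_dataset`: list with `slices` (list of `labeled_slice`),
#'   `manifest` (data frame: patient_id, slice_index, seed, cavity_radius,
#'   myo_thickness, split), and `split` (named list of slice indices).
#' @export
generate_dataset <- function(n, params = phantom_params(), seed = 1L,
                             split = c(train = 0.8, val = 0.1, test = 0.1),
                             slices_per_patient = 10L) {
  assert_scalar_num(n, "n", lower = 1)
  validate_phantom_params(params)
  if (length(split) < 1L || any(split < 0) || abs(sum(split) - 1) > 1e-8)
    stop("`split` fractions must be non-negative and sum to 1", call. = FALSE)
  if (is.null(names(split))) names(split) <- c("train", "val", "test")[seq_along(split)]
  n <- as.integer(n)

  slices <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    pid <- sprintf("P%03d", k %/% slices_per_patient + 1L)
    slices[[k + 1L]] <- generate_phantom(params, seed = seed + k,
                                         patient_id = pid,
                                         slice_index = k %% slices_per_patient)
  }

  # largest-remainder apportionment of split sizes
  raw <- split * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  groups <- rep(names(split), times = sizes)
  membership <- character(n)
  membership[perm] <- groups
  split_idx <- lapply(stats::setNames(names(split), names(split)),
                      function(g) which(membership == g))

  manifest <- data.frame(
    patient_id = vapply(slices, `[[`, "", "patient_id"),
    slice_index = vapply(slices, `[[`, 0L, "slice_index"),
    seed = vapply(slices, function(s) s$geometry$seed, 0L),
    cavity_radius = vapply(slices, function(s) s$geometry$cavity_radius, 0),
    myo_thickness = vapply(slices, function(s) s$geometry$myo_thickness, 0),
    split = membership,
    stringsAsFactors = FALSE)

  structure(list(slices = slices, manifest = manifest, split = split_idx,
                 params = params, seed = as.integer(seed)),
            class = "phantom_dataset")
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale image/mask pairs with matching stems under
#' `images/` and `masks/`, plus `manifest.csv`.
#'
#' @param dataset a `phantom_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param format `"auto"` (PNG when the \pkg{png} package is available, else
#'   plain-text PGM), `"png"`, or `"pgm"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = "auto") {
  stopifnot(inherits(dataset, "phantom_dataset"))
  ext <- gray_ext(format)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  stems <- sprintf("%s_s%02d", dataset$manifest$patient_id,
                   dataset$manifest$slice_index)
  for (i in seq_along(dataset$slices)) {
    write_gray(dataset$slices[[i]]$image,
               file.path(dir, "images", paste0(stems[i], ext)))
    write_gray(dataset$slices[[i]]$mask,
               file.path(dir, "masks", paste0(stems[i], ext)))
  }
  manifest <- cbind(dataset$manifest, stem = stems, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.labeled_slice <- function(x, ...) {
  cat(sprintf("<labeled_slice> %s #%d: %d x %d, classes {%s}\n",
              x$patient_id, x$slice_index, nrow(x$image), ncol(x$image),
              paste(sort(unique(as.vector(x$mask))), collapse = ", ")))
  invisible(x)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d slices (%s), %d x %d, seed %d\n",
              length(x$slices),
              paste(sprintf("%s=%d", names(x$split), lengths(x$split)),
                    collapse = ", "),
              x$params$height, x$params$width, x$seed))
  invisible(x)
}
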