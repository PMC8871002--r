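#' Class pixel frequencies over a set of masks
#'
#' In short-axis label masks the background dominates (typically > 85% of
#' pixels), which biases a pixel classifier towards the majority class.
#' This computes the empirical class distribution that the inverse-frequency
#' weighting corrects.
#'
#' @param masks a class-grid matrix, a list of such matrices, or a
#'   `phantom_dataset` (in which case all of its masks are used).
#' @param C number of classes; mask values must lie in `[0, C)`.
#' @return numeric vector of length `C` summing to 1, named by class, with
#'   attribute `total_pixels`.
#' @export
class_frequencies <- function(masks, C = 3L) {
  if (inherits(masks, "phantom_dataset")) masks <- lapply(masks$slices, `[[`, "mask")
  if (is.matrix(masks)) masks <- list(masks)
  if (!is.list(masks) || length(masks) == 0L)
    stop("`masks` must be a non-empty matrix or list of matrices", call. = FALSE)
  C <- as.integer(C)
  counts <- numeric(C)
  total <- 0
  for (m in masks) {
    v <- as.integer(m)
    if (any(v < 0L | v >= C))
      stop(sprintf("mask values must lie in [0, %d)", C), call. = FALSE)
    counts <- counts + tabulate(v + 1L, nbins = C)
    total <- total + length(v)
  }
  structure(counts / total, names = as.character(seq_len(C) - 1L),
            total_pixels = total)
}

#' Inverse-frequency class weights
#'
#' Weights each class by the inverse of its pixel frequency so that rare
#' foreground classes (LV cavity, myocardium) contribute to the loss on a
#' par with the dominant background.  Weights are normalized as
#' `w_c = 1 / (C * f_c)`, so uniform frequencies give unit weights and
#' `w_c * f_c = 1/C` exactly for every present class.  Classes absent from
#' the data (`f_c = 0`) receive weight 0 with a warning rather than an
#' infinite weight.
#'
#' @param frequencies numeric vector summing to 1 (e.g. from
#'   [class_frequencies()]).
#' @param C number of classes; defaults to `length(frequencies)`.
#' @return an object of class `class_weights`: list with `weights`,
#'   `frequencies` and `total_pixels`.
#' @examples
#' inverse_frequency_weights(c(0.9, 0.05, 0.05))
#' @export
inverse_frequency_weights <- function(frequencies, C = length(frequencies)) {
  if (any(frequencies < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (length(frequencies) != C)
    stop("`frequencies` must have length C", call. = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-8)
    stop("frequencies must sum to 1", call. = FALSE)
  w <- ifelse(frequencies > 0, 1 / (C * frequencies), 0)
  if (any(frequencies == 0))
    warning(sprintf("class(es) %s absent from the data: weight set to 0",
                    paste(which(frequencies == 0) - 1L, collapse = ", ")),
            call. = FALSE)
  structure(list(weights = unname(w),
                 frequencies = unname(frequencies),
                 total_pixels = attr(frequencies, "total_pixels") %||% NA_real_),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat("<class_weights>\n")
  print(data.frame(class = seq_along(x$weights) - 1L,
                   frequency = x$frequencies, weight = x$weights))
  invisible(x)
}

#' Compute inverse-frequency weights from a training dataset
#'
#' Convenience wrapper: frequencies are computed on the training split only
#' (never on validation/test masks) and inverted.
#'
#' @param dataset a `phantom_dataset` or list of masks.
#' @param C number of classes.
#' @return a `class_weights` object.
#' @export
training_class_weights <- function(dataset, C = 3L) {
  masks <- if (inherits(dataset, "phantom_dataset"))
    lapply(dataset$slices[dataset$split$train], `[[`, "mask")
  else dataset
  inverse_frequency_weights(class_frequencies(masks, C), C)
}
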