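#' Specification of the 15-layer encoder-decoder FCN
#'
#' Declares the fixed layer graph of the segmentation network: a single
#' encoder stage (3x3 same-padded convolution, batch normalization, ReLU,
#' 2x2/stride-2 max pooling), two further conv-BN-ReLU blocks at half
#' resolution, a 4x4/stride-2 transpose convolution back to full resolution,
#' a final 3x3 convolution onto the class channels, softmax, and a pixel
#' classification layer.  Filter widths default to 16/32/64 in the encoder
#' and 16 after upsampling.
#'
#' The kernel geometry is part of the architecture's contract and is
#' validated: convolutions must be 3x3 same-padded, pooling 2x2 stride 2,
#' the transpose convolution 4x4 stride 2.  Filter widths and the class
#' count are configurable (small widths are useful for finite-difference
#' testing).
#'
#' @param input_shape `c(height, width, channels)`; height and width must be
#'   even (one pooling level).  Default 256 x 192 x 1.
#' @param num_classes number of output classes C (default 3: background, LV
#'   cavity, myocardium; use 2 for a background/foreground variant).
#' @param filters widths of the three encoder convolutions and of the
#'   transpose convolution output, default `c(16, 32, 64, 16)`.
#' @param conv_kernel,pool_size,tconv_kernel kernel geometry; validated
#'   against the architecture's contract (3, 2, 4).
#' @return an object of class `fcn_spec` with a `layers` list of per-layer
#'   descriptors.
#' @examples
#' spec <- fcn_spec()
#' forward_shapes(spec)[[5]]   # 128 96 16 after pooling
#' count_learnables(fcn_spec(num_classes = 2))   # 40210
#' @export
fcn_spec <- function(input_shape = c(256L, 192L, 1L), num_classes = 3L,
                     filters = c(16L, 32L, 64L, 16L),
                     conv_kernel = 3L, pool_size = 2L, tconv_kernel = 4L) {
  if (conv_kernel != 3L)
    stop("architecture contract: convolutions are 3x3 (got ",
         conv_kernel, ")", call. = FALSE)
  if (pool_size != 2L)
    stop("architecture contract: max pooling is 2x2 stride 2", call. = FALSE)
  if (tconv_kernel != 4L)
    stop("architecture contract: transpose convolution is 4x4 stride 2",
         call. = FALSE)
  if (length(input_shape) != 3L || input_shape[3] != 1L)
    stop("`input_shape` must be c(height, width, 1)", call. = FALSE)
  if (any(input_shape[1:2] < 8L) || any(input_shape[1:2] %% 2L != 0L))
    stop("input height/width must be even and >= 8 (one 2x2 pooling level)",
         call. = FALSE)
  if (length(filters) != 4L || any(filters < 1L))
    stop("`filters` must be four positive widths", call. = FALSE)
  if (num_classes < 2L) stop("`num_classes` must be >= 2", call. = FALSE)

  f <- as.integer(filters); C <- as.integer(num_classes)
  lay <- function(kind, kernel = NULL, filters = NA_integer_, stride = 1L,
                  padding = "same")
    list(kind = kind, kernel = kernel, filters = filters, stride = stride,
         padding = padding)
  layers <- list(
    lay("input"),
    lay("convolution", c(3L, 3L), f[1]),
    lay("batch_norm", filters = f[1]),
    lay("relu"),
    lay("max_pool", c(2L, 2L), stride = 2L, padding = "valid"),
    lay("convolution", c(3L, 3L), f[2]),
    lay("batch_norm", filters = f[2]),
    lay("relu"),
    lay("convolution", c(3L, 3L), f[3]),
    lay("batch_norm", filters = f[3]),
    lay("relu"),
    lay("transpose_convolution", c(4L, 4L), f[4], stride = 2L),
    lay("convolution", c(3L, 3L), C),
    lay("softmax"),
    lay("pixel_classification"))
  for (i in seq_along(layers)) layers[[i]]$index <- i
  structure(list(layers = layers,
                 input_shape = as.integer(input_shape),
                 num_classes = C, filters = f),
            class = "fcn_spec")
}

#' @export
print.fcn_spec <- function(x, ...) {
  cat(sprintf("<fcn_spec> input %s, %d classes, %s learnables\n",
              paste(x$input_shape, collapse = "x"), x$num_classes,
              format(count_learnables(x), big.mark = ",")))
  sh <- forward_shapes(x)
  for (i in seq_along(x$layers)) {
    s <- if (is.null(sh[[i]])) "-" else paste(sh[[i]], collapse = " x ")
    cat(sprintf("  %2d %-22s %s\n", i, x$layers[[i]]$kind, s))
  }
  invisible(x)
}

#' Activation shapes through the network
#'
#' Propagates `c(height, width, channels)` through every layer.  Same-padded
#' convolutions preserve the spatial size, pooling halves it, the stride-2
#' transpose convolution doubles it back (its raw `2H+2` output is cropped
#' symmetrically to `2H`), so the softmax output matches the input spatial
#' size with `num_classes` channels.  The pixel classification layer emits
#' the `height x width` class map (channel dimension collapsed).
#'
#' @param spec an [fcn_spec()].
#' @return list of integer shape vectors, one per layer.
#' @export
forward_shapes <- function(spec) {
  stopifnot(inherits(spec, "fcn_spec"))
  sh <- spec$input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    sh <- switch(l$kind,
      input = sh,
      convolution = c(sh[1:2], l$filters),
      batch_norm = sh,
      relu = sh,
      max_pool = {
        if (any(sh[1:2] %% 2L != 0L))
          stop(sprintf("layer %d: spatial dims %s not divisible by pooling stride",
                       i, paste(sh[1:2], collapse = "x")), call. = FALSE)
        c(sh[1:2] %/% 2L, sh[3])
      },
      transpose_convolution = c(sh[1:2] * 2L, l$filters),
      softmax = sh,
      pixel_classification = sh[1:2],
      stop("unknown layer kind: ", l$kind))
    out[[i]] <- sh
  }
  out
}

#' Shapes of every learnable tensor
#'
#' @param spec an [fcn_spec()].
#' @return named list of integer dim vectors (weights/bias per convolution,
#'   offset/scale per batch normalization).
#' @export
learnable_shapes <- function(spec) {
  stopifnot(inherits(spec, "fcn_spec"))
  sh <- spec$input_shape
  out <- list()
  conv_i <- 0L; bn_i <- 0L
  for (l in spec$layers) {
    if (l$kind == "convolution") {
      conv_i <- conv_i + 1L
      nm <- paste0("conv", conv_i)
      out[[paste0(nm, "_weights")]] <- c(l$kernel, sh[3], l$filters)
      out[[paste0(nm, "_bias")]] <- c(1L, 1L, l$filters)
      sh <- c(sh[1:2], l$filters)
    } else if (l$kind == "batch_norm") {
      bn_i <- bn_i + 1L
      out[[paste0("bn", bn_i, "_offset")]] <- c(1L, 1L, l$filters)
      out[[paste0("bn", bn_i, "_scale")]] <- c(1L, 1L, l$filters)
    } else if (l$kind == "transpose_convolution") {
      # printed layout: kh x kw x Cout x Cin
      out$tconv_weights <- c(l$kernel, l$filters, sh[3])
      out$tconv_bias <- c(1L, 1L, l$filters)
      sh <- c(sh[1:2] * 2L, l$filters)
    } else if (l$kind == "max_pool") {
      sh <- c(sh[1:2] %/% 2L, sh[3])
    }
  }
  out
}

#' Total number of learnable parameters
#'
#' Sum of the element counts of every weight, bias, offset and scale tensor.
#' Being fully convolutional, the count is independent of the input spatial
#' size.
#'
#' @param spec an [fcn_spec()].
#' @return integer.
#' @export
count_learnables <- function(spec) {
  sum(vapply(learnable_shapes(spec), prod, 0))
}
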