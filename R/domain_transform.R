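#' Centre and scale an image by its mean and standard deviation
#'
#' Standardises a real-valued image: subtracts the mean of all its pixels and
#' divides by their population standard deviation, so the result has mean 0
#' and standard deviation 1. Applied identically at training and evaluation
#' time; with the default per-image statistics no information can leak
#' across data splits. Supplying `center` and `scale` (e.g. computed once on
#' a training split) gives dataset-level normalisation instead.
#'
#' @param img Numeric array, `H x W` or `H x W x C`.
#' @param center,scale Optional externally supplied statistics; both default
#'   to the image's own mean and population standard deviation.
#' @return The standardised array, with attribute `normalized = TRUE`.
#' @examples
#' normalize_image(matrix(c(0, 2), 1))  # -> -1, +1
#' @export
normalize_image <- function(img, center = NULL, scale = NULL) {
  if (!is.numeric(img)) stop("`img` must be a numeric array")
  mu <- center %||% mean(img)
  sdev <- scale %||% sqrt(mean((img - mu)^2))  # population standard deviation
  if (sdev < 1e-12) {
    stop("degenerate input: constant image has zero standard deviation")
  }
  out <- (img - mu) / sdev
  attr(out, "normalized") <- TRUE
  out
}

#' Resize an image to a square side length
#'
#' Bilinear interpolation with antialiasing (the smoothing applied on
#' downscaling), delegated to EBImage.
#'
#' @param img Numeric array, `H x W` or `H x W x C`.
#' @param side Target side length in pixels (output is `side x side`).
#' @return Resized array with the same number of channels.
#' @export
resize_image <- function(img, side) {
  if (!is.numeric(side) || length(side) != 1 || side < 1) {
    stop("`side` must be a positive integer")
  }
  side <- as.integer(side)
  nd <- length(dim(img) %||% integer(0))
  if (nd == 2 && all(dim(img) == c(side, side))) return(img)
  if (nd == 3 && all(dim(img)[1:2] == c(side, side))) return(img)
  cm <- if (nd == 3) "Color" else "Grayscale"
  r <- EBImage::resize(EBImage::Image(img, colormode = cm),
                       w = side, h = side, antialias = TRUE)
  out <- EBImage::imageData(r)
  if (nd == 2) dim(out) <- c(side, side)
  out
}

#' Read an image file into an 8-bit array
#'
#' Reads PNG/JPEG/TIFF images (via EBImage) into an `H x W x C` numeric
#' array scaled to `[0, 255]`, the range the rest of the pipeline treats as
#' raw pixel input.
#'
#' @param path Image file path.
#' @return Numeric array `H x W x C` (or `H x W` for greyscale).
#' @export
read_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path)) * 255
  d <- dim(img)
  # EBImage stores width-first; transpose to the row-major H x W convention
  if (length(d) == 3 && d[3] == 1) dim(img) <- d[1:2]
  if (length(dim(img)) == 3) aperm(img, c(2, 1, 3)) else t(img)
}

#' The DFT (Fourier) Vandermonde matrix
#'
#' The `N x N` symmetric matrix with entry `(j, k) = w^(j*k)`,
#' `w = exp(-2i*pi/N)`, whose product with a length-`N` signal is its
#' discrete Fourier transform. Every entry has unit modulus and
#' `F %*% Conj(F) / N` is the identity.
#'
#' @param N Matrix order, `N >= 1`.
#' @return An `N x N` complex matrix.
#' @examples
#' dft_matrix(2)  # [[1, 1], [1, -1]]
#' @export
dft_matrix <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N)) {
    stop("`N` must be a positive integer")
  }
  k <- 0:(N - 1)
  exp(-2i * pi * outer(k, k) / N)
}

#' Convert a real image into the complex (Fourier) domain
#'
#' Multiplies each image row (per channel) by the DFT Vandermonde matrix and
#' keeps only the first `floor(W/2) + 1` frequency components: for real
#' input the remaining components are their conjugate mirror (Hermitian
#' symmetry), so the retained half is lossless while holding almost half the
#' components. With `axis = "both"` a full DFT is also applied along the
#' height axis (the width axis is still the reduced one).
#'
#' @param img Numeric array, `H x W` or `H x W x C`.
#' @param axis Transform the `"width"` axis only (default) or `"both"`
#'   spatial axes.
#' @return A `complex_tensor` of shape `H x W' x C` with
#'   `W' = floor(W/2) + 1`, carrying attributes `original_width`, `axis` and
#'   `input_rank` for exact reconstruction.
#' @seealso [reconstruct_real()]
#' @export
to_complex_domain <- function(img, axis = c("width", "both")) {
  axis <- match.arg(axis)
  nd <- length(dim(img) %||% integer(0))
  if (nd == 2) dim(img) <- c(dim(img), 1)
  if (length(dim(img)) != 3) stop("`img` must be H x W or H x W x C")
  d <- dim(img); H <- d[1]; W <- d[2]; C <- d[3]
  z <- img
  if (axis == "both") {
    Fh <- dft_matrix(H)
    z <- Fh %*% matrix(z, H, W * C)
    dim(z) <- c(H, W, C)
  }
  Wp <- W %/% 2 + 1
  Fm <- dft_matrix(W)[seq_len(Wp), , drop = FALSE]
  m <- aperm(z, c(2, 1, 3))
  dim(m) <- c(W, H * C)
  Z <- Fm %*% m
  dim(Z) <- c(Wp, H, C)
  Z <- aperm(Z, c(2, 1, 3))
  out <- complex_tensor(array(Re(Z), dim(Z)), array(Im(Z), dim(Z)))
  attr(out, "original_width") <- W
  attr(out, "axis") <- axis
  attr(out, "input_rank") <- nd
  out
}

#' Invert the Hermitian-reduced Fourier representation
#'
#' Rebuilds the full spectrum from the retained non-redundant half by
#' conjugate symmetry and applies the inverse DFT. For any real input image
#' the round trip through [to_complex_domain()] is exact to numerical
#' precision, which is the sense in which the reduction is lossless.
#'
#' @param cimg A `complex_tensor` produced by [to_complex_domain()].
#' @param W Original image width.
#' @return The reconstructed real image array.
#' @export
reconstruct_real <- function(cimg, W) {
  stopifnot(inherits(cimg, "complex_tensor"))
  d <- dim(cimg$re)
  H <- d[1]; Wp <- d[2]; C <- d[3]
  if (Wp != W %/% 2 + 1) {
    stop("shape mismatch: tensor width ", Wp, " is not floor(W/2)+1 for W = ", W)
  }
  axis <- attr(cimg, "axis") %||% "width"
  Z <- as_complex_array(cimg)
  Zf <- array(0i, c(H, W, C))
  Zf[, seq_len(Wp), ] <- Z
  if (W > Wp) {
    rowmap <- if (axis == "both") c(1L, seq(H, 2L)) else seq_len(H)
    for (k in seq(Wp + 1, W)) {
      Zf[, k, ] <- Conj(Z[rowmap, W - k + 2, , drop = FALSE])
    }
  }
  m <- aperm(Zf, c(2, 1, 3))
  dim(m) <- c(W, H * C)
  x <- Conj(dft_matrix(W)) %*% m / W
  dim(x) <- c(W, H, C)
  x <- aperm(x, c(2, 1, 3))
  if (axis == "both") {
    x <- Conj(dft_matrix(H)) %*% matrix(x, H, W * C) / H
    dim(x) <- c(H, W, C)
  }
  out <- array(Re(x), c(H, W, C))
  if (identical(attr(cimg, "input_rank"), 2L) ||
      identical(attr(cimg, "input_rank"), 2)) {
    dim(out) <- c(H, W)
  }
  out
}
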