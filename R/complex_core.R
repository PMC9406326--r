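# Complex-valued layer algebra. Every operation is expressed over paired
# real component arrays, so the gradients used in training are ordinary
# real partial derivatives with respect to each component (the layers are
# not holomorphic; zReLU in particular is not).

# ---- im2col machinery (shared by real and complex convolution) ----------

# Column ordering matches col-major flattening of a (kh, kw, C_in) kernel
# block, so a flattened weight array multiplies directly.
.im2col_geometry <- function(H, W, C, kh, kw, stride) {
  i0 <- seq(1, H - kh + 1, by = stride)
  j0 <- seq(1, W - kw + 1, by = stride)
  oh <- length(i0); ow <- length(j0)
  base <- rep(i0, times = ow) + (rep(j0, each = oh) - 1) * H
  g <- expand.grid(a = seq_len(kh), b = seq_len(kw), c = seq_len(C))
  off <- (g$a - 1) + (g$b - 1) * H + (g$c - 1) * H * W
  list(idx = outer(base, off, "+"), oh = oh, ow = ow,
       P = oh * ow, K = kh * kw * C, kh = kh, kw = kw, stride = stride)
}

# Gather indices depend only on the layer geometry and batch size, so they
# are built once and memoised for the lifetime of the session.
.geom_cache <- new.env(parent = emptyenv())

.im2col_batch_idx <- function(geom, H, W, C, B) {
  key <- paste(H, W, C, B, geom$kh, geom$kw, geom$stride, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- geom$P
  IDX <- geom$idx[rep(seq_len(P), B), , drop = FALSE]
  IDX <- IDX + rep((seq_len(B) - 1) * H * W * C, each = P)
  storage.mode(IDX) <- "integer"
  .geom_cache[[key]] <- IDX
  IDX
}

.im2col <- function(x, IDX, K) {
  cpp_im2col(x, IDX)
}

.col2im <- function(dcols, IDX, H, W, C, B) {
  array(cpp_col2im(dcols, IDX, H * W * C * B), c(H, W, C, B))
}

.pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

.unpad_spatial <- function(x, p, H, W) {
  if (p == 0) return(x)
  x[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

.as_nhwcb <- function(a) {
  # canonicalise (H, W, C) or (H, W, C, B) to 4-D, remembering the rank
  d <- dim(a)
  if (length(d) == 3) {
    dim(a) <- c(d, 1)
    attr(a, "had_batch") <- FALSE
  } else if (length(d) == 4) {
    attr(a, "had_batch") <- TRUE
  } else {
    stop("expected an (H, W, C) or (H, W, C, B) array")
  }
  a
}

.resolve_padding <- function(padding, kh, stride) {
  if (identical(padding, "same")) {
    if (stride != 1) stop("'same' padding requires stride 1")
    if (kh %% 2 == 0) stop("'same' padding requires an odd kernel")
    (kh - 1) %/% 2
  } else {
    p <- as.integer(padding)
    if (p < 0) stop("padding must be >= 0 or 'same'")
    p
  }
}

# Real convolution core used by both domains. Returns output plus the cache
# needed for the backward pass.
.conv_fw_real <- function(x, w, stride, pad) {
  dw <- dim(w); kh <- dw[1]; kw <- dw[2]; Cin <- dw[3]; Cout <- dw[4]
  xp <- .pad_spatial(x, pad)
  d <- dim(xp); H <- d[1]; W <- d[2]; B <- d[4]
  if (d[3] != Cin) stop("geometry error: input has ", d[3],
                        " channels, kernel expects ", Cin)
  if (kh > H || kw > W) stop("geometry error: kernel larger than padded input")
  geom <- .im2col_geometry(H, W, Cin, kh, kw, stride)
  IDX <- .im2col_batch_idx(geom, H, W, Cin, B)
  X <- .im2col(xp, IDX, geom$K)
  Wm <- matrix(w, geom$K, Cout)
  Y <- cpp_mat_to_nhwc(X %*% Wm, geom$oh, geom$ow, Cout, B, 0L)
  list(y = Y, X = X, IDX = IDX, geom = geom,
       Hp = H, Wp = W, Cin = Cin, Cout = Cout, B = B)
}

.conv_mat_from_dy <- function(dy) {
  d <- dim(dy)
  cpp_nhwc_to_mat(dy, d[1], d[2], d[3], d[4])
}

#' Complex 2-D convolution
#'
#' Convolution of a complex-valued input with a complex-valued kernel,
#' computed over paired real components as
#' `out_re = conv(x_re, w_re) - conv(x_im, w_im)` and
#' `out_im = conv(x_re, w_im) + conv(x_im, w_re)`, i.e. elementwise complex
#' multiplication accumulated over the kernel support. Equal to performing
#' the convolution in native complex arithmetic. The sliding window follows
#' the deep-learning cross-correlation convention; set `flip_kernel = TRUE`
#' for textbook convolution (the two differ by a kernel flip only).
#'
#' @param x `complex_tensor`, shape `(H, W, C_in)` or `(H, W, C_in, B)`.
#' @param w `complex_tensor` kernel, shape `(kh, kw, C_in, C_out)`.
#' @param stride Spatial stride (scalar).
#' @param padding Zero-padding on each spatial side, or `"same"`.
#' @param bias Optional `complex_tensor` of length `C_out`.
#' @param flip_kernel Flip the kernel to get true convolution.
#' @return `complex_tensor` of shape `(oh, ow, C_out[, B])`.
#' @export
complex_conv2d <- function(x, w, stride = 1, padding = 0, bias = NULL,
                           flip_kernel = FALSE) {
  stopifnot(inherits(x, "complex_tensor"), inherits(w, "complex_tensor"))
  wre <- w$re; wim <- w$im
  if (length(dim(wre)) != 4) stop("kernel must be (kh, kw, C_in, C_out)")
  if (flip_kernel) {
    kh <- dim(wre)[1]; kw <- dim(wre)[2]
    wre <- wre[kh:1, kw:1, , , drop = FALSE]
    wim <- wim[kh:1, kw:1, , , drop = FALSE]
  }
  xre <- .as_nhwcb(x$re); xim <- .as_nhwcb(x$im)
  had_batch <- attr(xre, "had_batch")
  pad <- .resolve_padding(padding, dim(wre)[1], stride)
  fr <- .conv_fw_real(xre, wre, stride, pad)
  # reuse geometry for the remaining three real convolutions
  Xim <- .im2col(.pad_spatial(xim, pad), fr$IDX, fr$geom$K)
  Wre <- matrix(wre, fr$geom$K, fr$Cout)
  Wim <- matrix(wim, fr$geom$K, fr$Cout)
  Yre <- fr$X %*% Wre - Xim %*% Wim
  Yim <- fr$X %*% Wim + Xim %*% Wre
  shape_out <- function(Y) {
    dim(Y) <- c(fr$geom$oh, fr$geom$ow, fr$B, fr$Cout)
    aperm(Y, c(1, 2, 4, 3))
  }
  yre <- shape_out(Yre); yim <- shape_out(Yim)
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "complex_tensor"))
    # vector of length oh*ow*C_out, recycled over the batch dimension
    yre <- yre + rep(bias$re, each = fr$geom$P)
    yim <- yim + rep(bias$im, each = fr$geom$P)
  }
  if (!had_batch) {
    dim(yre) <- dim(yre)[1:3]; dim(yim) <- dim(yim)[1:3]
  }
  complex_tensor(yre, yim)
}

#' Complex ReLU (zReLU)
#'
#' Passes a complex value unchanged only when both its real and imaginary
#' parts are strictly positive; otherwise outputs `0 + 0i`. The `"crelu"`
#' mode instead rectifies the two components independently
#' (`relu(re) + i*relu(im)`), which reduces exactly to the ordinary ReLU
#' when the imaginary part is zero; it is used for real-embedding checks.
#'
#' @param z A `complex_tensor`.
#' @param mode `"zrelu"` (default) or `"crelu"`.
#' @return A `complex_tensor` of the same shape.
#' @export
complex_relu <- function(z, mode = c("zrelu", "crelu")) {
  mode <- match.arg(mode)
  stopifnot(inherits(z, "complex_tensor"))
  if (mode == "zrelu") {
    m <- (z$re > 0) & (z$im > 0)
    complex_tensor(z$re * m, z$im * m)
  } else {
    complex_tensor(pmax(z$re, 0), pmax(z$im, 0))
  }
}

#' Complex average pooling
#'
#' Arithmetic mean over non-overlapping spatial windows, applied to the real
#' and imaginary components independently; by linearity this equals the mean
#' of the complex values. Trailing rows/columns that do not fill a window
#' are dropped.
#'
#' @param z `complex_tensor`, shape `(H, W, C[, B])`.
#' @param window Square window side.
#' @param stride Must equal `window` (non-overlapping pooling).
#' @return Pooled `complex_tensor`.
#' @export
complex_avg_pool <- function(z, window = 2, stride = window) {
  stopifnot(inherits(z, "complex_tensor"))
  if (stride != window) stop("only non-overlapping pooling (stride == window) is supported")
  re <- .as_nhwcb(z$re); im <- .as_nhwcb(z$im)
  had_batch <- attr(re, "had_batch")
  yr <- .avg_pool_fw(re, window)$y
  yi <- .avg_pool_fw(im, window)$y
  if (!had_batch) { dim(yr) <- dim(yr)[1:3]; dim(yi) <- dim(yi)[1:3] }
  complex_tensor(yr, yi)
}

.avg_pool_fw <- function(x, w) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  oh <- H %/% w; ow <- W %/% w
  if (oh < 1 || ow < 1) stop("geometry error: window larger than input")
  xs <- x[seq_len(oh * w), seq_len(ow * w), , , drop = FALSE]
  dim(xs) <- c(w, oh, w, ow, C * B)
  tmp <- aperm(xs, c(1, 3, 2, 4, 5))
  dim(tmp) <- c(w * w, oh * ow * C * B)
  y <- colMeans(tmp)
  dim(y) <- c(oh, ow, C, B)
  list(y = y, H = H, W = W, oh = oh, ow = ow, w = w, C = C, B = B)
}

.avg_pool_bw <- function(dy, cache) {
  w <- cache$w
  tmp <- matrix(rep(as.vector(dy) / (w * w), each = w * w),
                w * w, cache$oh * cache$ow * cache$C * cache$B)
  dim(tmp) <- c(w, w, cache$oh, cache$ow, cache$C * cache$B)
  xs <- aperm(tmp, c(1, 3, 2, 4, 5))
  dim(xs) <- c(cache$oh * w, cache$ow * w, cache$C, cache$B)
  if (cache$oh * w == cache$H && cache$ow * w == cache$W) return(xs)
  dx <- array(0, c(cache$H, cache$W, cache$C, cache$B))
  dx[seq_len(cache$oh * w), seq_len(cache$ow * w), , ] <- xs
  dx
}

#' Complex dense (fully connected) layer
#'
#' `y = W x + b` with the bilinear (non-conjugating) complex product:
#' `y_re = W_re x_re - W_im x_im`, `y_im = W_re x_im + W_im x_re`.
#' Set `conjugate_weights = TRUE` for the Hermitian-inner-product variant
#' `y = Conj(W) x`.
#'
#' @param x `complex_tensor`: length-`n` vector or `(n, B)` matrix.
#' @param W `complex_tensor` weight matrix `(m, n)`.
#' @param b Optional `complex_tensor` bias of length `m`.
#' @param conjugate_weights Use the conjugated weight matrix.
#' @return `complex_tensor` of length `m` (or `(m, B)`).
#' @export
complex_linear <- function(x, W, b = NULL, conjugate_weights = FALSE) {
  stopifnot(inherits(x, "complex_tensor"), inherits(W, "complex_tensor"))
  xr <- x$re; xi <- x$im
  vec_in <- is.null(dim(xr)) || length(dim(xr)) == 1
  if (vec_in) { xr <- matrix(as.vector(xr)); xi <- matrix(as.vector(xi)) }
  Wr <- W$re; Wi <- if (conjugate_weights) -W$im else W$im
  if (ncol(Wr) != nrow(xr)) {
    stop("dimension mismatch: W is ", nrow(Wr), "x", ncol(Wr),
         ", x has ", nrow(xr), " rows")
  }
  yr <- Wr %*% xr - Wi %*% xi
  yi <- Wr %*% xi + Wi %*% xr
  if (!is.null(b)) {
    stopifnot(inherits(b, "complex_tensor"))
    yr <- yr + as.vector(b$re)   # recycles down columns over a batch
    yi <- yi + as.vector(b$im)
  }
  if (vec_in) { yr <- as.vector(yr); yi <- as.vector(yi) }
  complex_tensor(yr, yi)
}

#' Magnitude readout
#'
#' Elementwise modulus `sqrt(re^2 + im^2)`, projecting complex class scores
#' to real ones at the output layer.
#'
#' @param z A `complex_tensor`.
#' @return A real array of the same shape.
#' @export
magnitude_readout <- function(z) {
  stopifnot(inherits(z, "complex_tensor"))
  out <- sqrt(z$re^2 + z$im^2)
  dim(out) <- dim(z$re)
  out
}

#' Count trainable parameters of a layer
#'
#' Convolution and dense layers count `prod(kernel) * in * out` weights plus
#' `out` biases; for complex layers that is the count in complex units, and
#' one complex unit equals two trainable real scalars. Pooling and
#' activation layers are parameter-free. Real layers count real scalars
#' whichever unit is requested.
#'
#' @param layer A layer descriptor: a list with `kind` (`"conv"`, `"dense"`,
#'   `"pool"`, `"activation"`), `domain` (`"complex"` or `"real"`), and for
#'   parametric kinds `kernel` (conv only), `n_in`, `n_out`, `bias`.
#' @param unit Count in `"complex"` units or `"real_scalar"` units.
#' @return Integer parameter count.
#' @examples
#' count_parameters(list(kind = "conv", domain = "complex",
#'                       kernel = c(3, 3), n_in = 2, n_out = 4, bias = TRUE),
#'                  unit = "real_scalar")  # 152
#' @export
count_parameters <- function(layer, unit = c("complex", "real_scalar")) {
  unit <- match.arg(unit)
  kind <- layer$kind %||% stop("unresolved geometry: layer has no kind")
  if (kind %in% c("pool", "activation", "flatten", "readout")) return(0L)
  if (!kind %in% c("conv", "dense")) stop("unknown layer kind: ", kind)
  n_in <- layer$n_in; n_out <- layer$n_out
  if (is.null(n_in) || is.null(n_out)) stop("unresolved geometry")
  kmul <- if (kind == "conv") prod(layer$kernel %||% stop("unresolved geometry")) else 1
  n <- kmul * n_in * n_out + (if (isTRUE(layer$bias)) n_out else 0)
  domain <- layer$domain %||% "real"
  if (domain == "complex" && unit == "real_scalar") n <- 2 * n
  as.integer(n)
}
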