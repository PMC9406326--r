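#' Complex tensor carried as paired real arrays
#'
#' A complex-valued multi-axis array stored as two real arrays of identical
#' shape, `re` and `im`. All complex layer operations in this package act on
#' this representation so that ordinary real-valued differentiation can train
#' complex weights (a complex weight is two trainable real scalars, learned
#' jointly).
#'
#' @param re Real component: a numeric vector, matrix or array.
#' @param im Imaginary component, same shape as `re`. Defaults to zeros.
#' @return An object of class `"complex_tensor"`: a list with elements `re`
#'   and `im`.
#' @examples
#' z <- complex_tensor(matrix(1:4, 2), matrix(0, 2, 2))
#' Mod(as_complex_array(z))
#' @export
complex_tensor <- function(re, im = NULL) {
  if (!is.numeric(re)) stop("`re` must be numeric")
  if (is.null(im)) im <- array(0, dim = dim(re) %||% length(re))
  if (!is.numeric(im)) stop("`im` must be numeric")
  dre <- dim(re) %||% length(re)
  dim_im <- dim(im) %||% length(im)
  if (!identical(as.integer(dre), as.integer(dim_im))) {
    stop("real and imaginary components must have identical shape")
  }
  if (!all(is.finite(re)) || !all(is.finite(im))) {
    stop("complex_tensor components must be finite")
  }
  structure(list(re = re, im = im), class = "complex_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a complex tensor to a native complex array
#'
#' @param z A `complex_tensor`.
#' @return A base-R complex array of the same shape.
#' @export
as_complex_array <- function(z) {
  stopifnot(inherits(z, "complex_tensor"))
  out <- complex(real = as.vector(z$re), imaginary = as.vector(z$im))
  dim(out) <- dim(z$re)
  out
}

#' Build a complex tensor from a native complex array
#'
#' @param x A complex (or numeric) array.
#' @return A `complex_tensor`.
#' @export
as_complex_tensor <- function(x) {
  if (inherits(x, "complex_tensor")) return(x)
  re <- Re(x); im <- Im(x)
  dim(re) <- dim(x); dim(im) <- dim(x)
  complex_tensor(re, im)
}

#' @export
print.complex_tensor <- function(x, ...) {
  d <- dim(x$re) %||% length(x$re)
  cat("<complex_tensor> shape [", paste(d, collapse = " x "), "]\n", sep = "")
  if (prod(d) <= 16) print(as_complex_array(x))
  invisible(x)
}

#' @export
dim.complex_tensor <- function(x) dim(x$re)

.ct_map2 <- function(a, b, f) complex_tensor(f(a$re, b$re), f(a$im, b$im))
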