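#' Describe a convolutional network architecture
#'
#' One half of the paired comparison: an ordered layer schedule of three
#' convolution/pool/activation stages, three dense layers and a two-unit
#' output, in either the complex or the real numeric domain. Complex
#' networks prepend the Fourier-domain input conversion (so their effective
#' input width is `floor(W/2) + 1` frequency components) and end with a
#' magnitude readout that projects the two complex class scores to real
#' ones.
#'
#' @param domain `"complex"` or `"real"`.
#' @param input_size Input image side length in pixels.
#' @param in_channels Number of input channels.
#' @param conv_channels Output channels of the three convolution stages.
#' @param dense_units Units of the three fully connected layers.
#' @param kernel Convolution kernel side (odd; `"same"` padding, stride 1).
#' @param pool Average-pooling window (non-overlapping).
#' @param bias Use (complex) biases in conv/dense layers.
#' @param activation Complex nets: `"zrelu"` (default) or `"crelu"`; real
#'   nets always use the ordinary ReLU.
#' @param readout Complex nets: `"magnitude"` (default) or `"real"`
#'   (real-part projection; used for real-embedding checks).
#' @param input_transform Complex nets: `"dft"` (default) applies the
#'   Fourier conversion; `"identity"` feeds the raw input as the real part.
#' @return An object of class `"architecture_spec"`.
#' @export
architecture_spec <- function(domain = c("complex", "real"),
                              input_size = 32,
                              in_channels = 3,
                              conv_channels = c(8, 16, 32),
                              dense_units = c(64, 32, 16),
                              kernel = 3,
                              pool = 2,
                              bias = TRUE,
                              activation = c("zrelu", "crelu"),
                              readout = c("magnitude", "real"),
                              input_transform = c("dft", "identity")) {
  domain <- match.arg(domain)
  activation <- match.arg(activation)
  readout <- match.arg(readout)
  input_transform <- match.arg(input_transform)
  if (input_size < 8) stop("configuration error: input_size must be >= 8")
  if (any(conv_channels < 1) || any(dense_units < 1)) {
    stop("configuration error: channel/unit counts must be positive")
  }
  if (kernel %% 2 != 1) stop("configuration error: kernel must be odd")
  spec <- structure(list(
    domain = domain, input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    conv_channels = as.integer(conv_channels),
    dense_units = as.integer(dense_units),
    kernel = as.integer(kernel), pool = as.integer(pool),
    bias = isTRUE(bias), activation = activation, readout = readout,
    input_transform = input_transform
  ), class = "architecture_spec")
  # resolving the schedule validates the geometry (pooling must not empty
  # the spatial grid)
  network_layers(spec)
  spec
}

#' Resolved layer schedule of an architecture
#'
#' Expands an [architecture_spec()] into ordered layer descriptors with all
#' geometry resolved (channel fan-in/out, flatten width), suitable for
#' [count_parameters()].
#'
#' @param spec An `architecture_spec`.
#' @return A list of layer descriptors.
#' @export
network_layers <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  H <- spec$input_size
  W <- if (spec$domain == "complex" && spec$input_transform == "dft") {
    spec$input_size %/% 2 + 1
  } else {
    spec$input_size
  }
  layers <- list()
  cin <- spec$in_channels
  for (i in seq_along(spec$conv_channels)) {
    cout <- spec$conv_channels[i]
    layers <- c(layers, list(
      list(kind = "conv", domain = spec$domain, kernel = c(spec$kernel, spec$kernel),
           n_in = cin, n_out = cout, bias = spec$bias),
      list(kind = "pool", domain = spec$domain, window = spec$pool),
      list(kind = "activation", domain = spec$domain)
    ))
    H <- H %/% spec$pool
    W <- W %/% spec$pool
    if (H < 1 || W < 1) {
      stop("configuration error: pooling exhausts the spatial grid")
    }
    cin <- cout
  }
  layers <- c(layers, list(list(kind = "flatten", domain = spec$domain)))
  nin <- H * W * cin
  for (u in spec$dense_units) {
    layers <- c(layers, list(
      list(kind = "dense", domain = spec$domain, n_in = nin, n_out = u,
           bias = spec$bias),
      list(kind = "activation", domain = spec$domain)
    ))
    nin <- u
  }
  layers <- c(layers, list(
    list(kind = "dense", domain = spec$domain, n_in = nin, n_out = 2L,
         bias = spec$bias)
  ))
  if (spec$domain == "complex") {
    layers <- c(layers, list(list(kind = "readout", domain = spec$domain)))
  }
  layers
}

#' The shipped parameter-matched architecture pair
#'
#' The default complex/real pair used throughout the package: identical
#' layer schedules (three conv/pool/activation stages, three dense layers,
#' two-unit output), with the real network's first dense layer widened
#' (80 vs 64 units) so that the two networks carry an equivalent number of
#' trainable real scalars (one complex weight = two scalars) despite the
#' complex network's halved input width in the Fourier domain. At the
#' default test scale the totals are 50,244 (complex, in real scalars)
#' versus 50,226 (real), a ratio of 1.0004.
#'
#' @param input_size Input side length (default 32; use 224 for the
#'   full-resolution configuration).
#' @param in_channels Input channels.
#' @param ... Further arguments passed to both [architecture_spec()] calls.
#' @return A list with elements `complex` and `real`.
#' @export
default_architecture_pair <- function(input_size = 32, in_channels = 3, ...) {
  list(
    complex = architecture_spec("complex", input_size = input_size,
                                in_channels = in_channels,
                                dense_units = c(64, 32, 16), ...),
    real = architecture_spec("real", input_size = input_size,
                             in_channels = in_channels,
                             dense_units = c(80, 32, 16), ...)
  )
}

#' Read an architecture from a YAML configuration
#'
#' The file holds the [architecture_spec()] fields by name, e.g.
#' `domain: complex`, `input_size: 32`, `conv_channels: [8, 16, 32]`,
#' `dense_units: [64, 32, 16]`, `kernel: 3`, `pool: 2`, `bias: true`,
#' `activation: zrelu`, `readout: magnitude`, `input_transform: dft`.
#' Omitted fields take the constructor defaults.
#'
#' @param path YAML file path.
#' @return An `architecture_spec`.
#' @export
architecture_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(architecture_spec)), "...")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("configuration error: unknown field(s) ",
         paste(unknown, collapse = ", "))
  }
  do.call(architecture_spec, cfg)
}

#' Instantiate a trainable network from an architecture
#'
#' Draws initial weights (zero-mean Gaussian, variance scaled to the fan-in;
#' a complex weight's two components each carry half the variance budget)
#' and returns a callable model. Complex models apply the Fourier-domain
#' conversion to their input batch and end with the configured readout.
#'
#' @param spec An `architecture_spec`.
#' @param seed Optional integer seed for weight initialisation (the ambient
#'   RNG state is preserved).
#' @return An object of class `"cvfair_network"`.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  descs <- network_layers(spec)
  build <- function() lapply(descs, .build_layer, spec = spec)
  layers <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(spec = spec, layers = layers), class = "cvfair_network")
}

#' Forward pass of a network
#'
#' @param object A `cvfair_network`.
#' @param newdata Real-valued input batch, `(H, W, C)` or `(H, W, C, B)`,
#'   already preprocessed (resized/normalised).
#' @param type `"score"` for the two class scores, `"class"` for 0/1 labels
#'   (class 1 = abnormal wins ties).
#' @param ... Unused.
#' @return A `2 x B` score matrix, or an integer vector of labels.
#' @export
predict.cvfair_network <- function(object, newdata, type = c("score", "class"),
                                   ...) {
  type <- match.arg(type)
  prep <- .prepare_inputs(object, newdata)
  scores <- .net_forward(object, prep, want_cache = FALSE)$scores
  if (type == "score") return(scores)
  as.integer(scores[2, ] >= scores[1, ])
}

#' @export
print.cvfair_network <- function(x, ...) {
  total <- sum(vapply(network_layers(x$spec), count_parameters,
                      numeric(1), unit = "real_scalar"))
  cat("<cvfair_network> ", x$spec$domain, "-valued, input ",
      x$spec$input_size, "x", x$spec$input_size, "x", x$spec$in_channels,
      ", ", total, " trainable real scalars\n", sep = "")
  invisible(x)
}

#' Parameter-parity report for a paired comparison
#'
#' Totals the trainable parameters of both architectures in real-scalar
#' units (one complex weight = two scalars) and checks that the ratio lies
#' within `1 +/- tolerance`, the fairness contract of the paired design.
#'
#' @param cspec Complex-domain `architecture_spec`.
#' @param rspec Real-domain `architecture_spec`.
#' @param tolerance Allowed relative deviation of the ratio from 1.
#' @return An object of class `"parity_report"`: complex total (real
#'   scalars), complex total (complex units), real total, ratio, pass flag.
#' @export
parity_report <- function(cspec, rspec, tolerance = 0.10) {
  stopifnot(inherits(cspec, "architecture_spec"),
            inherits(rspec, "architecture_spec"))
  cl <- network_layers(cspec)
  rl <- network_layers(rspec)
  c_scalars <- sum(vapply(cl, count_parameters, numeric(1), unit = "real_scalar"))
  c_units <- sum(vapply(cl, count_parameters, numeric(1), unit = "complex"))
  r_scalars <- sum(vapply(rl, count_parameters, numeric(1), unit = "real_scalar"))
  ratio <- c_scalars / r_scalars
  structure(list(
    complex_total_real_scalars = c_scalars,
    complex_total_complex_units = c_units,
    real_total = r_scalars,
    ratio = ratio,
    tolerance = tolerance,
    pass = ratio >= 1 - tolerance && ratio <= 1 + tolerance
  ), class = "parity_report")
}

#' @export
print.parity_report <- function(x, ...) {
  cat("Parameter parity (real-scalar units)\n",
      "  complex network: ", x$complex_total_real_scalars,
      " (", x$complex_total_complex_units, " complex units)\n",
      "  real network:    ", x$real_total, "\n",
      sprintf("  ratio: %.4f  [tolerance +/- %.2f]  %s\n", x$ratio,
              x$tolerance, if (x$pass) "PASS" else "FAIL"), sep = "")
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the previous RNG state
#' afterwards, so seeded generation never disturbs the ambient stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
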