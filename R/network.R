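# Internal forward/backward engine. Complex activations are carried as
# plain lists(re, im) of (H, W, C, B) arrays inside the engine to keep the
# hot loop free of S3 dispatch; the public API wraps them as complex_tensor.

.init_array <- function(d, sd) array(stats::rnorm(prod(d), 0, sd), d)

.build_layer <- function(desc, spec) {
  domain <- spec$domain
  switch(desc$kind,
    conv = {
      k <- desc$kernel
      d <- c(k, desc$n_in, desc$n_out)
      fan_in <- prod(k) * desc$n_in
      if (domain == "complex") {
        sd <- sqrt(1 / fan_in)
        list(type = "cconv",
             w = list(re = .init_array(d, sd), im = .init_array(d, sd)),
             b = if (spec$bias) list(re = numeric(desc$n_out),
                                     im = numeric(desc$n_out)))
      } else {
        list(type = "conv", w = .init_array(d, sqrt(2 / fan_in)),
             b = if (spec$bias) numeric(desc$n_out))
      }
    },
    pool = list(type = if (domain == "complex") "cpool" else "pool",
                window = desc$window),
    activation = if (domain == "complex") {
      list(type = "cact", mode = spec$activation)
    } else {
      list(type = "act")
    },
    flatten = list(type = "flatten"),
    dense = {
      fan_in <- desc$n_in
      if (domain == "complex") {
        sd <- sqrt(1 / fan_in)
        list(type = "cdense",
             W = list(re = .init_array(c(desc$n_out, desc$n_in), sd),
                      im = .init_array(c(desc$n_out, desc$n_in), sd)),
             b = if (spec$bias) list(re = numeric(desc$n_out),
                                     im = numeric(desc$n_out)))
      } else {
        list(type = "dense",
             W = .init_array(c(desc$n_out, desc$n_in), sqrt(2 / fan_in)),
             b = if (spec$bias) numeric(desc$n_out))
      }
    },
    readout = list(type = "readout", mode = spec$readout),
    stop("unknown layer descriptor kind: ", desc$kind)
  )
}

.prepare_inputs <- function(net, x) {
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1); d <- dim(x) }
  spec <- net$spec
  if (spec$domain == "real") return(x)
  if (spec$input_transform == "identity") {
    return(list(re = x, im = array(0, d)))
  }
  H <- d[1]; W <- d[2]
  Wp <- W %/% 2 + 1
  Fm <- dft_matrix(W)[seq_len(Wp), , drop = FALSE]
  m <- aperm(x, c(2, 1, 3, 4))
  dim(m) <- c(W, prod(d[-2]))
  Z <- Fm %*% m
  dim(Z) <- c(Wp, H, d[3], d[4])
  Z <- aperm(Z, c(2, 1, 3, 4))
  list(re = array(Re(Z), dim(Z)), im = array(Im(Z), dim(Z)))
}

.layer_forward <- function(layer, x, want_cache) {
  cache <- NULL
  out <- switch(layer$type,
    conv = {
      fr <- .conv_fw_real(x, layer$w, 1L,
                          .resolve_padding("same", dim(layer$w)[1], 1L))
      y <- fr$y
      if (!is.null(layer$b)) y <- y + rep(layer$b, each = fr$geom$P)
      if (want_cache) cache <- fr
      y
    },
    cconv = {
      # fused complex convolution: one gather per component, one stacked
      # GEMM [X_re X_im] %*% [[W_re, W_im], [-W_im, W_re]]
      kdim <- dim(layer$w$re)
      pad <- .resolve_padding("same", kdim[1], 1L)
      xre <- .pad_spatial(x$re, pad); xim <- .pad_spatial(x$im, pad)
      d <- dim(xre); H <- d[1]; W <- d[2]; B <- d[4]
      Cout <- kdim[4]
      geom <- .im2col_geometry(H, W, kdim[3], kdim[1], kdim[2], 1L)
      IDX <- .im2col_batch_idx(geom, H, W, kdim[3], B)
      K <- geom$K
      X2 <- cpp_im2col2(xre, xim, IDX)
      Wre <- matrix(layer$w$re, K, Cout)
      Wim <- matrix(layer$w$im, K, Cout)
      W2 <- rbind(cbind(Wre, Wim), cbind(-Wim, Wre))
      Y2 <- X2 %*% W2
      yre <- cpp_mat_to_nhwc(Y2, geom$oh, geom$ow, Cout, B, 0L)
      yim <- cpp_mat_to_nhwc(Y2, geom$oh, geom$ow, Cout, B, Cout)
      if (!is.null(layer$b)) {
        yre <- yre + rep(layer$b$re, each = geom$P)
        yim <- yim + rep(layer$b$im, each = geom$P)
      }
      if (want_cache) {
        cache <- list(X2 = X2, W2 = W2, IDX = IDX, geom = geom, K = K,
                      Hp = H, Wp = W, Cin = kdim[3], Cout = Cout, B = B,
                      pad = pad)
      }
      list(re = yre, im = yim)
    },
    pool = {
      pf <- .avg_pool_fw(x, layer$window)
      if (want_cache) cache <- pf
      pf$y
    },
    cpool = {
      pr <- .avg_pool_fw(x$re, layer$window)
      pi_ <- .avg_pool_fw(x$im, layer$window)
      if (want_cache) cache <- pr
      list(re = pr$y, im = pi_$y)
    },
    act = {
      m <- x > 0
      if (want_cache) cache <- m
      x * m
    },
    cact = {
      if (layer$mode == "zrelu") {
        m <- (x$re > 0) & (x$im > 0)
        if (want_cache) cache <- list(mre = m, mim = m)
        list(re = x$re * m, im = x$im * m)
      } else {
        mre <- x$re > 0; mim <- x$im > 0
        if (want_cache) cache <- list(mre = mre, mim = mim)
        list(re = x$re * mre, im = x$im * mim)
      }
    },
    flatten = {
      if (is.list(x)) {
        d <- dim(x$re)
        if (want_cache) cache <- d
        n <- prod(d[1:3])
        re <- x$re; im <- x$im
        dim(re) <- c(n, d[4]); dim(im) <- c(n, d[4])
        list(re = re, im = im)
      } else {
        d <- dim(x)
        if (want_cache) cache <- d
        dim(x) <- c(prod(d[1:3]), d[4])
        x
      }
    },
    dense = {
      y <- layer$W %*% x
      if (!is.null(layer$b)) y <- y + layer$b
      if (want_cache) cache <- x
      y
    },
    cdense = {
      # fused complex matrix-vector product on stacked components
      m <- nrow(layer$W$re)
      Wbig <- rbind(cbind(layer$W$re, -layer$W$im),
                    cbind(layer$W$im, layer$W$re))
      X2 <- rbind(x$re, x$im)
      Y2 <- Wbig %*% X2
      yre <- Y2[seq_len(m), , drop = FALSE]
      yim <- Y2[m + seq_len(m), , drop = FALSE]
      if (!is.null(layer$b)) { yre <- yre + layer$b$re; yim <- yim + layer$b$im }
      if (want_cache) cache <- list(X2 = X2, Wbig = Wbig, m = m)
      list(re = yre, im = yim)
    },
    readout = {
      if (layer$mode == "magnitude") {
        y <- sqrt(x$re^2 + x$im^2)
        if (want_cache) cache <- list(x = x, y = y)
        y
      } else {
        if (want_cache) cache <- list(x = x)
        x$re
      }
    },
    stop("unknown layer type: ", layer$type)
  )
  list(out = out, cache = cache)
}

.layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      fr <- cache
      dYm <- .conv_mat_from_dy(dy)
      dW <- crossprod(fr$X, dYm)
      dim(dW) <- dim(layer$w)
      db <- if (!is.null(layer$b)) colSums(dYm)
      dx <- NULL
      if (need_dx) {
        Wm <- matrix(layer$w, fr$geom$K, fr$Cout)
        dXc <- tcrossprod(dYm, Wm)
        pad <- .resolve_padding("same", dim(layer$w)[1], 1L)
        dx <- .col2im(dXc, fr$IDX, fr$Hp, fr$Wp, fr$Cin, fr$B)
        dx <- .unpad_spatial(dx, pad, fr$Hp - 2 * pad, fr$Wp - 2 * pad)
      }
      list(dx = dx, grads = list(w = dW, b = db))
    },
    cconv = {
      K <- cache$K; Cout <- cache$Cout
      dd <- dim(dy$re)
      dY2 <- cpp_nhwc_to_mat2(dy$re, dy$im, dd[1], dd[2], dd[3], dd[4])
      dW2 <- crossprod(cache$X2, dY2)            # (2K x 2Cout) blocks
      i1 <- seq_len(K); i2 <- K + i1
      j1 <- seq_len(Cout); j2 <- Cout + j1
      dWre <- dW2[i1, j1, drop = FALSE] + dW2[i2, j2, drop = FALSE]
      dWim <- dW2[i1, j2, drop = FALSE] - dW2[i2, j1, drop = FALSE]
      dim(dWre) <- dim(layer$w$re); dim(dWim) <- dim(layer$w$im)
      db <- if (!is.null(layer$b)) {
        list(re = colSums(dY2[, j1, drop = FALSE]),
             im = colSums(dY2[, j2, drop = FALSE]))
      }
      dx <- NULL
      if (need_dx) {
        dX2 <- tcrossprod(dY2, cache$W2)
        H <- cache$Hp - 2 * cache$pad; W <- cache$Wp - 2 * cache$pad
        sc <- cpp_col2im2(dX2, cache$IDX,
                          cache$Hp * cache$Wp * cache$Cin * cache$B)
        shape <- c(cache$Hp, cache$Wp, cache$Cin, cache$B)
        dx <- list(
          re = .unpad_spatial(array(sc$re, shape), cache$pad, H, W),
          im = .unpad_spatial(array(sc$im, shape), cache$pad, H, W))
      }
      list(dx = dx,
           grads = list(w = list(re = dWre, im = dWim), b = db))
    },
    pool = list(dx = .avg_pool_bw(dy, cache), grads = NULL),
    cpool = list(dx = list(re = .avg_pool_bw(dy$re, cache),
                           im = .avg_pool_bw(dy$im, cache)), grads = NULL),
    act = list(dx = dy * cache, grads = NULL),
    cact = list(dx = list(re = dy$re * cache$mre, im = dy$im * cache$mim),
                grads = NULL),
    flatten = {
      if (is.list(dy)) {
        dim(dy$re) <- cache; dim(dy$im) <- cache
        list(dx = dy, grads = NULL)
      } else {
        dim(dy) <- cache
        list(dx = dy, grads = NULL)
      }
    },
    dense = {
      x <- cache
      dW <- tcrossprod(dy, x)
      db <- if (!is.null(layer$b)) rowSums(dy)
      list(dx = crossprod(layer$W, dy), grads = list(W = dW, b = db))
    },
    cdense = {
      m <- cache$m
      n <- ncol(layer$W$re)
      dY2 <- rbind(dy$re, dy$im)
      dWbig <- tcrossprod(dY2, cache$X2)          # (2m x 2n) blocks
      r1 <- seq_len(m); r2 <- m + r1
      c1 <- seq_len(n); c2 <- n + c1
      dWre <- dWbig[r1, c1, drop = FALSE] + dWbig[r2, c2, drop = FALSE]
      dWim <- dWbig[r2, c1, drop = FALSE] - dWbig[r1, c2, drop = FALSE]
      db <- if (!is.null(layer$b)) list(re = rowSums(dy$re), im = rowSums(dy$im))
      dX2 <- crossprod(cache$Wbig, dY2)
      list(dx = list(re = dX2[c1, , drop = FALSE], im = dX2[c2, , drop = FALSE]),
           grads = list(W = list(re = dWre, im = dWim), b = db))
    },
    readout = {
      if (layer$mode == "magnitude") {
        x <- cache$x; y <- cache$y
        safe <- pmax(y, 1e-12)
        g <- dy / safe
        list(dx = list(re = g * x$re, im = g * x$im), grads = NULL)
      } else {
        x <- cache$x
        list(dx = list(re = dy, im = array(0, dim(x$im))), grads = NULL)
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

.net_forward <- function(net, prep, want_cache = FALSE) {
  x <- prep
  caches <- if (want_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- .layer_forward(net$layers[[i]], x, want_cache)
    x <- fw$out
    if (want_cache) caches[[i]] <- fw$cache
  }
  list(scores = x, caches = caches)
}

.net_backward <- function(net, caches, dscores) {
  grads <- vector("list", length(net$layers))
  dy <- dscores
  for (i in rev(seq_along(net$layers))) {
    # the first layer needs no input gradient (inputs are not trained)
    bw <- .layer_backward(net$layers[[i]], caches[[i]], dy, need_dx = i > 1)
    grads[i] <- list(bw$grads)   # keep NULL slots for parameter-free layers
    dy <- bw$dx
  }
  grads
}

.net_params <- function(net) {
  lapply(net$layers, function(l) {
    switch(l$type,
      conv = , cconv = list(w = l$w, b = l$b),
      dense = , cdense = list(W = l$W, b = l$b),
      NULL)
  })
}

.net_set_params <- function(net, params) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p)) next
    for (nm in names(p)) net$layers[[i]][[nm]] <- p[[nm]]
  }
  net
}
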