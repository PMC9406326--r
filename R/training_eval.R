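#' Training configuration
#'
#' Hyperparameters of the cross-validated training loop. Defaults follow
#' the published study where stated (learning rate 0.001, Adam with the
#' complex second-moment correction, k = 10 folds); epochs and batch size
#' are this package's defaults for the test-scale problem.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam denominator offset.
#' @param epochs Training epochs per fold.
#' @param batch_size Mini-batch size.
#' @param k Number of cross-validation folds.
#' @param seed Base seed controlling fold assignment, weight init and batch
#'   order.
#' @param loss Loss name; only `"cross_entropy"` (softmax over the two real
#'   class scores) is implemented.
#' @return An object of class `"training_config"`.
#' @export
training_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-8, epochs = 50, batch_size = 16,
                            k = 10, seed = 1, loss = "cross_entropy") {
  if (k < 2) stop("k must be >= 2")
  if (learning_rate < 0) stop("learning rate must be >= 0")
  if (!identical(loss, "cross_entropy")) stop("unknown loss: ", loss)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), k = as.integer(k),
                 seed = as.integer(seed), loss = loss),
            class = "training_config")
}

#' Stratified k-fold split
#'
#' Partitions record indices into `k` validation folds preserving the class
#' proportions: within each class, shuffled indices are dealt round-robin,
#' so per-fold class counts differ by at most one item from the global
#' ratio. Every record is validated exactly once.
#'
#' @param labels Integer/factor label vector (0 = normal, 1 = abnormal), or
#'   a `dataset_manifest`.
#' @param k Number of folds.
#' @param seed Integer seed (shuffling is deterministic given the seed).
#' @return A list of `k` lists with elements `train` and `val`.
#' @export
kfold_split <- function(labels, k = 10, seed = 1) {
  if (inherits(labels, "dataset_manifest")) labels <- labels$labels
  labels <- as.vector(labels)
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  tab <- table(labels)
  if (any(tab < k)) {
    stop("stratification error: class ", names(tab)[which.min(tab)],
         " has fewer than k = ", k, " members")
  }
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    list(train = which(fold_of != i), val = which(fold_of == i))
  })
}

#' One Adam step with the complex second-moment correction
#'
#' Standard Adam for real parameters. For complex parameters (leaves of the
#' form `list(re, im)`) the first moments are tracked per component, while a
#' single second-moment accumulator is shared between the two components and
#' driven by the squared gradient modulus `g_re^2 + g_im^2`; both components
#' are then scaled by the same bias-corrected `1/(sqrt(v_hat) + epsilon)`.
#' This treats each complex weight as one unit when adapting the step size,
#' rather than as two unrelated scalars.
#'
#' @param params Nested list of parameters; leaves are numeric arrays (real
#'   parameters) or `list(re, im)` pairs (complex parameters). `NULL` leaves
#'   are skipped.
#' @param grads Gradients, same structure as `params`.
#' @param state Optimiser state from a previous call, or `NULL` to
#'   initialise zero moments.
#' @param config A [training_config()].
#' @return `list(params, state)` with updated values.
#' @export
complex_adam_step <- function(params, grads, state = NULL, config = training_config()) {
  if (is.null(state)) state <- list(t = 0L, s = NULL)
  t <- state$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  lr <- config$learning_rate; eps <- config$epsilon
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t

  step <- function(p, g, s) {
    if (is.null(p)) return(list(p = NULL, s = NULL))
    if (is.list(p) && !is.null(p$re)) {            # complex leaf
      if (!all(is.finite(g$re)) || !all(is.finite(g$im))) {
        stop("training error: non-finite gradient")
      }
      if (is.null(s)) s <- list(mre = p$re * 0, mim = p$im * 0, v = p$re * 0)
      s$mre <- b1 * s$mre + (1 - b1) * g$re
      s$mim <- b1 * s$mim + (1 - b1) * g$im
      s$v <- b2 * s$v + (1 - b2) * (g$re^2 + g$im^2)
      denom <- sqrt(s$v / bc2) + eps
      p$re <- p$re - lr * (s$mre / bc1) / denom
      p$im <- p$im - lr * (s$mim / bc1) / denom
      list(p = p, s = s)
    } else if (is.list(p)) {                       # interior node
      out_p <- p; out_s <- if (is.null(s)) vector("list", length(p)) else s
      for (i in seq_along(p)) {
        r <- step(p[[i]], g[[i]], if (i <= length(out_s)) out_s[[i]])
        out_p[i] <- list(r$p); out_s[i] <- list(r$s)  # keep NULL slots
      }
      list(p = out_p, s = out_s)
    } else {                                       # real leaf
      if (!all(is.finite(g))) stop("training error: non-finite gradient")
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      p <- p - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      list(p = p, s = s)
    }
  }
  r <- step(params, grads, state$s)
  list(params = r$p, state = list(t = t, s = r$s))
}

.softmax_ce <- function(scores, y) {
  # scores: 2 x B; y: 0/1 labels. Returns loss and dscores.
  B <- ncol(scores)
  m <- pmax(scores[1, ], scores[2, ])
  es <- exp(sweep(scores, 2, m))
  Z <- colSums(es)
  p <- sweep(es, 2, Z, "/")
  picked <- p[cbind(y + 1L, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  d <- p
  d[cbind(y + 1L, seq_len(B))] <- d[cbind(y + 1L, seq_len(B))] - 1
  list(loss = loss, dscores = d / B)
}

#' Train a network on one fold
#'
#' Mini-batch softmax cross-entropy training with [complex_adam_step()].
#' Fully reproducible: batch order is drawn from `config$seed`.
#'
#' @param net A `cvfair_network` from [build_network()].
#' @param x Real input batch `(H, W, C, N)`, already preprocessed.
#' @param y Integer labels (0/1), length `N`.
#' @param config A [training_config()].
#' @return `list(network, loss_trace)`; `loss_trace` has one mean-loss entry
#'   per epoch.
#' @export
train_fold <- function(net, x, y, config = training_config()) {
  N <- length(y)
  if (N == 0) stop("training error: empty training data")
  prep <- .prepare_inputs(net, x)
  params <- .net_params(net)
  state <- NULL
  trace <- numeric(config$epochs)
  orders <- with_seed(config$seed, {
    lapply(seq_len(config$epochs), function(e) sample.int(N))
  })
  slice <- function(p, ids) {
    if (is.list(p)) list(re = p$re[, , , ids, drop = FALSE],
                         im = p$im[, , , ids, drop = FALSE])
    else p[, , , ids, drop = FALSE]
  }
  for (e in seq_len(config$epochs)) {
    ord <- orders[[e]]
    splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    eloss <- 0
    for (ids in splits) {
      xb <- slice(prep, ids)
      fw <- .net_forward(net, xb, want_cache = TRUE)
      lo <- .softmax_ce(fw$scores, y[ids])
      if (!is.finite(lo$loss)) stop("training error: divergence (non-finite loss)")
      grads <- .net_backward(net, fw$caches, lo$dscores)
      st <- complex_adam_step(params, grads, state, config)
      params <- st$params; state <- st$state
      net <- .net_set_params(net, params)
      eloss <- eloss + lo$loss * length(ids)
    }
    trace[e] <- eloss / N
  }
  list(network = net, loss_trace = trace)
}

#' Confusion-matrix metrics
#'
#' The five study metrics from raw confusion counts, with the abnormal
#' class as positive: Precision `TP/(TP+FP)`, Recall/Sensitivity
#' `TP/(TP+FN)`, F1 (harmonic mean), Accuracy `(TP+TN)/total`, Specificity
#' `TN/(TN+FP)`. A ratio with zero denominator is reported as 0 and named
#' in the `flagged` field.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts, total > 0.
#' @return A list with the five metrics plus `flagged` (character vector of
#'   metrics whose denominator was zero).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("degenerate input: all confusion counts are zero")
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    flagged <- unique(c(flagged, "f1_score")); 0
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / sum(counts)
  specificity <- safe(tn, tn + fp, "specificity")
  list(f1_score = f1, precision = precision, recall_sensitivity = recall,
       accuracy = accuracy, specificity = specificity, flagged = flagged)
}

.evaluate_fold <- function(net, x, y) {
  pred <- predict(net, x, type = "class")
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  m <- confusion_metrics(tp, fp, tn, fn)
  # decomposition identity: accuracy is the prevalence-weighted mean of
  # sensitivity and specificity (checked on every evaluation)
  P <- tp + fn; Ng <- tn + fp
  if (P > 0 && Ng > 0) {
    lhs <- m$accuracy
    rhs <- (P * m$recall_sensitivity + Ng * m$specificity) / (P + Ng)
    stopifnot(abs(lhs - rhs) < 1e-12)
  }
  m
}

#' Fold-metric table constructor
#'
#' @param df Data frame with columns `fold`, `f1_score`, `precision`,
#'   `recall_sensitivity`, `accuracy`, `specificity`.
#' @param dataset_id Dataset identifier.
#' @param structure_id `"complex"` or `"real"`.
#' @return The data frame with class `"fold_metric_table"` and id
#'   attributes.
#' @export
fold_metric_table <- function(df, dataset_id, structure_id) {
  needed <- c("fold", "f1_score", "precision", "recall_sensitivity",
              "accuracy", "specificity")
  if (!all(needed %in% names(df))) {
    stop("missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  structure(df[needed], class = c("fold_metric_table", "data.frame"),
            dataset_id = dataset_id, structure_id = structure_id)
}

#' Run the paired cross-validated experiment
#'
#' Trains the complex-valued and real-valued networks under identical
#' conditions: byte-identical stratified fold splits, identical batch-order
#' and initialisation seeds, identical preprocessed inputs (each structure
#' additionally applies its own domain conversion). Evaluates each fold's
#' held-out data with the abnormal class (label 1) as positive.
#'
#' @param manifest A `dataset_manifest` from the synthetic generators (or
#'   any list with `images`, `labels`, `profile`).
#' @param cspec,rspec The paired architecture specs.
#' @param config A [training_config()].
#' @return A list of class `"experiment_result"` with two
#'   [fold_metric_table()]s (`complex`, `real`) and the fold splits.
#' @export
run_experiment <- function(manifest, cspec, rspec,
                           config = training_config()) {
  stopifnot(inherits(cspec, "architecture_spec"),
            inherits(rspec, "architecture_spec"))
  y <- manifest$labels
  imgs <- lapply(manifest$images, normalize_image)
  d <- dim(imgs[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  X <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) X[, , , i] <- imgs[[i]]
  folds <- kfold_split(y, k = config$k, seed = config$seed)
  one_row <- function(spec, fold, i) {
    net <- build_network(spec, seed = config$seed + 1000L * i)
    tr <- train_fold(net, X[, , , fold$train, drop = FALSE], y[fold$train],
                     config)
    m <- .evaluate_fold(tr$network, X[, , , fold$val, drop = FALSE],
                        y[fold$val])
    data.frame(fold = i, f1_score = m$f1_score, precision = m$precision,
               recall_sensitivity = m$recall_sensitivity,
               accuracy = m$accuracy, specificity = m$specificity)
  }
  crows <- list(); rrows <- list()
  for (i in seq_along(folds)) {
    crows[[i]] <- one_row(cspec, folds[[i]], i)
    rrows[[i]] <- one_row(rspec, folds[[i]], i)
  }
  ds <- manifest$profile$name %||% "synthetic"
  structure(list(
    complex = fold_metric_table(do.call(rbind, crows), ds, "complex"),
    real = fold_metric_table(do.call(rbind, rrows), ds, "real"),
    folds = folds
  ), class = "experiment_result")
}
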