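## Feed-forward binary classifier on ray-gap feature vectors.
##
## Architecture: input (N gaps, mm) -> dense hidden layers with ReLU, then
## batch normalization, then dropout -> single sigmoid output.  Training
## uses Adam under a (decaying) triangular cyclic learning rate, weighted
## binary cross-entropy with class balancing, and optional per-epoch
## re-extraction of the training features under random rigid perturbations.
## Positive class: incorrectly seated (output 1).

#' Network architecture specification
#'
#' @param input_dim feature width (number of rays; default 198).
#' @param hidden_sizes hidden-layer widths, default `c(192, 128, 64, 32)`.
#' @param dropout_rate dropout probability after each hidden layer,
#'   default 0.25.
#' @param bn_momentum batch-norm running-statistic momentum, default 0.8:
#'   `running <- 0.8 * running + 0.2 * batch` per update.
#' @return A `network_spec`.
#' @export
network_spec <- function(input_dim = 198L,
                         hidden_sizes = c(192L, 128L, 64L, 32L),
                         dropout_rate = 0.25,
                         bn_momentum = 0.8) {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            bn_momentum > 0, bn_momentum < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 bn_momentum = bn_momentum),
            class = "network_spec")
}

#' Training configuration
#'
#' @param base_lr,max_lr cyclic learning-rate bounds (default 5e-5, 5e-4).
#' @param step_size cyclic half-period in optimizer iterations
#'   (default 2000).
#' @param lr_policy `"triangular2"` (amplitude halves every full cycle;
#'   default) or `"triangular"`.
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 1000).
#' @param class_balancing weight the loss by inverse class frequency
#'   (default `TRUE`).
#' @param standardize z-score features before training (off by default;
#'   raw mm distances are fed directly).
#' @param rng_seed seed controlling init, shuffling and dropout.
#' @return A `training_config`.
#' @export
training_config <- function(base_lr = 5e-5, max_lr = 5e-4,
                            step_size = 2000L,
                            lr_policy = c("triangular2", "triangular"),
                            batch_size = 32L, epochs = 1000L,
                            class_balancing = TRUE,
                            standardize = FALSE,
                            rng_seed = 0L) {
  lr_policy <- match.arg(lr_policy)
  stopifnot(base_lr > 0, base_lr < max_lr, step_size >= 1, batch_size >= 1,
            epochs >= 1)
  structure(list(base_lr = base_lr, max_lr = max_lr,
                 step_size = as.integer(step_size), lr_policy = lr_policy,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_balancing = isTRUE(class_balancing),
                 standardize = isTRUE(standardize),
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

#' Prediction configuration
#'
#' @param cutoff confidence threshold in (0,1); a joint is labeled
#'   incorrectly seated iff its confidence is `>= cutoff` (default 0.2,
#'   chosen low so that sensitivity to seating problems stays high).
#' @export
prediction_config <- function(cutoff = 0.2) {
  stopifnot(cutoff > 0, cutoff < 1)
  structure(list(cutoff = cutoff), class = "prediction_config")
}

#' Cyclic learning rate at a given optimizer iteration
#'
#' Triangular wave between `base_lr` and `max_lr` with half-period
#' `step_size` iterations; `lr(0) = base_lr`, first peak at iteration
#' `step_size`.  Under `"triangular2"` the amplitude halves every full
#' cycle (the decaying schedule).
#'
#' @param iteration 0-based optimizer iteration (vectorized).
#' @param cfg a [training_config].
#' @return Learning rate(s).
#' @export
cyclic_lr <- function(iteration, cfg) {
  stopifnot(all(iteration >= 0))
  cycle <- floor(1 + iteration / (2 * cfg$step_size))
  x <- abs(iteration / cfg$step_size - 2 * cycle + 1)
  scale <- if (cfg$lr_policy == "triangular2") 1 / (2^(cycle - 1)) else 1
  cfg$base_lr + (cfg$max_lr - cfg$base_lr) * pmax(0, 1 - x) * scale
}

#' Inverse-frequency class weights
#'
#' `weight_c = n_total / (2 * n_c)`, so the weighted loss contributions of
#' the two classes equalize.
#'
#' @param labels binary labels (0/1, logical, or `"correct"`/`"incorrect"`).
#' @return named numeric `c(negative = w0, positive = w1)` (negative =
#'   correctly seated).
#' @export
class_weights <- function(labels) {
  y <- encode_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present to compute class weights")
  n <- n0 + n1
  c(negative = n / (2 * n0), positive = n / (2 * n1))
}

# map labels to 0/1 with 1 = positive = incorrectly seated
encode_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("correct", "incorrect"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    as.integer(labels == "incorrect")
  } else {
    y <- as.integer(as.logical(labels))
    if (anyNA(y) || any(!y %in% c(0L, 1L))) stop("labels must be binary")
    y
  }
}

#' Trainable dense parameter count for an architecture
#'
#' Closed form over layer widths (d0, ..., dk, 1):
#' sum of d_i * d_(i+1) + d_(i+1) plus the output layer's dk + 1.
#' Batch-norm scale/shift parameters are counted separately.
#'
#' @param spec a [network_spec].
#' @return list with `dense`, `batchnorm`, `total`.
#' @export
count_parameters <- function(spec) {
  widths <- c(spec$input_dim, spec$hidden_sizes, 1L)
  dense <- sum(widths[-length(widths)] * widths[-1] + widths[-1])
  bn <- 2L * sum(spec$hidden_sizes)
  list(dense = dense, batchnorm = bn, total = dense + bn)
}

## ---- internal network machinery ------------------------------------------

BN_EPS <- 1e-3      # batch-norm variance epsilon
ADAM_EPS <- 1e-7    # Adam denominator epsilon
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999

init_network <- function(spec, seed) {
  widths <- c(spec$input_dim, spec$hidden_sizes)
  with_seed(seed, {
    layers <- vector("list", length(spec$hidden_sizes))
    for (l in seq_along(spec$hidden_sizes)) {
      d_in <- widths[l]; d_out <- widths[l + 1]
      layers[[l]] <- list(
        W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
        b = numeric(d_out),
        gamma = rep(1, d_out), beta = numeric(d_out),
        run_mean = numeric(d_out), run_var = rep(1, d_out))
    }
    d_last <- widths[length(widths)]
    out <- list(W = matrix(rnorm(d_last, sd = sqrt(1 / d_last)), d_last, 1),
                b = 0)
    list(hidden = layers, out = out)
  })
}

forward_pass <- function(net, X, spec, training = FALSE, dropout_masks = NULL) {
  cache <- list(X = X, layers = vector("list", length(net$hidden)))
  H <- X
  for (l in seq_along(net$hidden)) {
    ly <- net$hidden[[l]]
    Z <- sweep(H %*% ly$W, 2L, ly$b, `+`)
    A <- pmax(Z, 0)
    if (training) {
      mu <- colMeans(A)
      Ac <- sweep(A, 2L, mu, `-`)
      v <- colMeans(Ac^2)
      inv_sd <- 1 / sqrt(v + BN_EPS)
      Xhat <- sweep(Ac, 2L, inv_sd, `*`)
      net$hidden[[l]]$run_mean <- spec$bn_momentum * ly$run_mean +
        (1 - spec$bn_momentum) * mu
      net$hidden[[l]]$run_var <- spec$bn_momentum * ly$run_var +
        (1 - spec$bn_momentum) * v
    } else {
      inv_sd <- 1 / sqrt(ly$run_var + BN_EPS)
      Xhat <- sweep(sweep(A, 2L, ly$run_mean, `-`), 2L, inv_sd, `*`)
    }
    B <- sweep(sweep(Xhat, 2L, ly$gamma, `*`), 2L, ly$beta, `+`)
    if (training && spec$dropout_rate > 0) {
      M <- dropout_masks[[l]]
      B <- B * M / (1 - spec$dropout_rate)
    }
    cache$layers[[l]] <- list(H_in = H, Z = Z, A = A, Xhat = Xhat,
                              inv_sd = inv_sd,
                              mask = if (training) dropout_masks[[l]] else NULL)
    H <- B
  }
  z_out <- as.vector(H %*% net$out$W) + net$out$b
  p <- 1 / (1 + exp(-z_out))
  list(p = p, H_last = H, cache = cache, net = net)
}

backward_pass <- function(net, fwd, y, sample_w, spec) {
  n <- length(y)
  grads <- list(hidden = vector("list", length(net$hidden)), out = list())
  # d(loss)/d(z_out) for weighted BCE averaged over the batch
  dz <- sample_w * (fwd$p - y) / n
  grads$out$W <- crossprod(fwd$H_last, dz)
  grads$out$b <- sum(dz)
  dH <- matrix(dz, ncol = 1) %*% t(net$out$W)
  for (l in rev(seq_along(net$hidden))) {
    ly <- net$hidden[[l]]
    cc <- fwd$cache$layers[[l]]
    if (spec$dropout_rate > 0 && !is.null(cc$mask))
      dH <- dH * cc$mask / (1 - spec$dropout_rate)
    dgamma <- colSums(dH * cc$Xhat)
    dbeta <- colSums(dH)
    dXhat <- sweep(dH, 2L, ly$gamma, `*`)
    # batch-norm backward (biased batch variance)
    m <- nrow(dH)
    sum_dXhat <- colSums(dXhat)
    sum_dXhat_xhat <- colSums(dXhat * cc$Xhat)
    dA <- sweep(dXhat, 2L, sum_dXhat / m, `-`) -
      sweep(cc$Xhat, 2L, sum_dXhat_xhat / m, `*`)
    dA <- sweep(dA, 2L, cc$inv_sd, `*`)
    dZ <- dA * (cc$Z > 0)
    grads$hidden[[l]] <- list(W = crossprod(cc$H_in, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dH <- dZ %*% t(ly$W)
  }
  grads
}

adam_init <- function(net) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
    numeric(length(x))
  st <- list(t = 0L, hidden = vector("list", length(net$hidden)), out = list())
  for (l in seq_along(net$hidden)) {
    ly <- net$hidden[[l]]
    st$hidden[[l]] <- list(
      m = lapply(ly[c("W", "b", "gamma", "beta")], zero_like),
      v = lapply(ly[c("W", "b", "gamma", "beta")], zero_like))
  }
  st$out <- list(m = lapply(net$out, zero_like), v = lapply(net$out, zero_like))
  st
}

adam_update <- function(net, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - ADAM_BETA1^state$t
  bc2 <- 1 - ADAM_BETA2^state$t
  upd <- function(par, g, m, v) {
    m <- ADAM_BETA1 * m + (1 - ADAM_BETA1) * g
    v <- ADAM_BETA2 * v + (1 - ADAM_BETA2) * g^2
    par <- par - lr * (m / bc1) / (sqrt(v / bc2) + ADAM_EPS)
    list(par = par, m = m, v = v)
  }
  for (l in seq_along(net$hidden)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(net$hidden[[l]][[nm]], grads$hidden[[l]][[nm]],
               state$hidden[[l]]$m[[nm]], state$hidden[[l]]$v[[nm]])
      net$hidden[[l]][[nm]] <- u$par
      state$hidden[[l]]$m[[nm]] <- u$m
      state$hidden[[l]]$v[[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$out[[nm]], grads$out[[nm]],
             state$out$m[[nm]], state$out$v[[nm]])
    net$out[[nm]] <- u$par
    state$out$m[[nm]] <- u$m
    state$out$v[[nm]] <- u$v
  }
  list(net = net, state = state)
}

## ---- training and prediction ---------------------------------------------

#' Train the feed-forward seating classifier
#'
#' Runs `epochs * ceiling(n / batch_size)` Adam steps under the cyclic
#' learning rate, with batch normalization and dropout active in training
#' mode only, weighted binary cross-entropy, and (optionally) fresh
#' training features every epoch from `feature_provider` — the hook through
#' which the cross-validation harness re-casts rays under newly sampled
#' rigid perturbations each epoch.  Fully reproducible from
#' `cfg$rng_seed`.
#'
#' @param features numeric matrix, joints x `spec$input_dim`.  Used for
#'   every epoch unless `feature_provider` is given.
#' @param labels binary labels aligned with rows (positive = incorrectly
#'   seated).
#' @param spec a [network_spec].
#' @param cfg a [training_config].
#' @param feature_provider optional `function(epoch)` returning the epoch's
#'   training feature matrix (same row order as `labels`).
#' @return A `seating_classifier`: network weights, specs, the per-epoch
#'   mean training-loss trace, and the class weights used.
#' @export
train_classifier <- function(features, labels, spec = network_spec(),
                             cfg = training_config(),
                             feature_provider = NULL) {
  y <- encode_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present for training")
  if (is.null(feature_provider)) {
    features <- as.matrix(features)
    if (ncol(features) != spec$input_dim)
      stop("feature width ", ncol(features), " does not match input_dim ",
           spec$input_dim)
  }
  n <- length(y)
  cw <- if (cfg$class_balancing) class_weights(y) else
    c(negative = 1, positive = 1)
  sample_w_all <- ifelse(y == 1, cw["positive"], cw["negative"])
  center <- NULL; scale_ <- NULL
  net <- init_network(spec, derive_seed(cfg$rng_seed, "init"))
  state <- adam_init(net)
  iter <- 0L
  loss_trace <- numeric(cfg$epochs)
  n_batches <- ceiling(n / cfg$batch_size)
  for (epoch in seq_len(cfg$epochs)) {
    X <- if (is.null(feature_provider)) features else {
      Xe <- as.matrix(feature_provider(epoch))
      if (ncol(Xe) != spec$input_dim || nrow(Xe) != n)
        stop("feature_provider returned a ", nrow(Xe), " x ", ncol(Xe),
             " matrix; expected ", n, " x ", spec$input_dim)
      Xe
    }
    if (cfg$standardize) {
      if (is.null(center)) {       # frozen from the first epoch's features
        center <- colMeans(X)
        scale_ <- apply(X, 2L, sd)
        scale_[scale_ == 0] <- 1
      }
      X <- sweep(sweep(X, 2L, center, `-`), 2L, scale_, `/`)
    }
    perm <- with_seed(derive_seed(cfg$rng_seed, "shuffle", epoch), sample.int(n))
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      rows <- perm[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      wb <- sample_w_all[rows]
      masks <- if (spec$dropout_rate > 0)
        with_seed(derive_seed(cfg$rng_seed, "dropout", epoch, b),
                  lapply(spec$hidden_sizes, function(d)
                    matrix(runif(length(rows) * d) >= spec$dropout_rate,
                           length(rows), d)))
      else NULL
      fwd <- forward_pass(net, Xb, spec, training = TRUE,
                          dropout_masks = masks)
      net <- fwd$net                       # running BN stats updated
      eps <- 1e-12
      loss <- -mean(wb * (yb * log(fwd$p + eps) +
                          (1 - yb) * log(1 - fwd$p + eps)))
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             " (lr = ", signif(cyclic_lr(iter, cfg), 3), ")")
      epoch_loss <- epoch_loss + loss
      grads <- backward_pass(net, fwd, yb, wb, spec)
      au <- adam_update(net, grads, state, cyclic_lr(iter, cfg))
      net <- au$net
      state <- au$state
      iter <- iter + 1L
    }
    loss_trace[epoch] <- epoch_loss / n_batches
  }
  structure(list(net = net, spec = spec, config = cfg,
                 class_weights = cw, loss_trace = loss_trace,
                 center = center, scale = scale_,
                 n_iterations = iter),
            class = "seating_classifier")
}

#' @export
print.seating_classifier <- function(x, ...) {
  cat(sprintf("seating_classifier: %d -> %s -> 1, %d Adam iterations, final loss %.4f\n",
              x$spec$input_dim, paste(x$spec$hidden_sizes, collapse = "-"),
              x$n_iterations, tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict seating labels from ray features
#'
#' Runs the network in inference mode (no dropout; batch normalization
#' uses the running statistics) and thresholds the sigmoid confidence:
#' a joint is labeled incorrectly seated iff confidence `>= cutoff`
#' (boundary inclusive).
#'
#' @param model a trained `seating_classifier`.
#' @param features numeric matrix, joints x input_dim.
#' @param pcfg a [prediction_config] (default cutoff 0.2).
#' @return data.frame with `confidence` in (0,1) and `label`.
#' @export
predict_seating <- function(model, features, pcfg = prediction_config()) {
  stopifnot(inherits(model, "seating_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != model$spec$input_dim)
    stop("feature width ", ncol(features), " does not match input_dim ",
         model$spec$input_dim)
  if (!is.null(model$center))
    features <- sweep(sweep(features, 2L, model$center, `-`),
                      2L, model$scale, `/`)
  fwd <- forward_pass(model$net, features, model$spec, training = FALSE)
  data.frame(confidence = fwd$p,
             label = ifelse(fwd$p >= pcfg$cutoff, "incorrect", "correct"),
             stringsAsFactors = FALSE)
}

#' @export
predict.seating_classifier <- function(object, newdata,
                                       pcfg = prediction_config(), ...) {
  predict_seating(object, newdata, pcfg)
}

#' Save / load a trained classifier as JSON
#'
#' Weights plus the architecture and training configuration are serialized
#' to a single portable JSON file.
#'
#' @param model a `seating_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  ser <- list(
    spec = unclass(model$spec),
    config = unclass(model$config),
    class_weights = as.list(model$class_weights),
    center = model$center, scale = model$scale,
    n_iterations = model$n_iterations,
    loss_trace = model$loss_trace,
    hidden = lapply(model$net$hidden, function(ly)
      lapply(ly, function(p) if (is.matrix(p)) list(dim = dim(p),
                                                    data = as.vector(p))
             else as.vector(p))),
    out = list(W = list(dim = dim(model$net$out$W),
                        data = as.vector(model$net$out$W)),
               b = model$net$out$b))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  unmat <- function(p) if (is.list(p)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p)
  spec <- do.call(network_spec, ser$spec[c("input_dim", "hidden_sizes",
                                           "dropout_rate", "bn_momentum")])
  cfg <- do.call(training_config, ser$config[c("base_lr", "max_lr",
                                               "step_size", "lr_policy",
                                               "batch_size", "epochs",
                                               "class_balancing",
                                               "standardize", "rng_seed")])
  hidden <- lapply(ser$hidden, function(ly) lapply(ly, unmat))
  net <- list(hidden = hidden,
              out = list(W = unmat(ser$out$W), b = as.numeric(ser$out$b)))
  structure(list(net = net, spec = spec, config = cfg,
                 class_weights = unlist(ser$class_weights),
                 loss_trace = as.numeric(ser$loss_trace),
                 center = if (length(ser$center)) as.numeric(ser$center) else NULL,
                 scale = if (length(ser$scale)) as.numeric(ser$scale) else NULL,
                 n_iterations = as.integer(ser$n_iterations)),
            class = "seating_classifier")
}
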