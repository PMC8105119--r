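# The feedforward classifier: a four-layer fully connected network
# (input, two hidden layers of output width 100 and 50, two-way softmax
# output) with CReLU activations on the input and hidden layers, dropout
# between the hidden layers, L2 weight decay and early stopping.
#
# CReLU(z) = [max(z, 0), max(-z, 0)] concatenates the positive and
# negative parts, doubling the width: with p input features the widths
# run p -> 2p -> 100 -> 200 -> 50 -> 100 -> 2. Implemented directly with
# matrix algebra and Adam; the network is small enough that this trains
# in well under a second.

crelu <- function(z) cbind(pmax(z, 0), pmax(-z, 0))

# route the gradient of a CReLU output back to its pre-activation
crelu_back <- function(dout, z) {
  d <- ncol(z)
  dout[, seq_len(d), drop = FALSE] * (z > 0) -
    dout[, d + seq_len(d), drop = FALSE] * (z < 0)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Network hyperparameter specification
#'
#' Defaults follow the small-cohort regime the classifier is built for:
#' hidden output widths 100 and 50, dropout 0.4 between the hidden
#' layers, L2 penalty, Adam (learning rate 1e-3, batch 16), at most 500
#' epochs with patience-20 early stopping on a 10% validation split of
#' the training data.
#'
#' @param hidden_dims integer vector of the two hidden output widths.
#' @param dropout_rate dropout probability between the hidden layers.
#' @param l2_lambda L2 penalty weight on all weight matrices.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stop patience in epochs.
#' @param min_delta smallest monitored-loss drop that counts as an
#'   improvement for early stopping.
#' @param val_frac fraction of training data held out for early
#'   stopping (per class, at least 1 sample; 0 disables the split and
#'   monitors training loss instead).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return list of class `msm_net_spec`.
#' @export
net_spec <- function(hidden_dims = c(100, 50), dropout_rate = 0.4,
                     l2_lambda = 1e-4, learning_rate = 1e-3,
                     batch_size = 16, max_epochs = 500, patience = 20,
                     min_delta = 1e-4, val_frac = 0.1, seed = 1) {
  stopifnot(length(hidden_dims) == 2, dropout_rate >= 0, dropout_rate < 1,
            l2_lambda >= 0, max_epochs >= 1)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "msm_net_spec")
}

net_forward <- function(params, X, dropout_mask = NULL) {
  a0 <- crelu(X)
  z1 <- sweep(a0 %*% params$W1, 2, params$b1, `+`)
  a1 <- crelu(z1)
  if (!is.null(dropout_mask)) a1 <- a1 * dropout_mask
  z2 <- sweep(a1 %*% params$W2, 2, params$b2, `+`)
  a2 <- crelu(z2)
  z3 <- sweep(a2 %*% params$W3, 2, params$b3, `+`)
  list(a0 = a0, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
       probs = softmax_rows(z3))
}

net_loss <- function(params, X, Y, l2) {
  p <- net_forward(params, X)$probs
  ce <- -mean(log(pmax(rowSums(Y * p), 1e-12)))
  ce + l2 * (sum(params$W1^2) + sum(params$W2^2) + sum(params$W3^2))
}

#' Train the feedforward classifier
#'
#' Features are z-standardized internally (the scaler is stored and
#' re-applied at prediction time; zero-variance columns pass through
#' unscaled). Training minimizes cross-entropy plus the L2 penalty with
#' Adam and stops early when the monitored loss has not improved for
#' `patience` epochs, restoring the best weights.
#'
#' @param X numeric feature matrix.
#' @param y logical labels (`TRUE` = positive/sick class).
#' @param spec an `msm_net_spec`.
#' @return fitted model of class `msm_net`.
#' @export
msm_train <- function(X, y, spec = net_spec()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(is.finite(X)))
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, `/`)
  Y <- cbind(!y, y) * 1

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(spec$seed)

  # stratified early-stop split
  n <- nrow(Xs)
  val_idx <- integer(0)
  if (spec$val_frac > 0) {
    for (cls in c(TRUE, FALSE)) {
      ci <- which(y == cls)
      k <- max(1L, floor(spec$val_frac * length(ci)))
      if (length(ci) - k >= 2L)
        val_idx <- c(val_idx, sample(ci, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- Xs[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]
  monitor_val <- length(val_idx) >= 2L

  p <- ncol(Xs)
  h1 <- spec$hidden_dims[1]; h2 <- spec$hidden_dims[2]
  init <- function(nin, nout) matrix(stats::rnorm(nin * nout,
                                                  sd = sqrt(2 / nin)),
                                     nin, nout)
  params <- list(W1 = init(2 * p, h1), b1 = rep(0, h1),
                 W2 = init(2 * h1, h2), b2 = rep(0, h2),
                 W3 = init(2 * h2, 2), b3 = rep(0, 2))
  mom <- lapply(params, function(w) w * 0)
  vel <- lapply(params, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  l2 <- spec$l2_lambda
  keep <- 1 - spec$dropout_rate

  best_loss <- Inf; best_params <- params; wait <- 0L
  n_tr <- nrow(Xtr)
  history <- numeric(0)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n_tr)
    for (start in seq(1L, n_tr, by = spec$batch_size)) {
      bi <- ord[start:min(start + spec$batch_size - 1L, n_tr)]
      Xb <- Xtr[bi, , drop = FALSE]; Yb <- Ytr[bi, , drop = FALSE]
      nb <- length(bi)
      mask <- if (spec$dropout_rate > 0)
        matrix(stats::rbinom(nb * 2 * h1, 1, keep), nb, 2 * h1) / keep
      else NULL
      f <- net_forward(params, Xb, dropout_mask = mask)
      dz3 <- (f$probs - Yb) / nb
      g <- list()
      g$W3 <- crossprod(f$a2, dz3) + 2 * l2 * params$W3
      g$b3 <- colSums(dz3)
      da2 <- tcrossprod(dz3, params$W3)
      dz2 <- crelu_back(da2, f$z2)
      g$W2 <- crossprod(f$a1, dz2) + 2 * l2 * params$W2
      g$b2 <- colSums(dz2)
      da1 <- tcrossprod(dz2, params$W2)
      if (!is.null(mask)) da1 <- da1 * mask
      dz1 <- crelu_back(da1, f$z1)
      g$W1 <- crossprod(f$a0, dz1) + 2 * l2 * params$W1
      g$b1 <- colSums(dz1)
      step <- step + 1L
      lr_t <- spec$learning_rate *
        sqrt(1 - beta2^step) / (1 - beta1^step)
      for (nm in names(params)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr_t * mom[[nm]] / (sqrt(vel[[nm]]) + eps)
      }
    }
    # monitor plain cross-entropy; the L2 term decays smoothly and would
    # mask convergence of the fit itself
    loss <- if (monitor_val) net_loss(params, Xva, Yva, 0)
            else net_loss(params, Xtr, Ytr, 0)
    history <- c(history, loss)
    if (loss < best_loss - spec$min_delta) {
      best_loss <- loss; best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(params = best_params, center = center, scale = scl,
                 spec = spec, n_epochs = length(history),
                 monitor = if (monitor_val) "validation" else "training",
                 best_loss = best_loss, history = history),
            class = "msm_net")
}

#' Predict from a fitted network
#'
#' @param object an `msm_net`.
#' @param newdata numeric feature matrix with the training columns.
#' @param type `"class"` (logical, `TRUE` = sick) or `"prob"` (matrix of
#'   softmax probabilities, columns `not_sick`, `sick`).
#' @param ... unused.
#' @export
predict.msm_net <- function(object, newdata,
                            type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$center))
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  p <- net_forward(object$params, Xs)$probs
  colnames(p) <- c("not_sick", "sick")
  if (type == "prob") p else p[, "sick"] > p[, "not_sick"]
}

#' @export
print.msm_net <- function(x, ...) {
  p <- nrow(x$params$W1) / 2
  cat("<msm_net> ", p, " features -> CReLU -> ",
      ncol(x$params$W1), " -> CReLU/dropout -> ", ncol(x$params$W2),
      " -> CReLU -> 2 (softmax)\n", sep = "")
  cat("  trained ", x$n_epochs, " epoch(s); best ", x$monitor,
      " loss ", signif(x$best_loss, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.msm_net <- function(object, ...) {
  print(object)
  nw <- sum(vapply(object$params, length, integer(1)))
  cat("  parameters: ", nw, "; dropout ", object$spec$dropout_rate,
      "; l2 ", object$spec$l2_lambda, "; seed ", object$spec$seed, "\n",
      sep = "")
  invisible(object)
}
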