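#' Specification of the pattern-classification network
#'
#' A single-hidden-layer feed-forward network: hyperbolic-tangent hidden
#' units (20 by default, fixed across all input configurations of a study
#' run), a 4-way softmax output, and cross-entropy loss, trained by
#' full-batch gradient descent with momentum and an adaptive learning rate
#' (the rate grows while the loss falls and shrinks, with the step
#' rejected, when the loss rises by more than `max_perf_inc`). Training
#' stops early after `patience` consecutive epochs without improvement of
#' the validation loss; the best-validation weights are restored.
#'
#' @param hidden_units Hidden-layer size.
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param lr_inc,lr_dec Multiplicative learning-rate adaptation factors.
#' @param max_perf_inc Maximum tolerated loss increase before a step is
#'   rejected.
#' @param patience Validation-failure budget for early stopping.
#' @param init_scale Half-width of the uniform weight initialization.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden_units = 20, max_epochs = 300,
                            learning_rate = 0.01, momentum = 0.9,
                            lr_inc = 1.05, lr_dec = 0.7,
                            max_perf_inc = 1.04, patience = 6,
                            init_scale = 0.5) {
  structure(list(hidden_units = hidden_units, max_epochs = max_epochs,
                 learning_rate = learning_rate, momentum = momentum,
                 lr_inc = lr_inc, lr_dec = lr_dec,
                 max_perf_inc = max_perf_inc, patience = patience,
                 init_scale = init_scale),
            class = "classifier_spec")
}

## Row-wise softmax with overflow guard.
softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

mlp_forward <- function(X, w) {
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  P <- softmax_rows(sweep(H %*% w$W2, 2, w$b2, "+"))
  list(H = H, P = P)
}

xent <- function(P, y) -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))

## Train one network. X* are numeric matrices (already normalized), y*
## integer class labels 1..4. Returns weights and a convergence flag.
mlp_train <- function(Xtr, ytr, Xval, yval, spec, seed) {
  d <- ncol(Xtr); h <- spec$hidden_units; k <- 4L
  n <- nrow(Xtr)
  w <- with_seed(seed, list(
    W1 = matrix(stats::runif(d * h, -spec$init_scale, spec$init_scale) / sqrt(d), d, h),
    b1 = numeric(h),
    W2 = matrix(stats::runif(h * k, -spec$init_scale, spec$init_scale) / sqrt(h), h, k),
    b2 = numeric(k)
  ))
  v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = w$b2 * 0)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), ytr)] <- 1

  lr <- spec$learning_rate
  fw <- mlp_forward(Xtr, w)
  loss <- xent(fw$P, ytr)
  best <- w
  best_val <- xent(mlp_forward(Xval, w)$P, yval)
  fails <- 0L
  converged <- FALSE

  for (epoch in seq_len(spec$max_epochs)) {
    dL <- (fw$P - Y) / n
    gW2 <- crossprod(fw$H, dL); gb2 <- colSums(dL)
    dH <- (dL %*% t(w$W2)) * (1 - fw$H^2)
    gW1 <- crossprod(Xtr, dH); gb1 <- colSums(dH)

    v_new <- list(W1 = spec$momentum * v$W1 - lr * gW1,
                  b1 = spec$momentum * v$b1 - lr * gb1,
                  W2 = spec$momentum * v$W2 - lr * gW2,
                  b2 = spec$momentum * v$b2 - lr * gb2)
    w_new <- list(W1 = w$W1 + v_new$W1, b1 = w$b1 + v_new$b1,
                  W2 = w$W2 + v_new$W2, b2 = w$b2 + v_new$b2)
    fw_new <- mlp_forward(Xtr, w_new)
    loss_new <- xent(fw_new$P, ytr)

    if (loss_new > loss * spec$max_perf_inc) {
      ## reject the step, cool the learning rate, drop momentum memory
      lr <- lr * spec$lr_dec
      v <- lapply(v, function(z) z * 0)
      next
    }
    lr <- if (loss_new < loss) lr * spec$lr_inc else lr * spec$lr_dec
    w <- w_new; v <- v_new; fw <- fw_new; loss <- loss_new

    val <- xent(mlp_forward(Xval, w)$P, yval)
    if (val < best_val - 1e-9) {
      best_val <- val; best <- w; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= spec$patience) { converged <- TRUE; break }
    }
  }
  list(weights = best, converged = converged, val_loss = best_val)
}

mlp_predict <- function(w, X) max.col(mlp_forward(X, w)$P, ties.method = "first")

## 4x4 confusion matrix in %, rows = true class (row-normalized).
confusion_matrix <- function(y_true, y_pred) {
  m <- matrix(0, 4, 4, dimnames = list(true = NERVES, predicted = NERVES))
  for (i in seq_along(y_true)) m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1
  rs <- rowSums(m)
  rs[rs == 0] <- NA_real_
  sweep(m, 1, rs, "/") * 100
}
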