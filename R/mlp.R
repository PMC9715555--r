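#' Feed-forward softmax classifier (Adam, dropout, weighted loss)
#'
#' Minimal fully connected network used by the decoding module: ReLU hidden
#' layers, softmax output, cross-entropy loss with per-class weights
#' (inverse class frequency by default), inverted dropout on the hidden
#' activations, L2 weight decay, Adam updates, and early stopping on the
#' validation mean per-class accuracy with a fixed patience. Training is
#' deterministic given the seed (initialization, shuffling, dropout).
#'
#' @param x Numeric matrix, samples x features.
#' @param y Factor of training labels.
#' @param val_x,val_y Validation split used for early stopping.
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout Dropout probability on hidden activations.
#' @param weight_decay L2 penalty coefficient.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience, in validation evaluations
#'   (one per epoch).
#' @param class_weights `"balanced"` (inverse class frequency, default),
#'   `"none"`, or a named numeric vector.
#' @param seed Integer seed.
#' @return A `cd_mlp` model (weights at the best validation epoch).
#' @export
mlp_fit <- function(x, y, val_x, val_y, hidden = c(200L, 200L, 200L),
                    dropout = 0.25, weight_decay = 1e-4, lr = 1e-4,
                    batch_size = 64L, max_epochs = 200L, patience = 10L,
                    class_weights = "balanced", seed = 1L) {
  x <- as.matrix(x); val_x <- as.matrix(val_x)
  y <- as.factor(y); lev <- levels(y)
  val_y <- factor(val_y, levels = lev)
  K <- length(lev)
  cw <- if (identical(class_weights, "balanced")) {
    tb <- table(y); w <- sum(tb) / (K * pmax(tb, 1)); as.numeric(w)
  } else if (identical(class_weights, "none")) rep(1, K)
  else as.numeric(class_weights[lev])
  dims <- c(ncol(x), hidden, K)
  nl <- length(dims) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(nl), function(l)
      matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
             dims[l], dims[l + 1L]))
    b <- lapply(seq_len(nl), function(l) numeric(dims[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    yint <- as.integer(y)
    n <- nrow(x)
    best <- list(score = -Inf, W = W, b = b, epoch = 0L)
    stale <- 0L; step <- 0L
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (s0 in seq(1L, n, by = batch_size)) {
        ix <- ord[s0:min(s0 + batch_size - 1L, n)]
        a <- list(x[ix, , drop = FALSE])
        masks <- vector("list", nl - 1L)
        for (l in seq_len(nl - 1L)) {
          z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
          h <- pmax(z, 0)
          if (dropout > 0) {
            mk <- matrix(stats::runif(length(h)) >= dropout, nrow(h)) /
              (1 - dropout)
            h <- h * mk
            masks[[l]] <- mk
          }
          a[[l + 1L]] <- h
        }
        z <- sweep(a[[nl]] %*% W[[nl]], 2, b[[nl]], `+`)
        z <- z - apply(z, 1, max)
        p <- exp(z); p <- p / rowSums(p)
        wt <- cw[yint[ix]]
        g <- p
        g[cbind(seq_along(ix), yint[ix])] <-
          g[cbind(seq_along(ix), yint[ix])] - 1
        g <- g * (wt / sum(wt))
        step <- step + 1L
        for (l in nl:1) {
          gW <- crossprod(a[[l]], g) + weight_decay * W[[l]]
          gb <- colSums(g)
          if (l > 1L) {
            g <- tcrossprod(g, W[[l]])
            g <- g * (a[[l]] > 0)
            if (dropout > 0) g <- g * masks[[l - 1L]]
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
      }
      pred <- .mlp_forward(val_x, W, b)
      score <- mean_per_class_accuracy(lev[max.col(pred)], val_y)
      if (score > best$score + 1e-12) {
        best <- list(score = score, W = W, b = b, epoch = epoch)
        stale <- 0L
      } else stale <- stale + 1L
      if (stale >= patience) break
    }
    structure(list(W = best$W, b = best$b, levels = lev,
                   val_score = best$score, best_epoch = best$epoch,
                   params = list(hidden = hidden, dropout = dropout,
                                 weight_decay = weight_decay, lr = lr,
                                 batch_size = batch_size, seed = seed)),
              class = "cd_mlp")
  })
}

.mlp_forward <- function(x, W, b) {
  a <- as.matrix(x)
  nl <- length(W)
  for (l in seq_len(nl - 1L))
    a <- pmax(sweep(a %*% W[[l]], 2, b[[l]], `+`), 0)
  z <- sweep(a %*% W[[nl]], 2, b[[nl]], `+`)
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p / rowSums(p)
}

#' Predict from a fitted feed-forward classifier
#'
#' @param object A `cd_mlp`.
#' @param newdata Feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a probability matrix.
#' @export
predict.cd_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- .mlp_forward(newdata, object$W, object$b)
  colnames(p) <- object$levels
  if (type == "prob") p
  else factor(object$levels[max.col(p)], levels = object$levels)
}

#' Mean per-class (balanced) accuracy
#'
#' Unweighted mean of the per-class recalls, over the classes present in
#' the truth; equals the unweighted mean of the confusion-matrix diagonal
#' divided by the true class totals.
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @return Scalar in `[0, 1]`.
#' @export
mean_per_class_accuracy <- function(pred, truth) {
  truth <- as.character(truth); pred <- as.character(pred)
  cls <- unique(truth)
  mean(vapply(cls, function(cl) mean(pred[truth == cl] == cl), numeric(1)))
}
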