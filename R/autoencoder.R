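#' Composite-loss autoencoder reduction of protein embeddings
#'
#' Compresses a set of equal-shape embedding matrices (padded or trimmed)
#' into latent vectors of length `latent_dim` while preserving kinase family
#' structure. Each matrix is flattened residue-major, features are
#' standardized over kinases, and a compact dense autoencoder is trained
#' full-batch with Adam: a tanh encoder to the latent space, a linear
#' decoder for reconstruction and a softmax head for family classification.
#' The training loss is `MSE + lambda * cross-entropy`, so the latent space
#' retains both reconstructive detail and family clustering; both loss
#' components are logged per epoch.
#'
#' @param embeddings named list of numeric matrices, all the same shape.
#' @param families character/factor family label per matrix (>= 2 families).
#' @param latent_dim latent vector length; must be smaller than the
#'   flattened input dimension.
#' @param epochs full-batch training epochs.
#' @param lambda weight of the family cross-entropy term (default 1).
#' @param lr Adam learning rate.
#' @param seed integer seed for weight initialization.
#' @return object of class `pcm_reduction`: list with `encode` (function
#'   mapping a matrix or flattened vector to a latent vector), `latents`
#'   (training-set latents, kinases x latent_dim), `log` (data.frame with
#'   per-epoch `mse`, `ce`, `total`) and `families`.
#' @export
fit_reduction <- function(embeddings, families, latent_dim = 16,
                          epochs = 100, lambda = 1, lr = 0.01, seed = 1) {
  stopifnot(length(embeddings) == length(families))
  shapes <- vapply(embeddings, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    pcm_stop("all embedding matrices must share one shape",
             "pcm_consistency_error")
  fam <- factor(families)
  if (nlevels(fam) < 2L)
    pcm_stop("family classification head needs at least 2 families",
             "pcm_degenerate_error")
  X <- do.call(rbind, lapply(embeddings, function(m) as.vector(t(m))))
  d <- ncol(X)
  if (latent_dim >= d)
    pcm_stop("latent_dim must be smaller than the flattened input dimension",
             "pcm_no_compression_error")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  n <- nrow(Xs)
  K <- nlevels(fam)
  Y <- diag(K)[as.integer(fam), , drop = FALSE]

  withr::with_seed(seed, {
    init <- function(r, c, s) matrix(stats::rnorm(r * c, sd = s), r, c)
    W <- list(e = init(d, latent_dim, 0.1 / sqrt(d)),
              be = rep(0, latent_dim),
              d = init(latent_dim, d, 0.1 / sqrt(latent_dim)),
              bd = rep(0, d),
              c = init(latent_dim, K, 0.1 / sqrt(latent_dim)),
              bc = rep(0, K))
    mstate <- lapply(W, function(w) w * 0)
    vstate <- mstate
    b1 <- 0.9; b2 <- 0.999; epsn <- 1e-8
    log_df <- data.frame(epoch = integer(0), mse = numeric(0),
                         ce = numeric(0), total = numeric(0))
    for (ep in seq_len(epochs)) {
      Z <- tanh(sweep(Xs %*% W$e, 2, W$be, "+"))
      Xhat <- sweep(Z %*% W$d, 2, W$bd, "+")
      logits <- sweep(Z %*% W$c, 2, W$bc, "+")
      lm_ <- logits - apply(logits, 1, max)
      P <- exp(lm_) / rowSums(exp(lm_))
      R <- Xhat - Xs
      mse <- mean(R^2)
      ce <- -mean(log(pmax(rowSums(P * Y), 1e-12)))
      log_df <- rbind(log_df, data.frame(epoch = ep, mse = mse, ce = ce,
                                         total = mse + lambda * ce))
      dXhat <- 2 * R / (n * d)
      dLog <- lambda * (P - Y) / n
      dZ <- dXhat %*% t(W$d) + dLog %*% t(W$c)
      dPre <- dZ * (1 - Z^2)
      g <- list(e = t(Xs) %*% dPre, be = colSums(dPre),
                d = t(Z) %*% dXhat, bd = colSums(dXhat),
                c = t(Z) %*% dLog, bc = colSums(dLog))
      for (k in names(W)) {
        mstate[[k]] <- b1 * mstate[[k]] + (1 - b1) * g[[k]]
        vstate[[k]] <- b2 * vstate[[k]] + (1 - b2) * g[[k]]^2
        mhat <- mstate[[k]] / (1 - b1^ep)
        vhat <- vstate[[k]] / (1 - b2^ep)
        W[[k]] <- W[[k]] - lr * mhat / (sqrt(vhat) + epsn)
      }
    }
  })
  encode <- function(m) {
    v <- if (is.matrix(m) && nrow(m) > 1L) as.vector(t(m)) else as.numeric(m)
    vs <- (v - mu) / sd_
    as.numeric(tanh(vs %*% W$e + W$be))
  }
  latents <- t(vapply(embeddings, encode, numeric(latent_dim)))
  rownames(latents) <- names(embeddings)
  structure(list(encode = encode, latents = latents, log = log_df,
                 families = fam, latent_dim = latent_dim, lambda = lambda),
            class = "pcm_reduction")
}

#' @export
print.pcm_reduction <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "pcm_reduction: %d kinases -> latent %d; final loss %.4f (mse %.4f, ce %.4f)\n",
    nrow(x$latents), x$latent_dim, last$total, last$mse, last$ce))
  invisible(x)
}

#' Nearest-centroid family probe
#'
#' Simple deterministic linear probe used to compare representations:
#' classifies held-out rows by the nearest training-set family centroid
#' (Euclidean distance).
#'
#' @param train,test numeric matrices (rows = kinases).
#' @param train_fam,test_fam family labels.
#' @return held-out accuracy in `[0, 1]`.
#' @export
centroid_probe_accuracy <- function(train, train_fam, test, test_fam) {
  fams <- unique(train_fam)
  cent <- t(vapply(fams, function(f)
    colMeans(train[train_fam == f, , drop = FALSE]), numeric(ncol(train))))
  d2 <- outer(rowSums(test^2), rowSums(cent^2), "+") - 2 * test %*% t(cent)
  mean(fams[max.col(-d2, ties.method = "first")] == test_fam)
}
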