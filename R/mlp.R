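## A small fully-connected ReLU network for the tabular baselines: two
## hidden layers plus a sigmoid output (three weight layers), Adam with
## mini-batches, early stopping on validation AUROC. Shares the Adam
## implementation with the graph model.

mlp_init <- function(p, hidden, seed) {
  with_seed(seed, {
    dims <- c(p, hidden, 1L)
    lapply(seq_len(length(dims) - 1L), function(i)
      list(W = glorot(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L])))
  })
}

mlp_forward <- function(params, X) {
  acts <- list(X)
  nl <- length(params)
  for (i in seq_len(nl)) {
    Z <- sweep(acts[[i]] %*% params[[i]]$W, 2, params[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < nl) pmax(Z, 0) else Z
  }
  list(acts = acts, logits = drop(acts[[nl + 1L]]))
}

mlp_backward <- function(params, fwd, y) {
  nl <- length(params)
  n <- length(y)
  p <- expit(fwd$logits)
  delta <- matrix((p - y) / n, ncol = 1L)
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    grads[[i]] <- list(W = crossprod(fwd$acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% t(params[[i]]$W)
      delta <- delta * (fwd$acts[[i]] > 0)
    }
  }
  grads
}

mlp_fit <- function(X, y, X_val = NULL, y_val = NULL, hidden = c(64L, 32L),
                    lr = 1e-3, epochs = 200L, batch_size = 200L, l2 = 1e-4,
                    patience = 20L, seed = 1L) {
  params <- mlp_init(ncol(X), hidden, child_seed(seed, "mlp_init"))
  state <- adam_init(params)
  best <- list(params = params, auroc = -Inf); wait <- 0L
  with_seed(child_seed(seed, "mlp_train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(X))
      for (b in seq_len(ceiling(nrow(X) / batch_size))) {
        rows <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, nrow(X))]
        fwd <- mlp_forward(params, X[rows, , drop = FALSE])
        grads <- mlp_backward(params, fwd, y[rows])
        grads <- tree_map2(function(g, p) g + l2 * p, grads, params)
        res <- adam_step(params, grads, state, lr)
        params <- res$params; state <- res$state
      }
      if (!is.null(X_val)) {
        va <- auroc(y_val, expit(mlp_forward(params, X_val)$logits))
        if (va > best$auroc + 1e-12) { best <- list(params = params, auroc = va); wait <- 0L }
        else { wait <- wait + 1L; if (wait >= patience) break }
      }
    }
  })
  list(params = if (!is.null(X_val)) best$params else params,
       hidden = hidden, val_auroc = if (!is.null(X_val)) best$auroc else NA_real_)
}

mlp_predict <- function(fit, X) expit(mlp_forward(fit$params, X)$logits)
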