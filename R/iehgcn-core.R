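## ie-HGCN computational core.
##
## Each layer l computes, for every node type Omega:
##   Z_self  = H^{l-1}_Omega W_{Omega-Omega}
##   Z_Gamma = Ahat_{Omega-Gamma} H^{l-1}_Gamma W_{Gamma-Omega}
## with Ahat the row-normalized adjacency, then mixes the candidate messages
## with per-node type-level attention
##   e_r = ELU( [Z_r W_k^r || Z_self W_q] . w_a ),  a = softmax over relations
##   H^l_Omega = ELU( sum_r a_r * Z_r )
## The concatenated attention projection is evaluated as
## Z_r (W_k^r w_a1) + Z_self (W_q w_a2), with w_a split in halves.
##
## Gradients are reverse-mode, derived by hand for this fixed architecture;
## a finite-difference check lives in the test suite.

## ---- graph preprocessing ---------------------------------------------------

## Precompute per-target row-normalized adjacencies and neighbor sets.
graph_tensors <- function(g) {
  types <- names(g$schema)[vapply(g$schema, length, 1L) > 0]
  nbrs <- stats::setNames(vector("list", length(types)), types)
  ahat <- stats::setNames(vector("list", length(types)), types)
  for (tp in types) {
    nb <- character(0)
    for (other in setdiff(types, tp)) {
      A <- hetgraph_adjacency(g, tp, other)
      if (!is.null(A) && length(A@x) > 0) {
        nb <- c(nb, other)
        ahat[[tp]][[other]] <- row_normalize(A)
      }
    }
    nbrs[[tp]] <- nb
  }
  n <- vapply(g$schema, length, 1L)
  list(types = types, nbrs = nbrs, ahat = ahat, n = n[types],
       enc_features = g$enc_features)
}

## ---- parameters ------------------------------------------------------------

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize ie-HGCN parameters
#'
#' Three stacked layers; the final layer projects every type to the
#' 2-dimensional output. Featureless node types (providers, care units, and
#' encounters in the no-feature ablation) receive trainable per-node
#' embedding vectors of width `embed_dim`; `featureless_init = "onehot"`
#' instead uses a fixed identity input (useful for exactness tests).
#'
#' @param gt graph tensors (internal) or a `hetgraph`.
#' @param hidden_dim width of the two hidden layers.
#' @param attn_dim width of the attention key/query space.
#' @param embed_dim embedding width for featureless types (default
#'   `hidden_dim`).
#' @param featureless_init `"embedding"` or `"onehot"`.
#' @param out_dim output classes (2).
#' @param seed integer seed.
#' @return parameter list (layers, embeddings, dims).
#' @export
init_iehgcn_params <- function(gt, hidden_dim = 32L, attn_dim = 16L,
                               embed_dim = hidden_dim,
                               featureless_init = c("embedding", "onehot"),
                               out_dim = 2L, seed = 1L) {
  if (inherits(gt, "hetgraph")) gt <- graph_tensors(gt)
  featureless_init <- match.arg(featureless_init)
  with_seed(seed, {
    d_in <- stats::setNames(numeric(length(gt$types)), gt$types)
    embed <- list()
    for (tp in gt$types) {
      if (tp == "ENC" && !is.null(gt$enc_features)) {
        d_in[tp] <- ncol(gt$enc_features)
      } else if (featureless_init == "embedding") {
        embed[[tp]] <- matrix(stats::runif(gt$n[[tp]] * embed_dim, -0.5, 0.5),
                              gt$n[[tp]], embed_dim)
        d_in[tp] <- embed_dim
      } else {
        d_in[tp] <- gt$n[[tp]]
      }
    }
    dims <- c(hidden_dim, hidden_dim, out_dim)
    layers <- vector("list", 3L)
    for (l in 1:3) {
      d_out <- dims[l]
      lp <- list()
      for (tp in gt$types) {
        din_self <- if (l == 1) d_in[[tp]] else dims[l - 1]
        W <- list()
        for (nb in gt$nbrs[[tp]]) {
          din_nb <- if (l == 1) d_in[[nb]] else dims[l - 1]
          W[[nb]] <- glorot(din_nb, d_out)
        }
        Wk <- stats::setNames(lapply(c("self", gt$nbrs[[tp]]),
                                     function(r) glorot(d_out, attn_dim)),
                              c("self", gt$nbrs[[tp]]))
        lp[[tp]] <- list(W_self = glorot(din_self, d_out), W = W, Wk = Wk,
                         Wq = glorot(d_out, attn_dim),
                         wa = stats::runif(2L * attn_dim, -0.5, 0.5))
      }
      layers[[l]] <- lp
    }
    list(layers = layers, embed = embed, d_in = d_in, dims = dims,
         attn_dim = attn_dim, featureless_init = featureless_init,
         onehot_types = if (featureless_init == "onehot")
           setdiff(gt$types, if (is.null(gt$enc_features)) character(0) else "ENC")
         else character(0))
  })
}

## Input representations H^0 per type.
input_reps <- function(params, gt) {
  H <- list()
  for (tp in gt$types) {
    H[[tp]] <- if (tp == "ENC" && !is.null(gt$enc_features)) {
      unname(as.matrix(gt$enc_features))
    } else if (!is.null(params$embed[[tp]])) {
      params$embed[[tp]]
    } else diag(nrow = gt$n[[tp]])  # one-hot identity
  }
  H
}

## ---- single-target building blocks (exported spec surface) ----------------

#' Per-relation linear projections of one ie-HGCN layer
#'
#' Computes the self message `H_Omega W_self` and, for each neighbor type,
#' the aggregated message `Ahat %*% H_Gamma %*% W_Gamma`.
#'
#' @param H_prev named list of previous-layer representations per type.
#' @param layer_params the layer's parameter block for the target type
#'   (`W_self`, `W`, `Wk`, `Wq`, `wa`).
#' @param ahat named list of row-normalized adjacencies (target rows).
#' @param target target node type name.
#' @return named list of projected matrices: `self` plus one per neighbor.
#' @export
project <- function(H_prev, layer_params, ahat, target) {
  lp <- layer_params
  if (ncol(H_prev[[target]]) != nrow(lp$W_self))
    stopf("shape mismatch for self-relation of '%s': %d features vs %d rows of W",
          target, ncol(H_prev[[target]]), nrow(lp$W_self))
  Z <- list(self = H_prev[[target]] %*% lp$W_self)
  for (nb in names(lp$W)) {
    if (ncol(H_prev[[nb]]) != nrow(lp$W[[nb]]))
      stopf("shape mismatch for relation '%s-%s'", nb, target)
    Z[[nb]] <- as.matrix(ahat[[nb]] %*% H_prev[[nb]]) %*% lp$W[[nb]]
  }
  Z
}

#' Type-level attention coefficients for one target type
#'
#' Attention logit of relation r at node v is
#' `ELU([Z_r(v) W_k^r || Z_self(v) W_q] . w_a)`; coefficients are the
#' softmax over the relation set (self plus neighbors) per node, so each
#' node's coefficients sum to 1.
#'
#' @param Z named list from [project()] (must contain `self`).
#' @param layer_params the target type's parameter block.
#' @return matrix of coefficients, one row per node, one column per relation.
#' @export
type_attention <- function(Z, layer_params) {
  rels <- names(Z)
  if (length(rels) == 0L) stopf("no relations to attend over")
  at <- attention_internal(Z, layer_params)
  at$a
}

attention_internal <- function(Z, lp) {
  da <- length(lp$wa) / 2L
  wa1 <- lp$wa[seq_len(da)]; wa2 <- lp$wa[da + seq_len(da)]
  v_q <- lp$Wq %*% wa2
  q <- drop(Z$self %*% v_q)
  rels <- names(Z)
  pre <- vapply(rels, function(r) drop(Z[[r]] %*% (lp$Wk[[r]] %*% wa1)) + q,
                numeric(nrow(Z$self)))
  pre <- matrix(pre, nrow = nrow(Z$self), dimnames = list(NULL, rels))
  E <- elu(pre)
  a <- softmax_rows(E)
  list(a = a, pre = pre, q = q, wa1 = wa1, wa2 = wa2, v_q = v_q)
}

#' One ie-HGCN layer for every node type
#'
#' Combines [project()] and [type_attention()] and applies the ELU
#' activation: `H_out = ELU(sum_r a_r * Z_r)` with per-node coefficient
#' broadcast. Dropout (on layer inputs) and batch normalization (on the
#' encounter pre-activation of hidden layers) are applied only in training
#' mode by the fitting routine, not by this inference-path helper.
#'
#' @param H_prev named list of representations per type.
#' @param layer named list of per-type parameter blocks (one ie-HGCN layer).
#' @param gt graph tensors or `hetgraph`.
#' @param activation apply the ELU (final-layer logits also use ELU, matching
#'   the stacked formulation).
#' @return list with `H` (per-type outputs) and `attention` (per-type
#'   coefficient matrices).
#' @export
layer_forward <- function(H_prev, layer, gt, activation = TRUE) {
  if (inherits(gt, "hetgraph")) gt <- graph_tensors(gt)
  H <- list(); att <- list()
  for (tp in gt$types) {
    Z <- project(H_prev, layer[[tp]], gt$ahat[[tp]], tp)
    a <- type_attention(Z, layer[[tp]])
    S <- matrix(0, nrow(Z$self), ncol(Z$self))
    for (r in names(Z)) S <- S + a[, r] * Z[[r]]
    H[[tp]] <- if (activation) elu(S) else S
    att[[tp]] <- a
  }
  list(H = H, attention = att)
}

## ---- full forward with caches ----------------------------------------------

## Forward pass through all three layers. In training mode, applies inverted
## dropout to layer inputs and (optionally) batch normalization to the ENC
## pre-activation of hidden layers. Returns output logits, attention record
## and the caches needed for backprop.
iehgcn_forward <- function(params, gt, training = FALSE, dropout = 0,
                           batch_norm = FALSE, bn_eps = 1e-5) {
  H_prev <- input_reps(params, gt)
  caches <- vector("list", 3L)
  attrec <- vector("list", 3L)
  L <- length(params$layers)
  for (l in seq_len(L)) {
    lp <- params$layers[[l]]
    masks <- NULL
    Hd <- H_prev
    if (training && dropout > 0) {
      masks <- lapply(H_prev, function(h)
        matrix(stats::rbinom(length(h), 1, 1 - dropout) / (1 - dropout),
               nrow(h), ncol(h)))
      Hd <- mapply(function(h, m) h * m, H_prev, masks, SIMPLIFY = FALSE)
    }
    H_new <- list(); cache_l <- list(); att_l <- list()
    for (tp in gt$types) {
      M <- list()  # Ahat %*% H_Gamma, kept for weight gradients
      Z <- list(self = Hd[[tp]] %*% lp[[tp]]$W_self)
      for (nb in gt$nbrs[[tp]]) {
        M[[nb]] <- as.matrix(gt$ahat[[tp]][[nb]] %*% Hd[[nb]])
        Z[[nb]] <- M[[nb]] %*% lp[[tp]]$W[[nb]]
      }
      at <- attention_internal(Z, lp[[tp]])
      S <- matrix(0, nrow(Z$self), ncol(Z$self))
      for (r in names(Z)) S <- S + at$a[, r] * Z[[r]]
      bn <- NULL
      S_bn <- S
      if (batch_norm && tp == "ENC" && l < L && nrow(S) > 1) {
        mu <- colMeans(S)
        va <- colMeans(sweep(S, 2, mu)^2)
        xhat <- sweep(sweep(S, 2, mu), 2, sqrt(va + bn_eps), "/")
        S_bn <- xhat
        bn <- list(mu = mu, va = va, xhat = xhat)
      }
      H_new[[tp]] <- elu(S_bn)
      att_l[[tp]] <- at$a
      cache_l[[tp]] <- list(Z = Z, M = M, at = at, S = S, S_bn = S_bn, bn = bn)
    }
    caches[[l]] <- list(per_type = cache_l, Hd = Hd, masks = masks,
                        H_in = H_prev)
    attrec[[l]] <- att_l
    H_prev <- H_new
  }
  list(H_out = H_prev, logits = H_prev$ENC, attention = attrec,
       caches = caches)
}

## Backprop given d(loss)/d(logits) for the ENC output. Returns grads with
## the same shape as params.
iehgcn_backward <- function(params, gt, fwd, d_logits, dropout = 0,
                            batch_norm = FALSE, bn_eps = 1e-5) {
  L <- length(params$layers)
  grads <- list(layers = vector("list", L), embed = list())
  dH <- stats::setNames(vector("list", length(gt$types)), gt$types)
  dH[["ENC"]] <- d_logits

  for (l in rev(seq_len(L))) {
    cache <- caches_l <- fwd$caches[[l]]
    lp <- params$layers[[l]]
    gl <- list()
    dH_prev <- stats::setNames(vector("list", length(gt$types)), gt$types)
    for (tp in gt$types) {
      dHout <- dH[[tp]]
      gtp <- list(W_self = matrix(0, nrow(lp[[tp]]$W_self), ncol(lp[[tp]]$W_self)),
                  W = lapply(lp[[tp]]$W, function(w) matrix(0, nrow(w), ncol(w))),
                  Wk = lapply(lp[[tp]]$Wk, function(w) matrix(0, nrow(w), ncol(w))),
                  Wq = matrix(0, nrow(lp[[tp]]$Wq), ncol(lp[[tp]]$Wq)),
                  wa = numeric(length(lp[[tp]]$wa)))
      if (!is.null(dHout)) {
        cc <- cache$per_type[[tp]]
        at <- cc$at
        rels <- colnames(at$a)
        da_dim <- length(lp[[tp]]$wa) / 2L

        dS_bn <- dHout * elu_grad(cc$S_bn)
        if (!is.null(cc$bn)) {
          n <- nrow(dS_bn)
          sd_inv <- 1 / sqrt(cc$bn$va + bn_eps)
          m1 <- colMeans(dS_bn)
          m2 <- colMeans(dS_bn * cc$bn$xhat)
          dS <- sweep(dS_bn, 2, m1) - sweep(cc$bn$xhat, 2, m2, "*")
          dS <- sweep(dS, 2, sd_inv, "*")
        } else dS <- dS_bn

        dZ <- list(); dA <- matrix(0, nrow(dS), length(rels),
                                   dimnames = list(NULL, rels))
        for (r in rels) {
          dZ[[r]] <- at$a[, r] * dS
          dA[, r] <- rowSums(dS * cc$Z[[r]])
        }
        rowdot <- rowSums(at$a * dA)
        dE <- at$a * (dA - rowdot)
        dpre <- dE * elu_grad(at$pre)

        dq <- rowSums(dpre)
        dwa1 <- numeric(da_dim); dwa2 <- numeric(da_dim)
        for (r in rels) {
          u_r <- lp[[tp]]$Wk[[r]] %*% at$wa1
          dk <- dpre[, r]
          dZ[[r]] <- dZ[[r]] + outer(dk, drop(u_r))
          du <- crossprod(cc$Z[[r]], dk)
          gtp$Wk[[r]] <- gtp$Wk[[r]] + du %*% t(at$wa1)
          dwa1 <- dwa1 + drop(crossprod(lp[[tp]]$Wk[[r]], du))
        }
        dv <- crossprod(cc$Z$self, dq)
        gtp$Wq <- gtp$Wq + dv %*% t(at$wa2)
        dwa2 <- dwa2 + drop(crossprod(lp[[tp]]$Wq, dv))
        dZ$self <- dZ$self + outer(dq, drop(at$v_q))
        gtp$wa <- c(dwa1, dwa2)

        gtp$W_self <- crossprod(cache$Hd[[tp]], dZ$self)
        dHd_tp <- dZ$self %*% t(lp[[tp]]$W_self)
        dH_prev[[tp]] <- (dH_prev[[tp]] %||% 0) + dHd_tp
        for (nb in names(lp[[tp]]$W)) {
          gtp$W[[nb]] <- crossprod(cc$M[[nb]], dZ[[nb]])
          dM <- dZ[[nb]] %*% t(lp[[tp]]$W[[nb]])
          dH_prev[[nb]] <- (dH_prev[[nb]] %||% 0) +
            as.matrix(Matrix::crossprod(gt$ahat[[tp]][[nb]], dM))
        }
      }
      gl[[tp]] <- gtp
    }
    ## undo dropout scaling on the input gradients
    if (!is.null(cache$masks))
      for (tp in names(dH_prev))
        if (!is.null(dH_prev[[tp]]) && !is.null(cache$masks[[tp]]))
          dH_prev[[tp]] <- dH_prev[[tp]] * cache$masks[[tp]]
    grads$layers[[l]] <- gl
    dH <- dH_prev
  }
  for (tp in names(params$embed)) {
    g <- dH[[tp]] %||%
      matrix(0, nrow(params$embed[[tp]]), ncol(params$embed[[tp]]))
    dimnames(g) <- NULL  # keep parameter leaves free of adjacency dimnames
    grads$embed[[tp]] <- as.matrix(g)
  }
  grads
}

## ---- loss ------------------------------------------------------------------

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(y log p + (1-y) log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]` before the log.
#'
#' @param y 0/1 vector.
#' @param p probability vector of the same length.
#' @param eps clamping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) stopf("y and p must have the same length")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- parameter-tree helpers ------------------------------------------------

tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), recursive = FALSE, use.names = FALSE)
  else list(x)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}
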