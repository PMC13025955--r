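## Fitting the ie-HGCN: Adam optimization of the binary cross-entropy on
## mini-batches of labeled training encounters (full-graph message passing
## each step, as the graph is transductive), early stopping on validation
## AUROC, and hyperparameter search.

adam_init <- function(params) list(m = tree_map(function(x) x * 0, params),
                                   v = tree_map(function(x) x * 0, params),
                                   t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

align_labels <- function(labels, enc_ids, outcome) {
  if (inherits(labels, "medhg_labels") || (is.data.frame(labels) &&
      "encounter_id" %in% names(labels))) {
    y <- labels[[outcome]][match(enc_ids, labels$encounter_id)]
  } else {
    y <- labels[enc_ids]
  }
  if (any(is.na(y))) stopf("labels must cover every encounter node")
  as.numeric(y)
}

#' Fit an interpretable heterogeneous graph convolutional network
#'
#' The central model of the package: a three-layer heterogeneous GCN with
#' per-relation linear projections, row-normalized neighbour aggregation and
#' softmax-normalized type-level attention, trained with Adam on the binary
#' cross-entropy of the encounter outcome, with early stopping on validation
#' AUROC. Featureless node types (providers, care units) carry trainable
#' per-node embeddings.
#'
#' @param graph a [build_heterograph()] object.
#' @param labels a `medhg_labels` data.frame (or named 0/1 vector over
#'   encounter ids).
#' @param splits a [split_indices()] object, or `NULL` to train on all
#'   encounters without early stopping.
#' @param outcome which label column to fit (`"plos"`, `"mort30"`,
#'   `"mort90"`), ignored when `labels` is a plain vector.
#' @param hidden_dim width of the two hidden layers.
#' @param attn_dim attention key/query width.
#' @param embed_dim embedding width for featureless types.
#' @param lr Adam learning rate.
#' @param l2 L2 penalty coefficient (weight decay `l2 * theta` added to the
#'   gradient).
#' @param dropout dropout rate on layer inputs (training mode only).
#' @param batch_norm standardize the encounter pre-activation of hidden
#'   layers on batch statistics.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation AUROC
#'   improvement); ignored without a validation split.
#' @param batch_size mini-batch size over labeled training encounters.
#' @param featureless_init `"embedding"` or `"onehot"` input representation
#'   for featureless types.
#' @param seed integer seed controlling initialization, batching and dropout;
#'   same seed implies bit-identical fits.
#' @param verbose print per-epoch progress.
#' @return an object of class `iehgcn` with `params` (best-epoch
#'   parameters), `report` (per-epoch loss / validation AUROC), and the
#'   hyperparameters; supports `print`, `summary`, `coef`, `predict`,
#'   `residuals` and `plot`.
#' @export
#' @examples
#' cfg <- synth_config(n_patients = 120, seed = 7)
#' tabs <- generate_cohort(cfg)
#' labs <- derive_outcomes(tabs$encounters)
#' fm <- build_feature_matrix(tabs$encounters)
#' g <- build_heterograph(tabs$encounters, tabs$assignments, tabs$transfers, fm)
#' sp <- split_indices(tabs$encounters, seed = 1)
#' fit <- iehgcn(g, labs, sp, outcome = "plos", hidden_dim = 8, attn_dim = 4,
#'               epochs = 3, seed = 1)
#' head(predict(fit, g))
iehgcn <- function(graph, labels, splits = NULL, outcome = "plos",
                   hidden_dim = 32L, attn_dim = 16L, embed_dim = hidden_dim,
                   lr = 1e-2, l2 = 1e-5, dropout = 0, batch_norm = FALSE,
                   epochs = 100L, patience = 10L, batch_size = 512L,
                   featureless_init = c("embedding", "onehot"), seed = 1L,
                   verbose = FALSE) {
  featureless_init <- match.arg(featureless_init)
  gt <- graph_tensors(graph)
  enc_ids <- graph$schema$ENC
  y <- align_labels(labels, enc_ids, outcome)

  if (is.null(splits)) {
    train_ids <- enc_ids; val_ids <- character(0)
  } else {
    train_ids <- intersect(splits$train, enc_ids)
    val_ids <- intersect(splits$validation, enc_ids)
  }
  if (length(train_ids) == 0L) stopf("empty training split")
  tr_idx <- match(train_ids, enc_ids)
  va_idx <- match(val_ids, enc_ids)

  params <- init_iehgcn_params(gt, hidden_dim = hidden_dim, attn_dim = attn_dim,
                               embed_dim = embed_dim,
                               featureless_init = featureless_init,
                               seed = child_seed(seed, "init"))
  state <- adam_init(params[c("layers", "embed")])
  n_enc <- length(enc_ids)

  report <- data.frame(epoch = integer(0), loss = numeric(0),
                       val_auroc = numeric(0))
  best <- list(params = params, auroc = -Inf, epoch = 0L)
  wait <- 0L; reason <- "max_epochs"

  with_seed(child_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
        fwd <- iehgcn_forward(params, gt, training = TRUE, dropout = dropout,
                              batch_norm = batch_norm)
        prob <- softmax_rows(fwd$logits)
        ep_loss <- ep_loss + bce_loss(y[rows], prob[rows, 2L]) * length(rows)
        dlog <- matrix(0, n_enc, 2L)
        dlog[rows, 1L] <- (prob[rows, 1L] - (1 - y[rows])) / length(rows)
        dlog[rows, 2L] <- (prob[rows, 2L] - y[rows]) / length(rows)
        grads <- iehgcn_backward(params, gt, fwd, dlog, dropout = dropout,
                                 batch_norm = batch_norm)
        if (l2 > 0)  # weight decay on layer weights; embeddings exempt
          grads$layers <- tree_map2(function(g, p) g + l2 * p, grads$layers,
                                    params$layers)
        res <- adam_step(params[c("layers", "embed")],
                         grads, state, lr)
        params[c("layers", "embed")] <- res$params
        state <- res$state
      }
      ep_loss <- ep_loss / length(ord)
      va <- NA_real_
      if (length(va_idx)) {
        p_eval <- predict_probs(params, gt)
        va <- auroc(y[va_idx], p_eval[va_idx])
        if (!is.na(va) && va > best$auroc + 1e-12) {
          best <- list(params = params, auroc = va, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) {
            report <- rbind(report, data.frame(epoch = ep, loss = ep_loss,
                                               val_auroc = va))
            reason <- "early_stopping"
            break
          }
        }
      }
      report <- rbind(report, data.frame(epoch = ep, loss = ep_loss,
                                         val_auroc = va))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val AUROC %s", ep, ep_loss,
                        ifelse(is.na(va), "-", sprintf("%.4f", va))))
    }
  })

  final <- if (length(va_idx) && best$epoch > 0L) best$params else params
  hyper <- list(outcome = outcome, hidden_dim = hidden_dim, attn_dim = attn_dim,
                embed_dim = embed_dim, lr = lr, l2 = l2, dropout = dropout,
                batch_norm = batch_norm, epochs = epochs, patience = patience,
                batch_size = batch_size, featureless_init = featureless_init,
                seed = seed)
  out <- list(params = final, hyper = hyper,
              report = list(history = report,
                            best_epoch = if (length(va_idx)) best$epoch else nrow(report),
                            best_val_auroc = if (length(va_idx)) best$auroc else NA_real_,
                            stopping = reason, seed = seed),
              schema_types = names(graph$schema),
              n_features = if (is.null(graph$enc_features)) 0L
                           else ncol(graph$enc_features),
              y = stats::setNames(y, enc_ids),
              splits = if (is.null(splits)) NULL else
                splits[c("train", "validation", "test")])
  class(out) <- "iehgcn"
  out
}

predict_probs <- function(params, gt) {
  fwd <- iehgcn_forward(params, gt, training = FALSE)
  softmax_rows(fwd$logits)[, 2L]
}

#' Predict outcome probabilities from a fitted ie-HGCN
#'
#' Runs a full-graph forward pass in evaluation mode and returns the
#' positive-class softmax probability per encounter.
#'
#' @param object an `iehgcn` fit.
#' @param graph the `hetgraph` to score (must match the training schema).
#' @param type `"response"` (probabilities) or `"class"` (0/1 at 0.5).
#' @param ... unused.
#' @return named numeric vector over encounter ids.
#' @export
predict.iehgcn <- function(object, graph, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (!identical(names(graph$schema), object$schema_types))
    stopf("graph schema does not match the fitted model (%s vs %s)",
          paste(names(graph$schema), collapse = ","),
          paste(object$schema_types, collapse = ","))
  gt <- graph_tensors(graph)
  p <- stats::setNames(predict_probs(object$params, gt), graph$schema$ENC)
  if (type == "class") ifelse(p > 0.5, 1L, 0L) else p
}

#' @export
print.iehgcn <- function(x, ...) {
  cat(sprintf("ie-HGCN fit (outcome: %s)\n", x$hyper$outcome))
  cat(sprintf("  3 layers, hidden %d, attention dim %d, %d node types\n",
              x$hyper$hidden_dim, x$hyper$attn_dim, length(x$schema_types)))
  cat(sprintf("  epochs run: %d; best epoch %d; best val AUROC %s; stopped: %s\n",
              nrow(x$report$history), x$report$best_epoch,
              ifelse(is.na(x$report$best_val_auroc), "-",
                     sprintf("%.4f", x$report$best_val_auroc)),
              x$report$stopping))
  invisible(x)
}

#' @export
summary.iehgcn <- function(object, ...) {
  print(object)
  np <- sum(vapply(tree_leaves(object$params[c("layers", "embed")]), length, 1L))
  cat(sprintf("  trainable parameters: %d\n", np))
  cat(sprintf("  lr %.3g, L2 %.3g, dropout %.2f, batch_norm %s, batch size %d\n",
              object$hyper$lr, object$hyper$l2, object$hyper$dropout,
              object$hyper$batch_norm, object$hyper$batch_size))
  invisible(object)
}

#' @export
coef.iehgcn <- function(object, ...) object$params

#' @export
residuals.iehgcn <- function(object, graph, ...) {
  p <- predict(object, graph)
  object$y[names(p)] - p
}

#' @export
plot.iehgcn <- function(x, ...) {
  h <- x$report$history
  op <- graphics::par(mfrow = c(1, if (any(!is.na(h$val_auroc))) 2 else 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss", ...)
  if (any(!is.na(h$val_auroc)))
    plot(h$epoch, h$val_auroc, type = "l", xlab = "epoch",
         ylab = "validation AUROC", ...)
  invisible(x)
}

## ---- hyperparameter search -------------------------------------------------

#' Default ie-HGCN search space
#'
#' Learning rate and L2 on `[1e-7, 1e-1]` (log scale), dropout on
#' `[0, 0.8]`, batch normalization on/off, hidden width in
#' \{32, 64, 128, 256\} and attention width in \{8, 16, 32, 64, 128\}.
#'
#' @return named list of dimension specs.
#' @export
iehgcn_search_space <- function() {
  list(lr = list(type = "loguniform", low = 1e-7, high = 1e-1),
       l2 = list(type = "loguniform", low = 1e-7, high = 1e-1),
       dropout = list(type = "uniform", low = 0, high = 0.8),
       batch_norm = list(type = "choice", values = c(FALSE, TRUE)),
       hidden_dim = list(type = "choice", values = c(32L, 64L, 128L, 256L)),
       attn_dim = list(type = "choice", values = c(8L, 16L, 32L, 64L, 128L)))
}

sample_dim <- function(d) switch(d$type,
  loguniform = exp(stats::runif(1, log(d$low), log(d$high))),
  uniform = stats::runif(1, d$low, d$high),
  choice = d$values[[sample.int(length(d$values), 1)]],
  stopf("unknown search dimension type '%s'", d$type))

## Minimal tree-structured Parzen estimator over independent dimensions:
## trials are split at the score quantile gamma; numeric dimensions get a
## Gaussian kernel density per group (candidates scored by the good/bad
## density ratio), categorical dimensions a smoothed count ratio.
tpe_propose <- function(space, log_df, gamma = 0.25, n_cand = 24L) {
  scores <- log_df$score
  cut <- stats::quantile(scores, 1 - gamma, type = 7)
  good <- log_df[scores >= cut, , drop = FALSE]
  bad <- log_df[scores < cut, , drop = FALSE]
  if (nrow(good) == 0L || nrow(bad) == 0L)
    return(lapply(space, sample_dim))
  prop <- list()
  for (nm in names(space)) {
    d <- space[[nm]]
    if (d$type == "choice") {
      vals <- d$values
      pg <- (tabulate(match(good[[nm]], vals), length(vals)) + 1)
      pb <- (tabulate(match(bad[[nm]], vals), length(vals)) + 1)
      prop[[nm]] <- vals[[which.max(pg / pb * stats::runif(length(vals), 0.8, 1.2))]]
    } else {
      tx <- function(x) if (d$type == "loguniform") log(x) else x
      itx <- function(x) if (d$type == "loguniform") exp(x) else x
      g <- tx(as.numeric(good[[nm]])); b <- tx(as.numeric(bad[[nm]]))
      bw <- max(stats::sd(g), (tx(d$high) - tx(d$low)) / 20, na.rm = TRUE)
      cand <- stats::rnorm(n_cand, sample(g, n_cand, replace = TRUE), bw)
      cand <- pmin(pmax(cand, tx(d$low)), tx(d$high))
      dens <- function(x, pts) rowMeans(outer(x, pts, function(u, v)
        stats::dnorm(u, v, bw)))
      ratio <- dens(cand, g) / (dens(cand, b) + 1e-12)
      prop[[nm]] <- itx(cand[which.max(ratio)])
    }
  }
  prop
}

#' Hyperparameter search for the ie-HGCN
#'
#' Maximizes validation AUROC over the search space, by pure random search or
#' a tree-structured Parzen estimator (TPE) with random startup trials. Every
#' trial is trained with the same data seed, so the search is reproducible.
#'
#' @param graph,labels,splits,outcome as in [iehgcn()].
#' @param search_space named list of dimension specs
#'   ([iehgcn_search_space()]).
#' @param n_trials number of trials (>= 1).
#' @param strategy `"random"` or `"tpe"`.
#' @param seed integer seed.
#' @param n_startup random trials before TPE kicks in.
#' @param ... fixed arguments forwarded to [iehgcn()] (e.g. `epochs`).
#' @return list with `best` (hyperparameter list), `best_score`, and `trials`
#'   (data.frame log of every configuration and score).
#' @export
tune_iehgcn <- function(graph, labels, splits, outcome = "plos",
                        search_space = iehgcn_search_space(), n_trials = 10L,
                        strategy = c("random", "tpe"), seed = 1L,
                        n_startup = 5L, ...) {
  strategy <- match.arg(strategy)
  if (n_trials < 1L) stopf("'n_trials' must be >= 1")
  fixed <- list(...)
  trials <- NULL
  with_seed(child_seed(seed, "tune"), {
    for (i in seq_len(n_trials)) {
      cfg <- if (strategy == "tpe" && i > n_startup && !is.null(trials) &&
                 nrow(trials) >= 2L)
        tpe_propose(search_space, trials)
      else lapply(search_space, sample_dim)
      args <- c(list(graph = graph, labels = labels, splits = splits,
                     outcome = outcome, seed = seed), cfg, fixed)
      fit <- do.call(iehgcn, args)
      score <- fit$report$best_val_auroc
      row <- data.frame(trial = i, score = score, cfg,
                        stringsAsFactors = FALSE)
      trials <- if (is.null(trials)) row else rbind(trials, row)
    }
  })
  best_i <- which.max(trials$score)
  best <- as.list(trials[best_i, setdiff(names(trials), c("trial", "score")),
                         drop = FALSE])
  list(best = best, best_score = trials$score[best_i], trials = trials)
}
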