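## Interpretability: meta-path importance from the products of mean
## type-level attention coefficients, plus model-agnostic local attributions
## over encounter features (permutation-sampling Shapley and a LIME-style
## weighted local surrogate).

#' Mean attention coefficients of a fitted ie-HGCN
#'
#' Runs an evaluation-mode forward pass and averages, over target nodes, the
#' per-node normalized attention coefficients of every layer, target type and
#' relation. For each (layer, target type) the means sum to 1.
#'
#' @param model an `iehgcn` fit.
#' @param graph the `hetgraph` it was trained on.
#' @return object of class `mean_attention`: list of `L` layers, each a named
#'   list per target type of named coefficient vectors (`self` plus
#'   neighbours); `as.data.frame()` gives the long table.
#' @export
mean_attention <- function(model, graph) {
  if (!inherits(model, "iehgcn")) stopf("'model' must be an iehgcn fit")
  if (!identical(names(graph$schema), model$schema_types))
    stopf("graph schema does not match the fitted model")
  gt <- graph_tensors(graph)
  fwd <- iehgcn_forward(model$params, gt, training = FALSE)
  out <- lapply(fwd$attention, function(layer)
    lapply(layer, function(a) colMeans(a)))
  class(out) <- "mean_attention"
  out
}

#' @export
as.data.frame.mean_attention <- function(x, ...) {
  rows <- list()
  for (l in seq_along(x))
    for (tp in names(x[[l]]))
      for (r in names(x[[l]][[tp]]))
        rows[[length(rows) + 1L]] <- data.frame(
          layer = l, target = tp, relation = r,
          coefficient = unname(x[[l]][[tp]][[r]]))
  do.call(rbind, rows)
}

#' @export
print.mean_attention <- function(x, ...) {
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

## Score a type chain t0 = ENC, t1, ..., tk under the outward-in convention:
## the output layer's coefficients are the first factors, and paths shorter
## than the model depth are padded with the self coefficient of the terminal
## type on the remaining inner layers.
score_chain <- function(att, chain) {
  L <- length(att)
  k <- length(chain) - 1L
  if (k > L) stopf("path longer than model depth")
  imp <- 1
  for (i in seq_len(k)) {
    lay <- att[[L + 1L - i]]
    tgt <- chain[i]; rel <- chain[i + 1L]
    if (is.null(lay[[tgt]]) || is.na(lay[[tgt]][rel]))
      stopf("relation chain broken at %s-%s (layer %d)", tgt, rel, L + 1L - i)
    imp <- imp * lay[[tgt]][[rel]]
  }
  term <- chain[length(chain)]
  for (l in seq_len(L - k))
    imp <- imp * att[[l]][[term]][["self"]]
  imp
}

#' Meta-path importance ranking
#'
#' A meta-path is a chain of node types starting at the encounter type; its
#' importance is the product of mean attention coefficients along the chain,
#' read from the output layer inward, padded with the terminal type's self
#' coefficients on the remaining inner layers. The pure self chain (`ENC`)
#' represents the encounter's own features. With `all_sequences = TRUE`,
#' every layer-wise relation sequence (self steps allowed anywhere) is
#' enumerated instead; those importances sum to 1 by the softmax
#' normalization.
#'
#' @param att a [mean_attention()] object.
#' @param max_length maximum number of non-self steps (default: model depth).
#' @param paths optional list of explicit type chains (each starting `ENC`)
#'   to score instead of enumerating.
#' @param all_sequences enumerate full-length relation sequences rather than
#'   canonical meta-paths.
#' @return data.frame with `path`, `length`, `importance`, sorted descending.
#' @export
metapath_importance <- function(att, max_length = NULL, paths = NULL,
                                all_sequences = FALSE) {
  L <- length(att)
  if (is.null(max_length)) max_length <- L
  if (max_length > L) stopf("max_length exceeds model depth %d", L)

  if (all_sequences) {
    rows <- list()
    recur <- function(l, tp, seqv, imp) {
      if (l == 0L) {
        rows[[length(rows) + 1L]] <<- data.frame(
          path = paste(seqv, collapse = ","), length = L,
          importance = imp)
        return(invisible())
      }
      for (r in names(att[[l]][[tp]]))
        recur(l - 1L, if (r == "self") tp else r,
              c(seqv, paste0(tp, "<-", r)), imp * att[[l]][[tp]][[r]])
    }
    recur(L, "ENC", character(0), 1)
    out <- do.call(rbind, rows)
    return(out[order(-out$importance), , drop = FALSE])
  }

  if (is.null(paths)) {
    paths <- list()
    grow <- function(chain) {
      paths[[length(paths) + 1L]] <<- chain
      k <- length(chain) - 1L
      if (k >= max_length) return(invisible())
      tgt <- chain[length(chain)]
      lay <- att[[length(att) - k]]
      for (r in setdiff(names(lay[[tgt]]), "self")) grow(c(chain, r))
    }
    grow("ENC")
  } else {
    for (p in paths) if (p[1] != "ENC") stopf("paths must start at ENC")
  }
  out <- data.frame(path = vapply(paths, paste, "", collapse = "-"),
                    length = vapply(paths, length, 1L) - 1L,
                    importance = vapply(paths, function(p)
                      score_chain(att, p), 1))
  rownames(out) <- NULL
  out[order(-out$importance), , drop = FALSE]
}

#' Permutation-sampling Shapley attributions
#'
#' Estimates Shapley values of `predict_fn` at `instance` against a
#' background distribution by sampling feature permutations: for each
#' permutation one background row is drawn and features are switched from
#' background to instance values in permutation order, crediting each feature
#' its marginal change in prediction. The attributions satisfy the efficiency
#' property `sum(phi) = f(x) - mean f(b)` exactly per permutation and hence
#' in expectation.
#'
#' @param predict_fn function taking a numeric matrix (rows = points) and
#'   returning a numeric vector of predictions.
#' @param instance numeric feature vector.
#' @param background numeric matrix (or vector) of reference rows.
#' @param n_permutations number of sampled permutations (>= 1).
#' @param seed integer seed.
#' @return object of class `attribution_report`: `attributions` (named),
#'   `value` (`f(instance)`), `baseline` (mean background prediction over the
#'   sampled rows), `method`, `n`, `seed`.
#' @export
shapley_attribution <- function(predict_fn, instance, background,
                                n_permutations = 200L, seed = 1L) {
  if (is.vector(background)) background <- matrix(background, nrow = 1)
  if (nrow(background) == 0L) stopf("background must be nonempty")
  if (n_permutations < 1L) stopf("'n_permutations' must be >= 1")
  p <- length(instance)
  phi <- numeric(p)
  base_sum <- 0
  with_seed(seed, {
    for (it in seq_len(n_permutations)) {
      b <- background[sample.int(nrow(background), 1L), ]
      perm <- sample.int(p)
      ## p+1 evaluation points: b, then instance values switched on in order
      pts <- matrix(rep(b, p + 1L), nrow = p + 1L, byrow = TRUE)
      for (j in seq_len(p))
        pts[(j + 1L):(p + 1L), perm[j]] <- instance[perm[j]]
      f <- predict_fn(pts)
      phi[perm] <- phi[perm] + diff(f)
      base_sum <- base_sum + f[1L]
    }
  })
  phi <- phi / n_permutations
  names(phi) <- names(instance) %||% colnames(background) %||%
    paste0("x", seq_len(p))
  out <- list(attributions = phi,
              value = predict_fn(matrix(instance, nrow = 1))[1L],
              baseline = base_sum / n_permutations,
              method = "shapley", n = n_permutations, seed = seed)
  class(out) <- "attribution_report"
  out
}

#' LIME-style local surrogate attributions
#'
#' Draws Gaussian perturbations around the instance, weights them with an
#' exponential proximity kernel
#' `exp(-d^2 / kernel_width^2)` and fits a weighted least-squares linear
#' surrogate to the model's predictions; the surrogate coefficients are the
#' attributions. A singular weighted design falls back to a small ridge with
#' a warning.
#'
#' @param predict_fn as in [shapley_attribution()].
#' @param instance numeric feature vector.
#' @param n_samples number of perturbations (>= length(instance) + 1).
#' @param kernel_width proximity kernel width (default
#'   `0.75 * sqrt(length(instance))`, the common heuristic).
#' @param perturb_sd standard deviation of the Gaussian perturbations.
#' @param seed integer seed.
#' @return an `attribution_report` with surrogate coefficients.
#' @export
lime_explain <- function(predict_fn, instance, n_samples = 1000L,
                         kernel_width = 0.75 * sqrt(length(instance)),
                         perturb_sd = 1, seed = 1L) {
  p <- length(instance)
  if (n_samples < p + 1L) stopf("'n_samples' must be >= number of features + 1")
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_samples * p, 0, perturb_sd), n_samples, p)
    Xabs <- sweep(X, 2, instance, "+")
    y <- predict_fn(Xabs)
    w <- exp(-rowSums(X^2) / kernel_width^2)
    D <- cbind(1, X)
    A <- crossprod(D * w, D)
    bvec <- crossprod(D * w, y)
    beta <- tryCatch(solve(A, bvec), error = function(e) {
      warnf("singular weighted design; falling back to ridge")
      solve(A + diag(1e-8 * max(diag(A)), p + 1L), bvec)
    })
  })
  phi <- drop(beta)[-1L]
  names(phi) <- names(instance) %||% paste0("x", seq_len(p))
  out <- list(attributions = phi,
              value = predict_fn(matrix(instance, nrow = 1))[1L],
              baseline = drop(beta)[1L],
              method = "surrogate", n = n_samples, seed = seed)
  class(out) <- "attribution_report"
  out
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("%s attributions (n = %d):\n", x$method, x$n))
  print(round(sort(x$attributions, decreasing = TRUE), 4))
  cat(sprintf("value %.4f, baseline %.4f, attribution sum %.4f\n",
              x$value, x$baseline, sum(x$attributions)))
  invisible(x)
}

#' Prediction function over one encounter's features with the graph held fixed
#'
#' Builds the `predict_fn` used to attribute a fitted ie-HGCN's prediction
#' for a single encounter to its input features: each candidate feature row
#' replaces that encounter's row of the feature matrix while every other node
#' and edge stays fixed.
#'
#' @param model an `iehgcn` fit.
#' @param graph the `hetgraph`.
#' @param encounter_id the encounter to explain.
#' @return function mapping a feature matrix (rows = candidate feature
#'   vectors) to predicted positive-class probabilities.
#' @export
encounter_predict_fn <- function(model, graph, encounter_id) {
  i <- match(encounter_id, graph$schema$ENC)
  if (is.na(i)) stopf("unknown encounter '%s'", encounter_id)
  function(Xrows) {
    vapply(seq_len(nrow(Xrows)), function(r) {
      g2 <- graph
      g2$enc_features[i, ] <- Xrows[r, ]
      predict_probs(model$params, graph_tensors(g2))[i]
    }, 0)
  }
}
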