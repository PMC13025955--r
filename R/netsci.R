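## Network-science comparison arm: the holistic provider-provider
## interaction graph, per-encounter transfer digraphs, a metric battery with
## summary aggregation, and tabular ML baselines fed by those features.

#' Build the provider-provider interaction graph
#'
#' Undirected weighted graph over provider ids; each encounter adds +1 to
#' the edge weight of every pair of its (distinct) providers, so weights
#' count shared encounters. Restricted to the given encounter set (by
#' default, pass training encounters to avoid leakage; pass all encounters
#' for the holistic variant).
#'
#' @param assignments assignment table.
#' @param encounter_ids encounters to include (default: all).
#' @return an [igraph::graph] with `weight` edge attribute.
#' @export
build_provider_graph <- function(assignments,
                                 encounter_ids = unique(assignments$encounter_id)) {
  a <- assignments[assignments$encounter_id %in% encounter_ids, , drop = FALSE]
  if (nrow(a) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  by_enc <- split(a$provider_id, a$encounter_id)
  pairs <- lapply(by_enc, function(p) {
    p <- sort(unique(p))
    if (length(p) < 2L) return(NULL)
    t(utils::combn(p, 2L))
  })
  pairs <- do.call(rbind, pairs)
  providers <- sort(unique(a$provider_id))
  if (is.null(pairs)) {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(providers)
    return(g)
  }
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  w <- table(key)
  uk <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  el <- data.frame(from = uk[, 1], to = uk[, 2], weight = as.numeric(w),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = providers))
}

#' Build one encounter's patient-transfer digraph
#'
#' Nodes are the care-unit types visited; each consecutive pair of stays
#' (by `sequence_index`) contributes a directed edge with multiplicity.
#' Self-transitions (unit X back to X) are excluded; re-entries are still
#' reflected in stay counts and unit-duration covariates elsewhere.
#'
#' @param transfers transfer table.
#' @param encounter_id the encounter.
#' @return a directed [igraph::graph] with `weight` edge attribute.
#' @export
build_transfer_graph <- function(transfers, encounter_id) {
  tr <- transfers[transfers$encounter_id == encounter_id, , drop = FALSE]
  if (nrow(tr) == 0L) stopf("encounter '%s' has no transfer records", encounter_id)
  tr <- tr[order(tr$sequence_index), , drop = FALSE]
  if (!identical(as.integer(tr$sequence_index), seq_len(nrow(tr)) - 1L))
    stopf("non-contiguous sequence_index for encounter '%s'", encounter_id)
  units <- unique(tr$unit_type)
  if (nrow(tr) == 1L)
    return(igraph::make_empty_graph(directed = TRUE) + igraph::vertices(units))
  from <- tr$unit_type[-nrow(tr)]; to <- tr$unit_type[-1L]
  keep <- from != to
  if (!any(keep))
    return(igraph::make_empty_graph(directed = TRUE) + igraph::vertices(units))
  key <- paste(from[keep], to[keep], sep = "\r")
  w <- table(key)
  uk <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  igraph::graph_from_data_frame(
    data.frame(from = uk[, 1], to = uk[, 2], weight = as.numeric(w)),
    directed = TRUE, vertices = data.frame(name = units))
}

hits_authority <- function(g) {
  ## principal-eigenvector authority scores; igraph renamed this helper.
  ## Rescaled to unit Euclidean norm (documented convention).
  a <- if ("hits_scores" %in% getNamespaceExports("igraph"))
    igraph::hits_scores(g)$authority
  else suppressWarnings(igraph::authority_score(g)$vector)
  nrm <- sqrt(sum(a^2))
  if (nrm > 0) a / nrm else a
}

#' Standard node and graph metrics
#'
#' Per node: weighted degree (strength), betweenness / closeness /
#' eigenvector centrality (normalized), average degree connectivity of the
#' node's neighbours, local clustering coefficient, HITS authority and
#' PageRank (damping 0.85). Graph level: density (simple, unweighted), node
#' count and total edge weight. On the undirected provider graph the HITS
#' authority coincides with the principal eigenvector of the adjacency.
#'
#' @param g an igraph graph (possibly directed; may be empty).
#' @return list with `nodes` (data.frame of per-node metrics) and `graph`
#'   (named numeric vector `density`, `n_nodes`, `weighted_edges`).
#' @export
graph_metrics <- function(g) {
  n <- igraph::vcount(g)
  glevel <- c(density = if (n > 1) igraph::edge_density(igraph::simplify(g)) else 0,
              n_nodes = n,
              weighted_edges = if (igraph::ecount(g) > 0)
                sum(igraph::E(g)$weight %||% rep(1, igraph::ecount(g))) else 0)
  if (n == 0L)
    return(list(nodes = data.frame(), graph = glevel))
  fin <- function(x) { x[!is.finite(x)] <- 0; x }  # isolates yield NaN in igraph
  deg <- igraph::strength(g)
  btw <- fin(suppressWarnings(igraph::betweenness(g, normalized = TRUE)))
  clo <- fin(suppressWarnings(igraph::closeness(g, normalized = TRUE)))
  eig <- fin(if (igraph::ecount(g) > 0)
    suppressWarnings(igraph::eigen_centrality(g, directed = FALSE)$vector)
  else rep(0, n))
  adc <- fin(if (igraph::ecount(g) > 0) suppressWarnings(igraph::knn(
    igraph::as_undirected(g, mode = "collapse"))$knn) else rep(0, n))
  clu <- fin(suppressWarnings(igraph::transitivity(g, type = "local",
                                                   isolates = "zero")))
  aut <- fin(if (igraph::ecount(g) > 0) hits_authority(g) else rep(0, n))
  pr <- fin(igraph::page_rank(g, damping = 0.85)$vector)
  nodes <- data.frame(node = igraph::V(g)$name %||% as.character(seq_len(n)),
                      degree = unname(deg), betweenness = unname(btw),
                      closeness = unname(clo), eigenvector = unname(eig),
                      avg_degree_connectivity = unname(adc),
                      clustering = unname(clu), authority = unname(aut),
                      pagerank = unname(pr), stringsAsFactors = FALSE)
  list(nodes = nodes, graph = glevel)
}

#' Aggregate per-node metrics into summary features
#'
#' Five summaries per metric: maximum, minimum, mean, median and
#' interquartile range (linear-interpolation quartiles). An empty node table
#' yields the fill value with a `missing` flag.
#'
#' @param node_table the `nodes` data.frame from [graph_metrics()].
#' @param fill fill value for empty tables.
#' @return named numeric vector `<metric>_<summary>` plus `missing`.
#' @export
aggregate_metrics <- function(node_table, fill = 0) {
  metrics <- c("degree", "betweenness", "closeness", "eigenvector",
               "avg_degree_connectivity", "clustering", "authority", "pagerank")
  summaries <- c("max", "min", "mean", "median", "iqr")
  out <- stats::setNames(numeric(length(metrics) * length(summaries)),
                         as.vector(outer(metrics, summaries, paste, sep = "_")))
  if (nrow(node_table) == 0L) {
    out[] <- fill
    return(c(out, missing = 1))
  }
  for (m in metrics) {
    x <- node_table[[m]]
    out[paste0(m, "_max")] <- max(x)
    out[paste0(m, "_min")] <- min(x)
    out[paste0(m, "_mean")] <- mean(x)
    out[paste0(m, "_median")] <- stats::median(x)
    out[paste0(m, "_iqr")] <- stats::IQR(x, type = 7)
  }
  c(out, missing = 0)
}

#' Per-encounter network feature rows
#'
#' For each encounter: metrics of the subgraph induced by its providers
#' within the provider-provider graph, and metrics of its standalone transfer
#' digraph, each aggregated by [aggregate_metrics()] and suffixed with the
#' graph-level scalars.
#'
#' @param encounters encounter table.
#' @param assignments assignment table.
#' @param transfers transfer table.
#' @param provider_graph optionally a prebuilt provider graph (e.g. holistic
#'   or training-only); default builds from all encounters.
#' @return numeric matrix, one row per encounter.
#' @export
network_features <- function(encounters, assignments, transfers,
                             provider_graph = NULL) {
  if (is.null(provider_graph)) provider_graph <- build_provider_graph(assignments)
  by_enc_p <- split(assignments$provider_id, assignments$encounter_id)
  has_tr <- unique(transfers$encounter_id)
  rows <- lapply(encounters$encounter_id, function(e) {
    provs <- intersect(unique(by_enc_p[[e]]), igraph::V(provider_graph)$name)
    pg <- igraph::induced_subgraph(provider_graph, provs)
    pm <- graph_metrics(pg)
    tm <- if (e %in% has_tr) graph_metrics(build_transfer_graph(transfers, e))
          else list(nodes = data.frame(), graph = c(density = 0, n_nodes = 0,
                                                    weighted_edges = 0))
    c(stats::setNames(c(aggregate_metrics(pm$nodes), pm$graph),
                      paste0("prov_", c(names(aggregate_metrics(pm$nodes)),
                                        names(pm$graph)))),
      stats::setNames(c(aggregate_metrics(tm$nodes), tm$graph),
                      paste0("tr_", c(names(aggregate_metrics(tm$nodes)),
                                      names(tm$graph)))))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- encounters$encounter_id
  m
}

## ---- tabular baselines -----------------------------------------------------

## Newton (IRLS) ridge-penalized logistic regression; intercept unpenalized.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 500L, tol = 1e-10) {
  D <- cbind(`(Intercept)` = 1, X)
  p <- ncol(D)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    mu <- expit(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(D, y - mu) - pen %*% beta
    Hm <- crossprod(D * wt, D) + pen
    step <- tryCatch(solve(Hm, grad), error = function(e)
      solve(Hm + diag(1e-8, p), grad))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Fit a tabular baseline model
#'
#' `lr`: Newton-type (IRLS) L2-penalized logistic regression, up to 500
#' iterations. `mlp`: a 3-layer ReLU network trained with Adam (learning
#' rate 1e-3, mini-batch 200, at most 200 iterations), early-stopped on
#' validation AUROC. `gbt`: gradient-boosted trees (xgboost) with L2
#' regularization 1 and L1 0, early-stopped on validation AUROC.
#'
#' @param features numeric matrix with encounter-id rownames (no missing
#'   values).
#' @param labels `medhg_labels` or named 0/1 vector.
#' @param splits a [split_indices()] object.
#' @param model_kind `"lr"`, `"mlp"` or `"gbt"`.
#' @param outcome label column when `labels` is a label table.
#' @param tuning optional named list of hyperparameters overriding the
#'   defaults (e.g. `list(lambda = 1)` for lr; `list(nrounds = 300,
#'   max_depth = 4)` for gbt; `list(hidden = c(32, 16))` for mlp).
#' @param seed integer seed.
#' @return list of class `medhg_baseline`: `model_kind`, `predict_fn`,
#'   `scores` (test-set predictions), `metrics`
#'   ([classification_metrics()] on the test split), `val_auroc`.
#' @export
fit_baseline <- function(features, labels, splits,
                         model_kind = c("lr", "mlp", "gbt"), outcome = "plos",
                         tuning = NULL, seed = 1L) {
  model_kind <- match.arg(model_kind)
  ids <- rownames(features)
  y <- align_labels(labels, ids, outcome)
  tr <- match(intersect(splits$train, ids), ids)
  va <- match(intersect(splits$validation, ids), ids)
  te <- match(intersect(splits$test, ids), ids)
  if (length(unique(y[tr])) < 2L) stopf("single-class training labels")
  X <- as.matrix(features)

  if (model_kind == "lr") {
    lambda <- tuning$lambda %||% 1e-4
    beta <- ridge_logistic(X[tr, , drop = FALSE], y[tr], lambda = lambda,
                           max_iter = tuning$max_iter %||% 500L)
    predf <- function(M) expit(drop(cbind(1, M) %*% beta))
    fitobj <- beta
  } else if (model_kind == "mlp") {
    fitobj <- mlp_fit(X[tr, , drop = FALSE], y[tr],
                      X_val = if (length(va)) X[va, , drop = FALSE] else NULL,
                      y_val = if (length(va)) y[va] else NULL,
                      hidden = tuning$hidden %||% c(64L, 32L),
                      lr = tuning$lr %||% 1e-3,
                      epochs = tuning$epochs %||% 200L,
                      batch_size = tuning$batch_size %||% 200L,
                      l2 = tuning$l2 %||% 1e-4, seed = seed)
    predf <- function(M) mlp_predict(fitobj, M)
  } else {
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    watch <- list(train = dtr)
    if (length(va))
      watch$validation <- xgboost::xgb.DMatrix(X[va, , drop = FALSE],
                                               label = y[va])
    fitobj <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eval_metric = "auc",
                    eta = tuning$eta %||% 0.1,
                    max_depth = tuning$max_depth %||% 6L,
                    subsample = tuning$subsample %||% 1,
                    colsample_bytree = tuning$colsample %||% 1,
                    lambda = 1, alpha = 0, nthread = 1L,
                    seed = as.integer(seed)),
      data = dtr, nrounds = tuning$nrounds %||% 200L, evals = watch,
      early_stopping_rounds = if (length(va)) 20L else NULL, verbose = 0)
    predf <- function(M) predict(fitobj, xgboost::xgb.DMatrix(M))
  }

  val_auroc <- if (length(va)) auroc(y[va], predf(X[va, , drop = FALSE])) else NA_real_
  scores <- if (length(te)) predf(X[te, , drop = FALSE]) else numeric(0)
  metrics <- if (length(te)) classification_metrics(y[te], scores) else NULL
  out <- list(model_kind = model_kind, fit = fitobj, predict_fn = predf,
              scores = stats::setNames(scores, ids[te]), y_test = y[te],
              metrics = metrics, val_auroc = val_auroc, seed = seed)
  class(out) <- "medhg_baseline"
  out
}

#' @export
print.medhg_baseline <- function(x, ...) {
  cat(sprintf("%s baseline; validation AUROC %s\n", x$model_kind,
              ifelse(is.na(x$val_auroc), "-", sprintf("%.4f", x$val_auroc))))
  if (!is.null(x$metrics))
    cat(sprintf("  test AUROC %.4f, AUPRC %.4f, F1 %.4f\n",
                x$metrics$auroc, x$metrics$auprc, x$metrics$f1))
  invisible(x)
}

#' Random-search tuning for a tabular baseline
#'
#' Seeded random search over a gradient-boosting / lr / mlp search space,
#' scored by validation AUROC.
#'
#' @inheritParams fit_baseline
#' @param n_trials number of configurations.
#' @return list with `best` tuning list, `best_score`, `trials` log.
#' @export
tune_baseline <- function(features, labels, splits, model_kind = "gbt",
                          outcome = "plos", n_trials = 10L, seed = 1L) {
  draw <- function() switch(model_kind,
    gbt = list(nrounds = sample(50:600, 1), eta = stats::runif(1, 0.01, 0.3),
               max_depth = sample(3:15, 1), subsample = stats::runif(1, 0.6, 1),
               colsample = stats::runif(1, 0.5, 1)),
    lr = list(lambda = exp(stats::runif(1, log(1 / 50), log(1e6)))^-1),
    mlp = list(l2 = exp(stats::runif(1, log(1e-4), log(0.99)))))
  trials <- list()
  with_seed(child_seed(seed, "tune_baseline"), {
    for (i in seq_len(n_trials)) {
      cfg <- draw()
      fit <- fit_baseline(features, labels, splits, model_kind,
                          outcome = outcome, tuning = cfg, seed = seed)
      trials[[i]] <- list(cfg = cfg, score = fit$val_auroc)
    }
  })
  scores <- vapply(trials, function(t) t$score, 0)
  list(best = trials[[which.max(scores)]]$cfg, best_score = max(scores),
       trials = trials)
}
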