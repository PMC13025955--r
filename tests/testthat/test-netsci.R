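test_that("provider graph counts shared encounters as edge weights", {
  asg <- data.frame(
    encounter_id = c("E1", "E1", "E1", "E2", "E2"),
    provider_id = c("a", "b", "c", "a", "b"),
    role = "surgical_team")
  g <- build_provider_graph(asg)
  expect_equal(igraph::vcount(g), 3L)
  w <- igraph::E(g)$weight
  expect_true(all(w == round(w) & w > 0))
  get_w <- function(u, v) igraph::E(g, P = c(u, v))$weight
  expect_equal(get_w("a", "b"), 2)
  expect_equal(get_w("a", "c"), 1)
  expect_equal(get_w("b", "c"), 1)
  ## no self-loops, symmetric by construction
  expect_false(any(igraph::which_loop(g)))
})

test_that("total provider edge weight matches the combinatorial oracle", {
  tabs <- small_cohort(n_patients = 50, seed = 29)
  g <- build_provider_graph(tabs$assignments)
  sizes <- vapply(split(tabs$assignments$provider_id,
                        tabs$assignments$encounter_id),
                  function(p) length(unique(p)), 1L)
  expect_equal(sum(igraph::E(g)$weight), sum(choose(sizes, 2)))
})

test_that("transfer digraphs encode consecutive stays without self-loops", {
  tr <- data.frame(encounter_id = "E1",
                   unit_type = c("acute", "intensive", "acute"),
                   sequence_index = 0:2, duration = 1)
  g <- build_transfer_graph(tr, "E1")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::E(g, P = c("acute", "intensive"))$weight, 1)
  expect_equal(igraph::E(g, P = c("intensive", "acute"))$weight, 1)
  ## single stay: one node, no edges
  tr1 <- data.frame(encounter_id = "E2", unit_type = "acute",
                    sequence_index = 0L, duration = 1)
  g1 <- build_transfer_graph(tr1, "E2")
  expect_equal(igraph::vcount(g1), 1L)
  expect_equal(igraph::ecount(g1), 0L)
  ## repeated stays in the same unit add no self-transition edges
  tr2 <- data.frame(encounter_id = "E3", unit_type = c("acute", "acute"),
                    sequence_index = 0:1, duration = 1)
  g2 <- build_transfer_graph(tr2, "E3")
  expect_equal(igraph::ecount(g2), 0L)
  tr3 <- data.frame(encounter_id = "E4", unit_type = c("acute", "intensive"),
                    sequence_index = c(0L, 2L), duration = 1)
  expect_error(build_transfer_graph(tr3, "E4"), "non-contiguous")
})

test_that("graph metrics match closed forms on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::E(tri)$weight <- 1
  igraph::V(tri)$name <- c("a", "b", "c")
  m <- graph_metrics(tri)
  expect_equal(m$nodes$clustering, rep(1, 3))
  expect_equal(unname(m$graph["density"]), 1)
  path <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1),
    directed = FALSE)
  mp <- graph_metrics(path)
  expect_equal(mp$nodes$betweenness[mp$nodes$node == "b"], 1.0)
  ## empty graph: zero scalars, empty node table
  me <- graph_metrics(igraph::make_empty_graph(directed = FALSE))
  expect_equal(nrow(me$nodes), 0L)
  expect_equal(unname(me$graph), c(0, 0, 0))
})

test_that("PageRank matches a power-iteration oracle and sums to one", {
  set.seed(14)
  A <- matrix(rbinom(36, 1, 0.5), 6); diag(A) <- 0
  A <- pmax(A, t(A))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::E(g)$weight <- 1
  pr <- graph_metrics(g)$nodes$pagerank
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  d <- 0.85; n <- 6
  P <- A / pmax(rowSums(A), 1)
  dangling <- rowSums(A) == 0
  v <- rep(1 / n, n)
  for (i in 1:2000)
    v <- (1 - d) / n + d * (drop(crossprod(P, v)) + sum(v[dangling]) / n)
  expect_lt(max(abs(pr - v)), 1e-8)
})

test_that("authority scores have unit Euclidean norm", {
  tabs <- small_cohort(n_patients = 30, seed = 33)
  g <- build_provider_graph(tabs$assignments)
  m <- graph_metrics(g)
  expect_equal(sqrt(sum(m$nodes$authority^2)), 1, tolerance = 1e-8)
})

test_that("metric aggregation follows order-statistic conventions", {
  tbl <- data.frame(degree = c(1, 2, 3, 4), betweenness = 0, closeness = 0,
                    eigenvector = 0, avg_degree_connectivity = 0,
                    clustering = 0, authority = 0, pagerank = 0)
  agg <- aggregate_metrics(tbl)
  expect_equal(unname(agg[c("degree_max", "degree_min", "degree_mean",
                            "degree_median", "degree_iqr")]),
               c(4, 1, 2.5, 2.5, 1.5))
  one <- aggregate_metrics(tbl[2, , drop = FALSE])
  expect_equal(unname(one[c("degree_max", "degree_min", "degree_mean",
                            "degree_median", "degree_iqr")]),
               c(2, 2, 2, 2, 0))
  expect_equal(unname(one["missing"]), 0)
  empty <- aggregate_metrics(tbl[0, , drop = FALSE])
  expect_true(all(empty[setdiff(names(empty), "missing")] == 0))
  expect_equal(unname(empty["missing"]), 1)
})

test_that("network feature rows are finite with sane ranges", {
  tabs <- small_cohort(n_patients = 25, seed = 35)
  nf <- network_features(tabs$encounters, tabs$assignments, tabs$transfers)
  expect_equal(nrow(nf), nrow(tabs$encounters))
  expect_true(all(is.finite(nf)))
  expect_true(all(nf[, "prov_density"] >= 0 & nf[, "prov_density"] <= 1))
  expect_true(all(nf[, grepl("_iqr$", colnames(nf))] >= 0))
})

test_that("ridge logistic matches glm at negligible penalty", {
  set.seed(16)
  n <- 400
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, expit(0.5 + X %*% c(1, -0.7)))
  ours <- medhgps:::ridge_logistic(X, y, lambda = 1e-10)
  ref <- unname(stats::coef(stats::glm(y ~ X, family = stats::binomial())))
  expect_equal(unname(ours), ref, tolerance = 1e-6)
})

test_that("lr baseline separates a separable toy perfectly", {
  set.seed(18)
  n <- 60
  X <- cbind(a = c(rnorm(n / 2, -3, 0.5), rnorm(n / 2, 3, 0.5)), b = rnorm(n))
  rownames(X) <- sprintf("E%02d", 1:n)
  y <- rep(c(0, 1), each = n / 2)
  labs <- data.frame(encounter_id = rownames(X), plos = y, mort30 = 0,
                     mort90 = 0)
  sp <- list(train = rownames(X)[c(1:20, 31:50)],
             validation = rownames(X)[c(21:25, 51:55)],
             test = rownames(X)[c(26:30, 56:60)])
  fit <- fit_baseline(X, labs, sp, "lr", seed = 1)
  expect_equal(mean((fit$scores > 0.5) == (fit$y_test == 1)), 1.0)
  expect_error(fit_baseline(X, data.frame(encounter_id = rownames(X),
                                          plos = rep(1, n), mort30 = 0,
                                          mort90 = 0), sp, "lr"),
               "single-class")
})

test_that("null features give chance-level test AUROC", {
  set.seed(20)
  n <- 2000
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("E%04d", 1:n), paste0("f", 1:4)))
  y <- sample(rep(c(0, 1), each = n / 2))
  labs <- data.frame(encounter_id = rownames(X), plos = y, mort30 = 0,
                     mort90 = 0)
  ids <- rownames(X)
  sp <- list(train = ids[1:1600], validation = ids[1601:1800],
             test = ids[1801:2000])
  fit <- fit_baseline(X, labs, sp, "lr", seed = 2)
  expect_lt(abs(fit$metrics$auroc - 0.5), 0.08)
})

test_that("lr recovers planted coefficients within thirty percent", {
  set.seed(22)
  n <- 20000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(2, -1)
  y <- rbinom(n, 1, expit(drop(X %*% beta)))
  est <- medhgps:::ridge_logistic(X, y, lambda = 1e-6)[-1]
  expect_true(all(sign(est) == sign(beta)))
  expect_true(all(abs(est - beta) / abs(beta) < 0.30))
})

test_that("mlp and gbt baselines train, early-stop and reproduce with a seed", {
  set.seed(24)
  n <- 500
  X <- cbind(a = rnorm(n), b = rnorm(n))
  rownames(X) <- sprintf("E%03d", 1:n)
  y <- rbinom(n, 1, expit(2 * X[, "a"]))
  labs <- data.frame(encounter_id = rownames(X), plos = y, mort30 = 0,
                     mort90 = 0)
  ids <- rownames(X)
  sp <- list(train = ids[1:400], validation = ids[401:450],
             test = ids[451:500])
  m1 <- fit_baseline(X, labs, sp, "mlp", seed = 5,
                     tuning = list(epochs = 30))
  m2 <- fit_baseline(X, labs, sp, "mlp", seed = 5,
                     tuning = list(epochs = 30))
  expect_gt(m1$metrics$auroc, 0.8)
  expect_identical(m1$scores, m2$scores)
  g1 <- fit_baseline(X, labs, sp, "gbt", seed = 5,
                     tuning = list(nrounds = 50))
  expect_gt(g1$metrics$auroc, 0.8)
})

test_that("the graph model out-recalls boosted trees on connectivity-driven risk", {
  res <- lapply(1:3, function(s) connectivity_benchmark(seed = s,
                                                        n_patients = 1200))
  wins <- vapply(res, function(r) r$recall_graph > r$recall_gbt, TRUE)
  expect_gte(sum(wins), 2)
})

test_that("mlp gradients agree with finite differences", {
  set.seed(26)
  X <- matrix(rnorm(12), 4, 3)
  y <- c(1, 0, 1, 0)
  params <- medhgps:::mlp_init(3, c(4L, 3L), seed = 2)
  ## move biases off zero so no pre-activation sits on the ReLU kink
  params <- lapply(params, function(l) {
    l$b <- rnorm(length(l$b), 0, 0.3); l
  })
  fwd <- medhgps:::mlp_forward(params, X)
  grads <- medhgps:::mlp_backward(params, fwd, y)
  lossfn <- function(pp) {
    p <- expit(medhgps:::mlp_forward(pp, X)$logits)
    bce_loss(y, p)
  }
  eps <- 1e-6
  for (li in seq_along(params)) for (fld in c("W", "b")) {
    leaf <- params[[li]][[fld]]
    for (i in sample(length(leaf), min(2, length(leaf)))) {
      pp <- params; pp[[li]][[fld]][i] <- leaf[i] + eps; up <- lossfn(pp)
      pp[[li]][[fld]][i] <- leaf[i] - eps; dn <- lossfn(pp)
      expect_equal(grads[[li]][[fld]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
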