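## Hand-buildable mean-attention object: 3 layers, ENC attending over self
## and two care-unit relations, each unit type attending over self and ENC.
uniform_attention <- function(coefs_enc = c(self = 1/3, C_acute = 1/3,
                                            C_intensive = 1/3),
                              coefs_unit = c(self = 0.5, ENC = 0.5)) {
  layer <- list(ENC = coefs_enc,
                C_acute = coefs_unit, C_intensive = coefs_unit)
  structure(list(layer, layer, layer), class = "mean_attention")
}

test_that("mean attention equals the arithmetic mean of per-node records", {
  rm <- random_model(23)
  fit <- list(params = rm$params, schema_types = names(rm$graph$schema))
  class(fit) <- "iehgcn"
  att <- mean_attention(fit, rm$graph)
  fwd <- medhgps:::iehgcn_forward(rm$params, rm$gt)
  for (l in 1:3) for (tp in names(att[[l]])) {
    expect_equal(att[[l]][[tp]], colMeans(fwd$attention[[l]][[tp]]),
                 tolerance = 1e-12)
    expect_equal(sum(att[[l]][[tp]]), 1, tolerance = 1e-6)
  }
  ## single-relation targets have mean coefficient exactly 1
  one_rel <- att[[1]][vapply(att[[1]], length, 1L) == 1]
  for (v in one_rel) expect_equal(unname(v), 1)
})

test_that("uniform coefficients give every full-length sequence (1/3)^3", {
  att <- uniform_attention()
  full <- metapath_importance(att, all_sequences = TRUE)
  ## ENC has 3 relations at each layer; sequences through units branch too
  expect_equal(sum(full$importance), 1, tolerance = 1e-9)
  enc_only <- full[grepl("^ENC<-", full$path), ]
  first_step <- metapath_importance(att)
  expect_equal(first_step$importance[first_step$path == "ENC-C_acute-ENC-C_acute"],
               (1/3) * (1/2) * (1/3), tolerance = 1e-12)
})

test_that("canonical meta-paths follow the outward-in padding convention", {
  att <- uniform_attention(coefs_enc = c(self = 0.2, C_acute = 0.5,
                                         C_intensive = 0.3),
                           coefs_unit = c(self = 0.6, ENC = 0.4))
  mp <- metapath_importance(att)
  ## length-1 path: outer coefficient x terminal self padding on 2 layers
  expect_equal(mp$importance[mp$path == "ENC-C_acute"], 0.5 * 0.6 * 0.6,
               tolerance = 1e-12)
  ## length-2 path: two outer steps, ENC self padding on layer 1
  expect_equal(mp$importance[mp$path == "ENC-C_acute-ENC"], 0.5 * 0.4 * 0.2,
               tolerance = 1e-12)
  ## pure self path
  expect_equal(mp$importance[mp$path == "ENC"], 0.2^3, tolerance = 1e-12)
  expect_true(all(diff(mp$importance) <= 1e-12))
})

test_that("top meta-path matches an exhaustive enumeration oracle", {
  set.seed(41)
  rand_simplex <- function(nms) {
    x <- rexp(length(nms)); stats::setNames(x / sum(x), nms)
  }
  att <- structure(lapply(1:3, function(l)
    list(ENC = rand_simplex(c("self", "C_acute", "C_intensive")),
         C_acute = rand_simplex(c("self", "ENC")),
         C_intensive = rand_simplex(c("self", "ENC")))),
    class = "mean_attention")
  mp <- metapath_importance(att)
  ## oracle: enumerate all chains up to length 3 by brute force
  oracle <- list()
  add <- function(chain) {
    k <- length(chain) - 1
    imp <- 1
    for (i in seq_len(k)) imp <- imp * att[[4 - i]][[chain[i]]][[chain[i + 1]]]
    for (l in seq_len(3 - k)) imp <- imp * att[[l]][[chain[k + 1]]][["self"]]
    oracle[[paste(chain, collapse = "-")]] <<- imp
  }
  add("ENC")
  for (a in c("C_acute", "C_intensive")) {
    add(c("ENC", a))
    add(c("ENC", a, "ENC"))
    for (b in c("C_acute", "C_intensive")) add(c("ENC", a, "ENC", b))
  }
  expect_setequal(mp$path, names(oracle))
  best <- names(oracle)[which.max(unlist(oracle))]
  expect_equal(mp$path[1], best)
  expect_equal(mp$importance, unname(unlist(oracle)[mp$path]),
               tolerance = 1e-12)
})

test_that("broken relation chains raise errors", {
  att <- uniform_attention()
  expect_error(metapath_importance(att, paths = list(c("ENC", "P_nurse"))),
               "chain broken")
  expect_error(metapath_importance(att, paths = list(c("C_acute", "ENC"))),
               "start at ENC")
  expect_error(metapath_importance(att, max_length = 4), "depth")
})

test_that("Shapley attributions are exact for additive models", {
  w <- c(2, -1, 0.5)
  f <- function(M) drop(M %*% w)
  x <- c(1, 2, 3); b <- c(0, 0, 1)
  rep <- shapley_attribution(f, x, b, n_permutations = 10, seed = 1)
  expect_equal(unname(rep$attributions), w * (x - b), tolerance = 1e-12)
  ## instance equal to background -> all zero
  rep0 <- shapley_attribution(f, b, b, n_permutations = 5, seed = 1)
  expect_equal(unname(rep0$attributions), rep(0, 3))
  expect_error(shapley_attribution(f, x, matrix(numeric(0), 0, 3)), "nonempty")
})

test_that("sampled Shapley matches exact enumeration on a nonlinear toy", {
  set.seed(12)
  p <- 6
  W <- matrix(rnorm(p * p, 0, 0.3), p)
  f <- function(M) apply(M, 1, function(r) sum(r * (1:p)) + drop(r %*% W %*% r))
  x <- rnorm(p); b <- rnorm(p)
  ## exact Shapley by full subset enumeration against the single background
  exact <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  val <- function(mask) { z <- b; z[mask] <- x[mask]; f(matrix(z, 1)) }
  vals <- apply(subsets, 1, function(m) val(as.logical(m)))
  for (i in seq_len(p)) {
    without <- !subsets[[i]]
    for (s in which(without)) {
      mask <- as.logical(subsets[s, ])
      k <- sum(mask)
      pair <- s + 2^(i - 1)
      weight <- factorial(k) * factorial(p - k - 1) / factorial(p)
      exact[i] <- exact[i] + weight * (vals[pair] - vals[s])
    }
  }
  rep <- shapley_attribution(f, x, b, n_permutations = 4000, seed = 3)
  expect_lt(max(abs(rep$attributions - exact)), 0.01)
  ## efficiency: attributions sum to f(x) - f(b)
  expect_equal(sum(rep$attributions), f(matrix(x, 1)) - f(matrix(b, 1)),
               tolerance = 1e-9)
})

test_that("Shapley efficiency holds within Monte-Carlo error for random backgrounds", {
  set.seed(5)
  f <- function(M) apply(M, 1, function(r) sum(r^2))
  x <- rnorm(4)
  B <- matrix(rnorm(40), 10, 4)
  rep <- shapley_attribution(f, x, B, n_permutations = 500, seed = 7)
  fb <- f(B)
  mc_se <- stats::sd(fb) / sqrt(rep$n)
  expect_lt(abs(sum(rep$attributions) - (rep$value - mean(fb))),
            3 * mc_se + abs(mean(fb) - rep$baseline) + 1e-9)
  ## per-permutation efficiency makes sum(phi) = value - realized baseline
  expect_equal(sum(rep$attributions), rep$value - rep$baseline,
               tolerance = 1e-9)
})

test_that("the local surrogate recovers linear models exactly", {
  w <- c(1.5, -2, 0.25)
  f <- function(M) drop(M %*% w) + 3
  x <- c(0.5, 1, -1)
  rep <- lime_explain(f, x, n_samples = 200, seed = 2)
  expect_equal(unname(rep$attributions), w, tolerance = 1e-6)
  fc <- function(M) rep(1.7, nrow(M))
  rep0 <- lime_explain(fc, x, n_samples = 100, seed = 2)
  expect_equal(unname(rep0$attributions), rep(0, 3), tolerance = 1e-8)
  expect_error(lime_explain(f, x, n_samples = 3), "number of features")
})

test_that("surrogate coefficients approach the gradient for smooth models", {
  f <- function(M) apply(M, 1, function(r) r[1]^2 + 2 * r[1] * r[2] - r[2]^2)
  x <- c(1, -0.5)
  grad <- c(2 * x[1] + 2 * x[2], 2 * x[1] - 2 * x[2])
  rep <- lime_explain(f, x, n_samples = 4000, kernel_width = 0.5,
                      perturb_sd = 0.05, seed = 8)
  expect_equal(unname(rep$attributions), grad, tolerance = 0.05)
})

test_that("encounter predict_fn perturbs one row with the graph held fixed", {
  sg <- separable_graph()
  labs <- data.frame(encounter_id = names(sg$y), plos = unname(sg$y),
                     mort30 = 0L, mort90 = 0L)
  fit <- iehgcn(sg$graph, labs, splits = NULL, outcome = "plos",
                hidden_dim = 4, attn_dim = 3, epochs = 60, seed = 2)
  fn <- encounter_predict_fn(fit, sg$graph, "E01")
  base <- predict(fit, sg$graph)[["E01"]]
  same <- fn(matrix(sg$graph$enc_features["E01", ], 1))
  expect_equal(unname(same), unname(base), tolerance = 1e-10)
  ## the informative feature moves the prediction
  hi <- fn(matrix(c(2, 0), 1)); lo <- fn(matrix(c(-2, 0), 1))
  expect_gt(hi, lo)
})
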