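## Unit tests of the heterogeneous convolution building blocks and training.

make_single_rel <- function(n = 4, d = 3) {
  ## one target with itself + one neighbor relation, identity scaffolding
  H <- list(ENC = diag(n), NB = diag(n))
  lp <- list(W_self = diag(n)[, 1:d], W = list(NB = diag(n)[, 1:d]),
             Wk = list(self = matrix(0, d, 2), NB = matrix(0, d, 2)),
             Wq = matrix(0, d, 2), wa = rep(0, 4))
  list(H = H, lp = lp)
}

test_that("project applies the row-normalized aggregation and projections", {
  ## identity adjacency and weights -> Z equals H
  s <- make_single_rel()
  ahat <- list(NB = diag(4))
  lp <- s$lp; lp$W_self <- diag(4); lp$W$NB <- diag(4)
  Z <- project(s$H, lp, ahat, "ENC")
  expect_equal(Z$NB, s$H$NB)
  expect_equal(Z$self, s$H$ENC)
  ## zero adjacency row -> zero message row
  ahat0 <- list(NB = rbind(0, diag(4)[2:4, ]))
  Z0 <- project(s$H, lp, ahat0, "ENC")
  expect_equal(Z0$NB[1, ], rep(0, 4))
  ## dense matrix-product oracle on a random fixture
  set.seed(8)
  H <- list(A = matrix(rnorm(6), 2), B = matrix(rnorm(9), 3))
  W <- list(W_self = matrix(rnorm(6), 3, 2), W = list(B = matrix(rnorm(6), 3, 2)),
            Wk = NULL, Wq = NULL, wa = NULL)
  Ahat <- matrix(c(0.5, 0, 0.5, 1, 0, 0), 2, 3)
  Z2 <- project(list(A = H$A, B = H$B), W, list(B = Ahat), "A")
  expect_equal(Z2$B, Ahat %*% H$B %*% W$W$B, tolerance = 1e-12)
  expect_equal(Z2$self, H$A %*% W$W_self, tolerance = 1e-12)
  ## shape mismatch names the relation
  Wbad <- W; Wbad$W$B <- matrix(0, 5, 2)
  expect_error(project(list(A = H$A, B = H$B), Wbad, list(B = Ahat), "A"),
               "B-A")
})

test_that("type attention is a per-node softmax over the relation set", {
  ## singleton relation set -> coefficient 1
  s <- make_single_rel()
  Z <- list(self = matrix(rnorm(12), 4, 3))
  a <- type_attention(Z, s$lp)
  expect_equal(unname(a[, "self"]), rep(1, 4))
  ## identical messages with shared key weights -> symmetric 0.5
  set.seed(2)
  Zs <- matrix(rnorm(12), 4, 3)
  Wk <- matrix(rnorm(6), 3, 2)
  lp <- list(Wk = list(self = Wk, NB = Wk), Wq = matrix(rnorm(6), 3, 2),
             wa = rnorm(4))
  a2 <- type_attention(list(self = Zs, NB = Zs), lp)
  expect_equal(unname(a2), matrix(0.5, 4, 2), tolerance = 1e-12)
  ## direct scalar-arithmetic oracle
  Zx <- list(self = matrix(c(1, 2), 1), NB = matrix(c(-1, 0.5), 1))
  lpx <- list(Wk = list(self = matrix(c(0.3, -0.2), 2, 1),
                        NB = matrix(c(0.1, 0.4), 2, 1)),
              Wq = matrix(c(0.2, 0.2), 2, 1), wa = c(0.7, -0.3))
  q <- drop(Zx$self %*% lpx$Wq) * (-0.3)
  e_self <- drop(Zx$self %*% lpx$Wk$self) * 0.7 + q
  e_nb <- drop(Zx$NB %*% lpx$Wk$NB) * 0.7 + q
  elu1 <- function(x) ifelse(x > 0, x, exp(x) - 1)
  ex <- exp(c(elu1(e_self), elu1(e_nb)))
  a3 <- type_attention(Zx, lpx)
  expect_equal(unname(a3[1, ]), ex / sum(ex), tolerance = 1e-12)
  expect_error(type_attention(list(), lpx), "no relations")
})

test_that("layer_forward equals the stepwise project/attention/ELU oracle", {
  tg <- toy_graph()
  gt <- medhgps:::graph_tensors(tg$graph)
  params <- init_iehgcn_params(gt, hidden_dim = 4, attn_dim = 3, seed = 5)
  H0 <- medhgps:::input_reps(params, gt)
  out <- layer_forward(H0, params$layers[[1]], gt)
  for (tp in gt$types) {
    Z <- project(H0, params$layers[[1]][[tp]], gt$ahat[[tp]], tp)
    a <- type_attention(Z, params$layers[[1]][[tp]])
    S <- Reduce(`+`, lapply(names(Z), function(r) a[, r] * Z[[r]]))
    expect_equal(out$H[[tp]], medhgps:::elu(S), tolerance = 1e-8)
    expect_equal(rowSums(out$attention[[tp]]), rep(1, nrow(a)),
                 tolerance = 1e-9)
  }
  ## with nonnegative pre-activations the ELU is the identity
  Spos <- abs(matrix(rnorm(4), 2, 2)) ; expect_equal(medhgps:::elu(Spos), Spos)
})

test_that("layer_forward with one relation reduces to mean-aggregation GCN", {
  ## dense oracle: row-normalized adjacency times features times weights
  set.seed(4)
  n <- 6
  A <- matrix(rbinom(n * n, 1, 0.5), n); diag(A) <- 0
  H <- matrix(rnorm(n * 3), n, 3)
  W <- matrix(rnorm(6), 3, 2)
  Ahat <- as.matrix(row_normalize(A))
  lp <- list(W_self = matrix(0, 3, 2), W = list(NB = W),
             Wk = list(self = matrix(0, 2, 2), NB = matrix(0, 2, 2)),
             Wq = matrix(0, 2, 2), wa = rep(0, 4))
  Z <- project(list(T1 = H, NB = H), lp, list(NB = Ahat), "T1")
  ## with zero attention parameters the coefficients are uniform (0.5/0.5);
  ## forcing all mass on the neighbor relation recovers the GCN layer
  oracle <- medhgps:::elu(Ahat %*% H %*% W)
  expect_equal(medhgps:::elu(1 * Z$NB + 0 * Z$self), oracle, tolerance = 1e-10)
})

test_that("softmax head behaves like a two-class sigmoid", {
  expect_equal(medhgps:::softmax_rows(matrix(c(0, 0), 1))[1, 2], 0.5)
  expect_equal(medhgps:::softmax_rows(matrix(c(0, 10), 1))[1, 2], expit(10),
               tolerance = 1e-12)
  set.seed(3)
  P <- medhgps:::softmax_rows(matrix(rnorm(20), 5))
  expect_true(all(P > 0 & P < 1))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-12)
})

test_that("bce_loss matches the direct summation oracle", {
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(6)
  y <- rbinom(10, 1, 0.4); p <- runif(10, 0.05, 0.95)
  expect_equal(bce_loss(y, p),
               -sum(y * log(p) + (1 - y) * log(1 - p)) / 10, tolerance = 1e-12)
  expect_error(bce_loss(c(1, 0), 0.5), "same length")
})

test_that("hand-derived gradients agree with finite differences", {
  tg <- toy_graph()
  gt <- medhgps:::graph_tensors(tg$graph)
  y <- c(1, 0, 1, 0, 1)
  for (bn in c(FALSE, TRUE)) {
    params <- init_iehgcn_params(gt, hidden_dim = 4, attn_dim = 3, seed = 3)
    lossfn <- function(pp) {
      fwd <- medhgps:::iehgcn_forward(pp, gt, batch_norm = bn, training = TRUE)
      bce_loss(y, medhgps:::softmax_rows(fwd$logits)[, 2])
    }
    fwd <- medhgps:::iehgcn_forward(params, gt, batch_norm = bn, training = TRUE)
    pr <- medhgps:::softmax_rows(fwd$logits)
    dlog <- (pr - cbind(1 - y, y)) / 5
    grads <- medhgps:::iehgcn_backward(params, gt, fwd, dlog, batch_norm = bn)
    eps <- 1e-6
    set_leaf <- function(obj, path, i, val) {
      if (length(path) == 0L) { obj[i] <- val; return(obj) }
      obj[[path[[1]]]] <- set_leaf(obj[[path[[1]]]], path[-1], i, val)
      obj
    }
    paths <- list(list("layers", 1L, "ENC", "W_self"),
                  list("layers", 1L, "P_tech", "W", "ENC"),
                  list("layers", 2L, "ENC", "W", "C_acute"),
                  list("layers", 3L, "ENC", "Wk", "P_surgical"),
                  list("layers", 3L, "ENC", "Wq"),
                  list("layers", 2L, "ENC", "wa"),
                  list("embed", "P_tech"))
    set.seed(1)
    for (pth in paths) {
      leaf <- Reduce(`[[`, pth, params)
      gleaf <- Reduce(`[[`, pth, grads)
      for (i in sample(length(leaf), 3)) {
        num <- (lossfn(set_leaf(params, pth, i, leaf[i] + eps)) -
                lossfn(set_leaf(params, pth, i, leaf[i] - eps))) / (2 * eps)
        expect_equal(gleaf[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training fits a separable toy to perfect accuracy", {
  sg <- separable_graph()
  labs <- data.frame(encounter_id = names(sg$y), plos = unname(sg$y),
                     mort30 = 0L, mort90 = 0L)
  fit <- iehgcn(sg$graph, labs, splits = NULL, outcome = "plos",
                hidden_dim = 4, attn_dim = 3, epochs = 200, lr = 1e-2,
                seed = 2)
  acc <- mean(predict(fit, sg$graph, type = "class") == sg$y)
  expect_equal(acc, 1.0)
})

test_that("loss is non-increasing over the first epochs on the separable toy", {
  sg <- separable_graph()
  labs <- data.frame(encounter_id = names(sg$y), plos = unname(sg$y),
                     mort30 = 0L, mort90 = 0L)
  fit <- iehgcn(sg$graph, labs, splits = NULL, outcome = "plos",
                hidden_dim = 4, attn_dim = 3, epochs = 5, lr = 1e-2, seed = 2)
  d <- diff(fit$report$history$loss)
  expect_true(all(d <= 1e-6))
})

test_that("zero learning rate leaves parameters unchanged", {
  sg <- separable_graph()
  labs <- data.frame(encounter_id = names(sg$y), plos = unname(sg$y),
                     mort30 = 0L, mort90 = 0L)
  fit0 <- iehgcn(sg$graph, labs, splits = NULL, outcome = "plos",
                 hidden_dim = 4, attn_dim = 3, epochs = 3, lr = 0, seed = 9)
  init <- init_iehgcn_params(medhgps:::graph_tensors(sg$graph), hidden_dim = 4,
                             attn_dim = 3,
                             seed = medhgps:::child_seed(9, "init"))
  expect_equal(fit0$params$layers, init$layers, tolerance = 1e-14)
  expect_equal(fit0$params$embed, init$embed, tolerance = 1e-14)
})

test_that("same seed reproduces the training trajectory bit-for-bit", {
  tg <- toy_graph()
  y <- c(1, 0, 1, 0, 1)
  labs <- data.frame(encounter_id = paste0("E", 1:5), plos = y,
                     mort30 = 0L, mort90 = 0L)
  sp <- list(train = paste0("E", 1:3), validation = c("E4", "E5"),
             test = character(0))
  f1 <- iehgcn(tg$graph, labs, sp, "plos", hidden_dim = 3, attn_dim = 2,
               epochs = 8, dropout = 0.2, seed = 31)
  f2 <- iehgcn(tg$graph, labs, sp, "plos", hidden_dim = 3, attn_dim = 2,
               epochs = 8, dropout = 0.2, seed = 31)
  expect_identical(f1$report$history, f2$report$history)
  expect_identical(f1$params, f2$params)
  expect_error(iehgcn(tg$graph, labs,
                      list(train = character(0), validation = "E5"), "plos"),
               "empty training split")
})

test_that("attention coefficients normalize on random graphs and models", {
  for (seed in 1:5) {
    rm <- random_model(seed)
    fwd <- medhgps:::iehgcn_forward(rm$params, rm$gt)
    for (l in 1:3) for (tp in names(fwd$attention[[l]]))
      expect_equal(rowSums(fwd$attention[[l]][[tp]]),
                   rep(1, nrow(fwd$attention[[l]][[tp]])), tolerance = 1e-6)
  }
})

test_that("hyperparameter search is reproducible and respects the space", {
  sg <- separable_graph()
  labs <- data.frame(encounter_id = names(sg$y), plos = unname(sg$y),
                     mort30 = 0L, mort90 = 0L)
  sp <- list(train = names(sg$y)[1:14], validation = names(sg$y)[15:20],
             test = character(0))
  space <- list(lr = list(type = "loguniform", low = 1e-3, high = 1e-1),
                hidden_dim = list(type = "choice", values = c(4L)),
                attn_dim = list(type = "choice", values = c(3L)))
  one <- tune_iehgcn(sg$graph, labs, sp, "plos", space, n_trials = 1,
                     seed = 4, epochs = 5)
  expect_equal(nrow(one$trials), 1L)
  expect_equal(one$best$hidden_dim, 4L)
  r1 <- tune_iehgcn(sg$graph, labs, sp, "plos", space, n_trials = 4,
                    strategy = "tpe", seed = 4, n_startup = 2, epochs = 5)
  r2 <- tune_iehgcn(sg$graph, labs, sp, "plos", space, n_trials = 4,
                    strategy = "tpe", seed = 4, n_startup = 2, epochs = 5)
  expect_identical(r1$trials, r2$trials)
  expect_error(tune_iehgcn(sg$graph, labs, sp, n_trials = 0), ">= 1")
})
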