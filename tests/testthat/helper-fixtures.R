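## Shared fixtures: everything is generated in code at test time.

## A small but fully populated cohort for integration-style tests.
small_cohort <- function(n_patients = 200, seed = 42, effects = NULL,
                         missingness = numeric(0)) {
  ew <- list(plos = effects %||% c(), mort30 = c(), mort90 = c())
  generate_cohort(synth_config(n_patients = n_patients, seed = seed,
                               effect_weights = ew,
                               missingness_rates = missingness))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Hand-built 5-encounter heterogeneous graph with known structure.
toy_graph <- function(features = TRUE, seed = 7) {
  enc <- data.frame(encounter_id = paste0("E", 1:5),
                    patient_id = paste0("P", 1:5))
  asg <- data.frame(
    encounter_id = c("E1", "E1", "E2", "E3", "E4", "E5", "E5"),
    provider_id = c("s1", "t1", "s1", "s2", "t1", "s2", "t2"),
    role = c("surgical_team", "technician", "surgical_team", "surgical_team",
             "technician", "surgical_team", "technician"))
  tr <- data.frame(encounter_id = c("E1", "E1", "E2", "E4"),
                   unit_type = c("acute", "intensive", "acute", "intermediate"),
                   sequence_index = c(0, 1, 0, 0), duration = c(5, 10, 3, 2))
  X <- NULL
  if (features) {
    set.seed(seed)
    X <- matrix(rnorm(15), 5, 3,
                dimnames = list(enc$encounter_id, paste0("f", 1:3)))
  }
  list(enc = enc, asg = asg, tr = tr, X = X,
       graph = build_heterograph(enc, asg, tr, X))
}

## A linearly separable toy graph: one informative encounter feature.
separable_graph <- function(n = 20, seed = 3) {
  set.seed(seed)
  enc <- data.frame(encounter_id = sprintf("E%02d", 1:n),
                    patient_id = sprintf("P%02d", 1:n))
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(sig = ifelse(y == 1, 1, -1) * runif(n, 0.8, 1.2),
             noise = rnorm(n, 0, 0.1))
  rownames(X) <- enc$encounter_id
  asg <- data.frame(encounter_id = enc$encounter_id,
                    provider_id = sample(c("a", "b", "c"), n, TRUE),
                    role = "surgical_team")
  asg <- asg[!duplicated(asg[c("encounter_id", "provider_id")]), ]
  tr <- data.frame(encounter_id = enc$encounter_id, unit_type = "acute",
                   sequence_index = 0L, duration = 1)
  g <- build_heterograph(enc, asg, tr, X)
  list(graph = g, y = stats::setNames(y, enc$encounter_id), enc = enc)
}

## Random small graph + random initialized parameters, for property tests.
random_model <- function(seed, n_patients = 40, hidden = 4, attn = 3) {
  tabs <- small_cohort(n_patients = n_patients, seed = seed)
  fm <- build_feature_matrix(tabs$encounters)
  g <- build_heterograph(tabs$encounters, tabs$assignments, tabs$transfers, fm)
  gt <- medhgps:::graph_tensors(g)
  params <- init_iehgcn_params(gt, hidden_dim = hidden, attn_dim = attn,
                               seed = seed)
  list(graph = g, gt = gt, params = params)
}
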