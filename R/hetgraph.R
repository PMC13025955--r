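## Heterogeneous graph construction: encounter, provider-subgroup and
## care-unit node types with per-relation count adjacency matrices. Only
## encounter nodes carry input features; providers and care units are
## featureless and connect to encounters through assignment and transfer
## events (no provider-provider or unit-unit edges).

NODE_TYPES <- c("ENC", "P_surgical", "P_other_clin", "P_nurse", "P_tech",
                "P_other", "C_intermediate", "C_intensive", "C_acute")

ROLE_TYPE <- c(surgical_team = "P_surgical", other_clinician = "P_other_clin",
               nurse = "P_nurse", technician = "P_tech", other = "P_other")
UNIT_TYPE <- c(intermediate = "C_intermediate", intensive = "C_intensive",
               acute = "C_acute")

rel_key <- function(a, b) paste0(a, "~", b)

#' Build the heterogeneous encounter-provider-care-unit graph
#'
#' Node types are `ENC`, five provider subgroups (surgical team, other
#' clinicians, nurses, technicians, others) and three care-unit levels
#' (intermediate, intensive, acute). Edges are undirected and exist only
#' between encounters and the other types: an encounter-provider edge of
#' weight 1 per distinct assignment pair, and an encounter-unit edge weighted
#' by the number of stays of that encounter in that unit type. Adjacency is
#' stored once per relation (ENC rows) and mirrored by transpose on access.
#' Unrecognised provider role strings map to the "other" subgroup with a
#' warning.
#'
#' @param encounters encounter table.
#' @param assignments assignment table (`encounter_id`, `provider_id`, `role`).
#' @param transfers transfer table (`encounter_id`, `unit_type`,
#'   `sequence_index`, `duration`).
#' @param feature_matrix a `medhg_features` object (or a plain numeric matrix
#'   with encounter-id rownames) covering every encounter.
#' @return object of class `hetgraph`: list with `schema` (type -> node ids),
#'   `relations` (named list of sparse count matrices, ENC rows), and
#'   `enc_features`.
#' @export
build_heterograph <- function(encounters, assignments, transfers, feature_matrix) {
  enc_ids <- encounters$encounter_id
  X <- if (inherits(feature_matrix, "medhg_features")) feature_matrix$X else feature_matrix
  if (!is.null(X)) {
    if (is.null(rownames(X)) || !all(enc_ids %in% rownames(X)))
      stopf("feature_matrix rows must cover all encounters")
    X <- X[enc_ids, , drop = FALSE]
  }

  bad <- setdiff(assignments$encounter_id, enc_ids)
  if (length(bad)) stopf("assignment references unknown encounter '%s'", bad[1])
  bad <- setdiff(transfers$encounter_id, enc_ids)
  if (length(bad)) stopf("transfer references unknown encounter '%s'", bad[1])

  role <- as.character(assignments$role)
  unknown <- !role %in% names(ROLE_TYPE)
  if (any(unknown)) {
    warnf("%d assignment(s) with unrecognised role mapped to 'other'",
          sum(unknown))
    role[unknown] <- "other"
  }
  ptype <- ROLE_TYPE[role]

  schema <- list(ENC = enc_ids)
  relations <- list()

  ## encounter-provider: weight 1 per distinct pair
  for (tp in unique(ptype)) {
    sel <- ptype == tp
    pairs <- unique(data.frame(e = assignments$encounter_id[sel],
                               p = assignments$provider_id[sel],
                               stringsAsFactors = FALSE))
    pids <- sort(unique(pairs$p))
    schema[[tp]] <- pids
    relations[[rel_key("ENC", tp)]] <- Matrix::sparseMatrix(
      i = match(pairs$e, enc_ids), j = match(pairs$p, pids), x = 1,
      dims = c(length(enc_ids), length(pids)),
      dimnames = list(enc_ids, pids))
  }

  ## encounter-care-unit: weight = stay count
  ut <- as.character(transfers$unit_type)
  if (length(ut) && any(!ut %in% names(UNIT_TYPE)))
    stopf("unknown unit_type '%s'", setdiff(ut, names(UNIT_TYPE))[1])
  for (u in unique(ut)) {
    tp <- UNIT_TYPE[[u]]
    sel <- ut == u
    schema[[tp]] <- u
    cnt <- tapply(rep(1, sum(sel)), transfers$encounter_id[sel], sum)
    relations[[rel_key("ENC", tp)]] <- Matrix::sparseMatrix(
      i = match(names(cnt), enc_ids), j = rep(1L, length(cnt)),
      x = as.numeric(cnt), dims = c(length(enc_ids), 1L),
      dimnames = list(enc_ids, u))
  }

  ## stable type order
  schema <- schema[intersect(NODE_TYPES, names(schema))]
  out <- list(schema = schema, relations = relations, enc_features = X,
              feature_names = colnames(X))
  class(out) <- "hetgraph"
  out
}

#' @export
print.hetgraph <- function(x, ...) {
  cat("Heterogeneous encounter graph\n")
  for (tp in names(x$schema))
    cat(sprintf("  %-14s %6d nodes\n", tp, length(x$schema[[tp]])))
  for (r in names(x$relations))
    cat(sprintf("  relation %-22s %8.0f total edge weight\n", r,
                sum(x$relations[[r]])))
  cat(if (is.null(x$enc_features)) "  ENC featureless\n" else
      sprintf("  ENC features: %d columns\n", ncol(x$enc_features)))
  invisible(x)
}

## Adjacency of relation (a, b), mirroring the stored ENC-rows matrix.
hetgraph_adjacency <- function(g, a, b) {
  k <- rel_key(a, b)
  if (!is.null(g$relations[[k]])) return(g$relations[[k]])
  k2 <- rel_key(b, a)
  if (!is.null(g$relations[[k2]])) return(Matrix::t(g$relations[[k2]]))
  NULL
}

#' Row-normalize an adjacency matrix
#'
#' Returns `diag(A 1)^-1 A`; rows with no neighbours stay zero rows, so the
#' message for an isolated node is the zero vector.
#'
#' @param A non-negative (sparse or dense) matrix.
#' @return row-stochastic matrix of the same class family.
#' @export
row_normalize <- function(A) {
  if (any(A < 0)) stopf("adjacency entries must be >= 0")
  rs <- Matrix::rowSums(A)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  Matrix::Diagonal(x = inv) %*% A
}

#' Extract an ablation subgraph
#'
#' Restricts the graph to the requested node types (which must include
#' `ENC`). With `use_enc_features = FALSE` the encounter feature matrix is
#' removed; encounter nodes then receive trainable embeddings like the
#' featureless types (the "provider team alone" ablation).
#'
#' @param g a `hetgraph`.
#' @param keep_types character vector of node types to keep; provider and
#'   care-unit families may be named collectively as `"providers"` /
#'   `"units"`.
#' @param use_enc_features keep the encounter feature matrix?
#' @return a `hetgraph`.
#' @export
subgraph <- function(g, keep_types, use_enc_features = TRUE) {
  keep <- unique(unlist(lapply(keep_types, function(k) switch(k,
    providers = unname(ROLE_TYPE), units = unname(UNIT_TYPE), k))))
  if (!"ENC" %in% keep) stopf("keep_types must include ENC")
  keep <- intersect(names(g$schema), keep)
  rels <- g$relations[vapply(names(g$relations), function(k) {
    ab <- strsplit(k, "~", fixed = TRUE)[[1]]
    all(ab %in% keep)
  }, TRUE)]
  out <- list(schema = g$schema[keep], relations = rels,
              enc_features = if (use_enc_features) g$enc_features else NULL,
              feature_names = if (use_enc_features) g$feature_names else NULL)
  class(out) <- "hetgraph"
  out
}

#' Serialize a heterogeneous graph to a directory of CSV/JSON files
#'
#' Each relation becomes a `(row, col, weight)` triplet CSV; the node schema
#' is a JSON file; encounter features a CSV. Human-diffable and
#' language-neutral.
#'
#' @param g a `hetgraph`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_heterograph <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(g$schema, file.path(dir, "schema.json"))
  for (k in names(g$relations)) {
    A <- methods::as(methods::as(g$relations[[k]], "generalMatrix"), "TsparseMatrix")
    utils::write.csv(data.frame(row = rownames(A)[A@i + 1L],
                                col = colnames(A)[A@j + 1L], weight = A@x),
                     file.path(dir, paste0("rel_", gsub("~", "__", k), ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(g$enc_features))
    utils::write.csv(data.frame(encounter_id = rownames(g$enc_features),
                                g$enc_features, check.names = FALSE),
                     file.path(dir, "enc_features.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a heterogeneous graph written by [write_heterograph()]
#'
#' @param dir directory.
#' @return a `hetgraph`.
#' @export
read_heterograph <- function(dir) {
  schema <- lapply(jsonlite::read_json(file.path(dir, "schema.json")),
                   function(x) unlist(x))
  relations <- list()
  for (f in list.files(dir, pattern = "^rel_.*\\.csv$")) {
    k <- gsub("__", "~", sub("^rel_(.*)\\.csv$", "\\1", f))
    ab <- strsplit(k, "~", fixed = TRUE)[[1]]
    d <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
    relations[[k]] <- Matrix::sparseMatrix(
      i = match(d$row, schema[[ab[1]]]), j = match(d$col, schema[[ab[2]]]),
      x = d$weight,
      dims = c(length(schema[[ab[1]]]), length(schema[[ab[2]]])),
      dimnames = list(schema[[ab[1]]], schema[[ab[2]]]))
  }
  X <- NULL
  fx <- file.path(dir, "enc_features.csv")
  if (file.exists(fx)) {
    d <- utils::read.csv(fx, check.names = FALSE, stringsAsFactors = FALSE)
    X <- as.matrix(d[, -1, drop = FALSE])
    rownames(X) <- d$encounter_id
  }
  out <- list(schema = schema, relations = relations, enc_features = X,
              feature_names = colnames(X))
  class(out) <- "hetgraph"
  out
}
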