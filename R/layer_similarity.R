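# Per-layer drug/disease similarities and their fusion into the
# comprehensive matrices S_c (drugs) and S_d (diseases).

#' Tanimoto structural similarity between drugs
#'
#' Similarity of two fingerprints is the size of the intersection of their
#' set bits divided by the size of the union. The diagonal is forced to 1
#' (covering empty fingerprints); two distinct drugs with empty fingerprints
#' get 0.
#'
#' @param fps named list of integer bit-index sets, one entry per drug
#'   (as returned by [read_fingerprints()]).
#' @return drugs x drugs similarity matrix.
#' @export
tanimoto_similarity <- function(fps) {
  ids <- check_registry(names(fps), "fingerprint drug registry")
  m <- length(ids)
  allbits <- sort(unique(unlist(fps)))
  if (length(allbits) == 0) {
    S <- matrix(0, m, m, dimnames = list(ids, ids))
    diag(S) <- 1
    return(S)
  }
  B <- matrix(0, m, length(allbits), dimnames = list(ids, NULL))
  for (i in seq_len(m)) B[i, match(fps[[i]], allbits)] <- 1
  inter <- B %*% t(B)
  sz <- rowSums(B)
  un <- outer(sz, sz, "+") - inter
  S <- ifelse(un > 0, inter / un, 0)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  validate_similarity_matrix(S)
}

#' All-pairs shortest-path hop distances
#'
#' Unit edge lengths throughout. In `unipartite` mode `adj` is a symmetric
#' 0/1 adjacency matrix over one entity set. In the bipartite modes `adj` is
#' a binary rows x cols association matrix interpreted as a bipartite graph;
#' distances are returned between the row (resp. column) entities, so they
#' are always even. Unreachable pairs get `Inf`, the diagonal is 0.
#'
#' @param adj binary matrix with id dimnames.
#' @param mode one of `"unipartite"`, `"bipartite-rows"`, `"bipartite-cols"`.
#' @return symmetric distance matrix over the selected registry.
#' @export
shortest_path_distances <- function(adj,
                                    mode = c("unipartite", "bipartite-rows", "bipartite-cols")) {
  mode <- match.arg(mode)
  check_binary_matrix(adj, "adjacency/association matrix")
  if (mode == "unipartite") {
    if (nrow(adj) != ncol(adj) || !identical(rownames(adj), colnames(adj)))
      stop("unipartite mode needs a square matrix over one registry")
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
    D <- igraph::distances(g)
    return(D[rownames(adj), rownames(adj), drop = FALSE])
  }
  rids <- rownames(adj); cids <- colnames(adj)
  if (any(rids %in% cids)) stop("bipartite modes need disjoint row/column ids")
  idx <- which(adj == 1, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(rids) + length(cids), name = c(rids, cids))
  if (nrow(idx))
    g <- igraph::add_edges(g, rbind(rids[idx[, 1]], cids[idx[, 2]]))
  want <- if (mode == "bipartite-rows") rids else cids
  D <- igraph::distances(g, v = want, to = want)
  D[want, want, drop = FALSE]
}

#' Exponential-decay (Perlman) kernel on a distance matrix
#'
#' Converts hop distances to similarities as `a * exp(-b * d)`, with
#' `exp(-Inf) = 0` for unreachable pairs. The diagonal is forced to 1
#' (self-similarity), even though `a * exp(0) = a < 1`.
#'
#' @param D symmetric distance matrix (`Inf` allowed).
#' @param a amplitude in (0, 1].
#' @param b decay rate > 0.
#' @return similarity matrix over the same registry.
#' @export
perlman_kernel <- function(D, a, b) {
  stopifnot(a > 0, a <= 1, b > 0)
  S <- a * exp(-b * D)
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  validate_similarity_matrix(S)
}

#' Kernel-cosine similarity between two sets of binary profiles
#'
#' Internal workhorse for the gene-layer profile similarity and the prior
#' matrix: rows of `X` and `Yp` are binary gene profiles, compared under the
#' gene-gene kernel metric `Sg` as
#' `x' Sg y / (sqrt(x' Sg x) sqrt(y' Sg y))`. Rows with an empty profile
#' (or zero self-kernel) get 0 against everything.
#'
#' @keywords internal
kernel_cosine_cross <- function(X, Yp, Sg) {
  if (!identical(colnames(X), rownames(Sg)) || !identical(colnames(Yp), rownames(Sg)))
    stop("profile columns must match the gene kernel registry")
  G <- X %*% Sg
  num <- G %*% t(Yp)
  nx <- rowSums(G * X)          # diag(X Sg X')
  ny <- rowSums((Yp %*% Sg) * Yp)
  nx[nx < 0] <- 0; ny[ny < 0] <- 0
  den <- outer(sqrt(nx), sqrt(ny))
  out <- ifelse(den > 0, num / den, 0)
  out[out < 0] <- 0
  out[out > 1] <- 1
  dimnames(out) <- list(rownames(X), rownames(Yp))
  out
}

#' Gene-profile similarity between drugs (or diseases)
#'
#' Cosine similarity of binary gene-association profiles measured under the
#' gene-gene kernel `Sg`. Entities with an empty profile get similarity 0 to
#' all others and 1 to themselves; the diagonal is forced to 1.
#'
#' @param profiles binary entities x genes association matrix.
#' @param Sg gene-gene similarity matrix over the same gene registry.
#' @return entities x entities similarity matrix.
#' @export
profile_kernel_similarity <- function(profiles, Sg) {
  check_binary_matrix(profiles, "profile matrix")
  S <- kernel_cosine_cross(profiles, profiles, Sg)
  diag(S) <- 1
  validate_similarity_matrix(S)
}

#' Treatment-layer similarities from known drug-disease associations
#'
#' Builds the drug-disease bipartite graph of known treatments, computes
#' all-pairs shortest-path distances between drugs (and between diseases),
#' and converts them with the exponential kernel. Only entities with at
#' least one known treatment are covered; use [project_to_full()] to extend
#' the result to the full registries.
#'
#' @param Y binary drugs x diseases treatment matrix.
#' @param a,b kernel amplitude and decay (defaults 0.9 and 1).
#' @return list with `drug` and `disease` similarity matrices over the
#'   covered sub-registries.
#' @export
treatment_similarity <- function(Y, a = 0.9, b = 1) {
  check_binary_matrix(Y, "treatment matrix")
  if (sum(Y) < 1) stop("treatment layer needs at least one known association")
  dsub <- rownames(Y)[rowSums(Y) > 0]
  ssub <- colnames(Y)[colSums(Y) > 0]
  Ysub <- Y[dsub, ssub, drop = FALSE]
  list(
    drug = perlman_kernel(shortest_path_distances(Ysub, "bipartite-rows"), a, b),
    disease = perlman_kernel(shortest_path_distances(Ysub, "bipartite-cols"), a, b)
  )
}

#' Project a partial similarity matrix onto a full registry
#'
#' Entries between two covered entities are copied from `S_partial`. An
#' uncovered entity is placed into the similarity space through its
#' `k_neighbors` nearest covered neighbours in the `reference` matrix: its
#' row is the reference-similarity-weighted average of the neighbours' rows
#' (weights renormalized to sum 1); a pair of uncovered entities uses the
#' double-weighted average. An uncovered entity with zero reference
#' similarity to every covered entity gets 0 off-diagonal. The result is
#' symmetrized by averaging and gets a unit diagonal.
#'
#' @param S_partial similarity matrix over a subset of `reference`'s ids.
#' @param reference similarity matrix over the full registry.
#' @param k_neighbors number of covered neighbours used per uncovered entity.
#' @return similarity matrix over the full registry.
#' @export
project_to_full <- function(S_partial, reference, k_neighbors = 5) {
  S_partial <- validate_similarity_matrix(S_partial)
  reference <- validate_similarity_matrix(reference)
  covered <- rownames(S_partial)
  full <- rownames(reference)
  if (length(covered) == 0) stop("empty covered set")
  if (!all(covered %in% full)) stop("S_partial ids must be a subset of the reference registry")
  W <- matrix(0, length(full), length(covered), dimnames = list(full, covered))
  W[cbind(match(covered, full), seq_along(covered))] <- 1
  for (x in setdiff(full, covered)) {
    r <- reference[x, covered]
    k <- min(k_neighbors, length(covered))
    nb <- names(sort(r, decreasing = TRUE))[seq_len(k)]
    w <- r[nb]
    if (sum(w) > 0) W[x, nb] <- w / sum(w)
  }
  S <- W %*% S_partial %*% t(W)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  validate_similarity_matrix(S)
}

#' Zero out sub-threshold similarities
#'
#' Off-diagonal entries strictly below `tau` are set to 0; entries at or
#' above `tau` and the diagonal are kept.
#'
#' @param S similarity matrix.
#' @param tau threshold in \[0, 1\].
#' @return thresholded similarity matrix.
#' @export
apply_threshold <- function(S, tau) {
  stopifnot(tau >= 0, tau <= 1)
  S <- validate_similarity_matrix(S)
  S[S < tau] <- 0
  diag(S) <- 1
  S
}

#' Equal-contribution fusion weights from layer means
#'
#' Each layer's weight is proportional to the inverse of its mean
#' off-diagonal similarity, normalized to sum 1, so that
#' `weight * mean` is constant across layers: a layer whose scores run small
#' is up-weighted so all layers contribute equally to the fused matrix.
#'
#' @param means numeric vector of per-layer mean similarities (all > 0).
#' @return weight vector of the same length summing to 1.
#' @export
weights_from_means <- function(means) {
  if (any(!is.finite(means)) || any(means <= 0))
    stop("layer weights undefined: every layer mean must be positive")
  inv <- 1 / means
  w <- inv / sum(inv)
  names(w) <- names(means)
  w
}

#' Equal-contribution weights for three layer matrices
#'
#' Computes the mean off-diagonal entry of each layer matrix and applies the
#' inverse-mean rule of [weights_from_means()]. The diagonal is excluded
#' because it is identically 1 and carries no layer information.
#'
#' @param S_base,S_gene,S_treat similarity matrices over one registry.
#' @return named weight vector (base, gene, treatment) summing to 1.
#' @export
equal_contribution_weights <- function(S_base, S_gene, S_treat) {
  layers <- list(base = S_base, gene = S_gene, treatment = S_treat)
  means <- vapply(layers, function(S) {
    n <- nrow(S)
    if (n < 2) stop("need at least two entities to compute off-diagonal means")
    (sum(S) - sum(diag(S))) / (n * (n - 1))
  }, 1)
  weights_from_means(means)
}

#' Fuse layer similarity matrices by convex combination
#'
#' @param S_base,S_gene,S_treat similarity matrices sharing one registry.
#' @param w weight vector of length 3 (non-negative, summing to 1).
#' @return fused similarity matrix.
#' @export
fuse_layers <- function(S_base, S_gene, S_treat, w) {
  stopifnot(length(w) == 3, all(w >= 0), abs(sum(w) - 1) < 1e-12)
  if (!identical(rownames(S_base), rownames(S_gene)) ||
      !identical(rownames(S_base), rownames(S_treat)))
    stop("layer matrices must share one registry")
  S <- w[[1]] * S_base + w[[2]] * S_gene + w[[3]] * S_treat
  validate_similarity_matrix(S)
}
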