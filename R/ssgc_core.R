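# The semi-supervised graph cut solver over the implicit drug-disease pair
# graph. Nodes are all m*n (drug, disease) pairs; the edge weight between
# pairs s=(i,j) and t=(i',j') is S_c(i,i') * S_d(j,j') with no self-loops.
# The q x q weight matrix is Kronecker-structured and is never materialized:
# the normalized propagation operator is applied through m x n fields only.
#
# Flattening convention: pair s (0-based) = i0 * n + j0, i.e. vec(F) taken
# row-major over the drugs x diseases field. All dense oracles below use
# kronecker(Sc, Sd), which realizes exactly this indexing.

#' Gene-overlap prior for unlabeled drug-disease pairs
#'
#' For an unlabeled pair (i, j) the prior is the kernel-cosine similarity of
#' the drug's and the disease's gene profiles under the gene-gene kernel:
#' a drug hitting genes associated with the disease is a mechanistically
#' plausible candidate. Known treatment pairs (Y = 1) get prior 0, as do
#' pairs where either profile is empty.
#'
#' @param C binary drugs x genes association matrix.
#' @param D binary diseases x genes association matrix.
#' @param Sg gene-gene similarity matrix.
#' @param Y binary drugs x diseases treatment matrix.
#' @return drugs x diseases prior matrix P in \[0, 1\].
#' @export
compute_prior <- function(C, D, Sg, Y) {
  check_binary_matrix(C, "drug-gene matrix")
  check_binary_matrix(D, "disease-gene matrix")
  check_binary_matrix(Y, "treatment matrix")
  if (!identical(rownames(Y), rownames(C)) || !identical(colnames(Y), rownames(D)))
    stop("Y registries must match the drug-gene and disease-gene matrices")
  P <- kernel_cosine_cross(C, D, Sg)
  P[Y == 1] <- 0
  P
}

#' Degrees of the implicit pair graph
#'
#' The degree of pair node s = (i, j) is
#' `a_s = sum_i' S_c(i, i') * sum_j' S_d(j, j') - 1`, the row sum of the
#' pair-graph weight matrix (the -1 removes the would-be self-loop). In
#' `selfloops` mode (the HGBI reduction) the -1 is dropped. Degrees below
#' `degree_floor` (isolated pair nodes, possible after aggressive
#' thresholding) are floored with a warning rather than failing.
#'
#' @param Sc,Sd fused drug and disease similarity matrices.
#' @param degree_floor minimum degree substituted for smaller values.
#' @param selfloops logical; keep the self-loop weight in the degree.
#' @return list with `a` (m x n degree field), `A_hat` (elementwise sqrt)
#'   and `A_tilde` (= `A_hat^2` = `a`).
#' @export
pair_degrees <- function(Sc, Sd, degree_floor = 1e-12, selfloops = FALSE) {
  a <- outer(rowSums(Sc), colSums(Sd))
  if (!selfloops) a <- a - 1
  low <- a < degree_floor
  if (any(low)) {
    warning(sprintf("%d isolated pair node(s): degree floored at %g",
                    sum(low), degree_floor))
    a[low] <- degree_floor
  }
  list(a = a, A_hat = sqrt(a), A_tilde = a)
}

#' Apply the normalized pair-graph operator without materializing it
#'
#' Computes the field form of `S f` where
#' `S = A^{-1/2} (K - I_q) A^{-1/2}`, `K_st = S_c(i,i') S_d(j,j')`, using
#' only m x n and registry-sized products:
#' `Sf = S_c (F / A_hat) S_d / A_hat - F / A_tilde`.
#' With `selfloops = TRUE` the identity correction is dropped and `S`
#' normalizes the full Kronecker weight matrix (HGBI reduction).
#'
#' @param F drugs x diseases field.
#' @param Sc,Sd similarity matrices.
#' @param degrees degree list from [pair_degrees()] (must match `selfloops`).
#' @param selfloops logical, see [pair_degrees()].
#' @return drugs x diseases field equal to the dense product `S f`.
#' @export
apply_S <- function(F, Sc, Sd, degrees, selfloops = FALSE) {
  G <- F / degrees$A_hat
  out <- (Sc %*% G %*% Sd) / degrees$A_hat
  if (!selfloops) out <- out - F / degrees$A_tilde
  out
}

#' @keywords internal
loss_terms <- function(F, SF, Y, P, mu, xi) {
  U <- 1 - Y
  smooth <- 0.5 * (sum(F * F) - sum(F * SF))
  fitL <- 0.5 * mu * sum((Y * F - Y)^2)
  fitU <- 0.5 * xi * sum((U * F - P)^2)
  smooth + fitL + fitU
}

#' Loss of the relaxed graph-cut objective
#'
#' `0.5 f' (I - S) f + (mu/2) ||L f - y||^2 + (xi/2) ||U f - p||^2`, where
#' L and U select the labeled and unlabeled pairs, evaluated through the
#' implicit operator.
#'
#' @param F candidate score field (drugs x diseases).
#' @param Sc,Sd similarity matrices.
#' @param Y binary label field; `P` prior field.
#' @param mu,xi label and prior fit penalties.
#' @param degrees optional precomputed [pair_degrees()] result.
#' @return scalar loss.
#' @export
ssgc_loss <- function(F, Sc, Sd, Y, P, mu = 4, xi = 0.67, degrees = NULL) {
  if (is.null(degrees)) degrees <- pair_degrees(Sc, Sd)
  loss_terms(F, apply_S(F, Sc, Sd, degrees), Y, P, mu, xi)
}

#' Gradient of the relaxed graph-cut objective
#'
#' `(I + mu L + xi U) f - S f - (mu y + xi p)` in field form; its maximum
#' absolute entry at a solver output measures stationarity.
#'
#' @inheritParams ssgc_loss
#' @return drugs x diseases gradient field.
#' @export
ssgc_gradient <- function(F, Sc, Sd, Y, P, mu = 4, xi = 0.67, degrees = NULL) {
  if (is.null(degrees)) degrees <- pair_degrees(Sc, Sd)
  U <- 1 - Y
  F + mu * Y * F + xi * U * F - apply_S(F, Sc, Sd, degrees) - (mu * Y + xi * P)
}

#' @keywords internal
new_ssgc_result <- function(scores, iterations, converged, loss_trace, mode) {
  structure(list(scores = scores, iterations = iterations,
                 converged = converged,
                 final_loss = loss_trace[length(loss_trace)],
                 loss_trace = loss_trace, mode = mode),
            class = "ssgc_result")
}

#' @export
print.ssgc_result <- function(x, ...) {
  cat(sprintf("%s propagation: %d x %d pairs, %d iterations (%s), final loss %.6g\n",
              x$mode, nrow(x$scores), ncol(x$scores), x$iterations,
              if (x$converged) "converged" else "NOT converged", x$final_loss))
  invisible(x)
}

#' Semi-supervised graph-cut label propagation
#'
#' Iterates `f^(k+1) = alpha [ (mu - xi) U + S ] f^(k) + (1 - alpha) y_hat`
#' with `alpha = 1 / (1 + mu)` and `y_hat = y + (xi / mu) p`, starting from
#' `f^(0) = y_hat`, through the implicit operator of [apply_S()]. The
#' iteration map has spectral radius below 1 whenever `mu > xi > 0`, so the
#' sequence converges to the unique minimizer of the relaxed objective; the
#' relaxation is not re-clipped to \[0, 1\].
#'
#' @param Sc,Sd fused drug and disease similarity matrices.
#' @param Y binary drugs x diseases treatment label field.
#' @param P prior field (same shape); use 0 to disable the prior.
#' @param mu label-fit penalty (> xi); default 4.
#' @param xi prior-fit penalty (> 0); default 0.67.
#' @param tol convergence tolerance on the max-abs update; default 1e-6.
#' @param max_iter iteration cap; default 1000.
#' @param degree_floor floor for isolated pair-node degrees.
#' @return an `ssgc_result`: `scores` (non-negative drugs x diseases field),
#'   `iterations`, `converged`, `final_loss`, `loss_trace`.
#' @export
ssgc_solve <- function(Sc, Sd, Y, P, mu = 4, xi = 0.67, tol = 1e-6,
                       max_iter = 1000, degree_floor = 1e-12) {
  check_binary_matrix(Y, "treatment matrix")
  if (!(mu > xi && xi > 0)) stop("need mu > xi > 0")
  propagate(Sc, Sd, Y, P, mu = mu, xi = xi, tol = tol, max_iter = max_iter,
            degree_floor = degree_floor, selfloops = FALSE, mode = "SSGC")
}

#' HGBI reduction of the graph-cut propagation
#'
#' The same iteration with the prior disabled (`p = 0`), equal penalties
#' (`mu = xi`, so the unlabeled correction term vanishes) and self-loops
#' kept in the pair-graph weights (`W_ss = 1`, so degrees keep the full row
#' sum and the operator drops the identity correction). This reproduces
#' HGBI-style propagation on the normalized Kronecker similarity network,
#' exposed as a named mode for layer-ablation comparisons.
#'
#' @inheritParams ssgc_solve
#' @param mu penalty used for both labeled and unlabeled terms.
#' @return an `ssgc_result`.
#' @export
hgbi_mode_solve <- function(Sc, Sd, Y, mu = 4, tol = 1e-6, max_iter = 1000,
                            degree_floor = 1e-12) {
  check_binary_matrix(Y, "treatment matrix")
  P <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  propagate(Sc, Sd, Y, P, mu = mu, xi = mu, tol = tol, max_iter = max_iter,
            degree_floor = degree_floor, selfloops = TRUE, mode = "HGBI")
}

#' @keywords internal
propagate <- function(Sc, Sd, Y, P, mu, xi, tol, max_iter, degree_floor,
                      selfloops, mode) {
  stopifnot(identical(dim(Y), dim(P)),
            nrow(Y) == nrow(Sc), ncol(Y) == nrow(Sd))
  degrees <- pair_degrees(Sc, Sd, degree_floor = degree_floor,
                          selfloops = selfloops)
  alpha <- 1 / (1 + mu)
  Yhat <- Y + (xi / mu) * P
  U <- 1 - Y
  F <- Yhat
  loss_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (k in seq_len(max_iter)) {
    SF <- apply_S(F, Sc, Sd, degrees, selfloops = selfloops)
    loss_trace <- c(loss_trace, loss_terms(F, SF, Y, P, mu, xi))
    Fnew <- alpha * ((mu - xi) * (U * F) + SF) + (1 - alpha) * Yhat
    if (any(!is.finite(Fnew)))
      stop("non-finite values during propagation: check degrees and inputs")
    iterations <- k
    delta <- max(abs(Fnew - F))
    F <- Fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  SF <- apply_S(F, Sc, Sd, degrees, selfloops = selfloops)
  loss_trace <- c(loss_trace, loss_terms(F, SF, Y, P, mu, xi))
  dimnames(F) <- dimnames(Y)
  new_ssgc_result(F, iterations, converged, loss_trace, mode)
}

#' Exact minimizer of the relaxed objective by dense linear algebra
#'
#' Builds the q x q normalized pair-graph operator explicitly
#' (`q = m * n`, row-major pair indexing realized by `kronecker(Sc, Sd)`)
#' and solves the stationarity system
#' `(I_q + mu L + xi U - S) f = mu y + xi p`. Intended as the oracle for
#' [ssgc_solve()] on small instances.
#'
#' @inheritParams ssgc_solve
#' @param dense_cap refuse instances with `m * n` above this (default 2500).
#' @return drugs x diseases score field.
#' @export
closed_form_solve <- function(Sc, Sd, Y, P, mu = 4, xi = 0.67,
                              degree_floor = 1e-12, dense_cap = 2500) {
  m <- nrow(Y); n <- ncol(Y); q <- m * n
  if (q > dense_cap) stop("instance too large for the dense solver (q = ", q, ")")
  S <- dense_pair_operator(Sc, Sd, degree_floor = degree_floor)
  y <- as.vector(t(Y)); p <- as.vector(t(P))
  M <- diag(1 + mu * y + xi * (1 - y), q) - S
  f <- solve(M, mu * y + xi * p)
  matrix(f, m, n, byrow = TRUE, dimnames = dimnames(Y))
}

#' Dense normalized pair-graph operator (for small instances)
#'
#' Explicit `S = A^{-1/2} W A^{-1/2}` with `W = kronecker(Sc, Sd)` minus its
#' diagonal (or including it when `selfloops`). Exposed for diagnostics such
#' as spectral-radius checks of the iteration map.
#'
#' @inheritParams pair_degrees
#' @return q x q matrix, q = m * n, row-major pair order.
#' @export
dense_pair_operator <- function(Sc, Sd, degree_floor = 1e-12, selfloops = FALSE) {
  W <- kronecker(Sc, Sd)
  if (!selfloops) diag(W) <- 0
  a <- rowSums(W)
  low <- a < degree_floor
  if (any(low)) a[low] <- degree_floor
  d <- 1 / sqrt(a)
  W * outer(d, d)
}

#' Hard cut of a score field at a threshold
#'
#' Assigns each pair to the treatment group when its propagated score is at
#' or above `threshold`. Rankings, not cuts, are the primary output; this
#' helper recovers the binary cut view of the objective.
#'
#' @param scores drugs x diseases score field (or an `ssgc_result`).
#' @param threshold score cut point.
#' @return logical drugs x diseases matrix.
#' @export
cut_pairs <- function(scores, threshold = 0.05) {
  if (inherits(scores, "ssgc_result")) scores <- scores$scores
  scores >= threshold
}
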