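# Independent oracles and fixture builders. Everything here is coded
# directly from the dense definitions (explicit q x q matrices, brute-force
# enumeration) so it shares no code path with the package's implicit
# operator or sweep-based metrics.

rand_similarity <- function(n, prefix = "e") {
  M <- matrix(runif(n * n), n, n)
  S <- (M + t(M)) / 2
  diag(S) <- 1
  dimnames(S) <- list(paste0(prefix, seq_len(n)), paste0(prefix, seq_len(n)))
  S
}

rand_instance <- function(m, n, pos_rate = 0.3) {
  Sc <- rand_similarity(m, "dr")
  Sd <- rand_similarity(n, "di")
  Y <- matrix(rbinom(m * n, 1, pos_rate), m, n,
              dimnames = list(rownames(Sc), rownames(Sd)))
  P <- matrix(runif(m * n) * 0.3, m, n, dimnames = dimnames(Y))
  P[Y == 1] <- 0
  list(Sc = Sc, Sd = Sd, Y = Y, P = P)
}

# Dense normalized pair-graph operator, built entry by entry from the
# definition W_st = Sc(i,i') Sd(j,j') (s != t), s0 = i0 * n + j0.
oracle_dense_S <- function(Sc, Sd, selfloops = FALSE) {
  m <- nrow(Sc); n <- nrow(Sd); q <- m * n
  W <- matrix(0, q, q)
  for (s in seq_len(q)) {
    i <- (s - 1) %/% n + 1; j <- (s - 1) %% n + 1
    for (t in seq_len(q)) {
      ii <- (t - 1) %/% n + 1; jj <- (t - 1) %% n + 1
      W[s, t] <- Sc[i, ii] * Sd[j, jj]
    }
  }
  if (!selfloops) diag(W) <- 0
  a <- rowSums(W)
  diag(1 / sqrt(a)) %*% W %*% diag(1 / sqrt(a))
}

oracle_vec <- function(F) as.vector(t(F))
oracle_field <- function(f, m, n, dn = NULL) matrix(f, m, n, byrow = TRUE, dimnames = dn)

# Dense loss from Eq-level definitions: 0.5 f'(I - S)f + fits.
oracle_loss <- function(F, Sc, Sd, Y, P, mu, xi) {
  S <- oracle_dense_S(Sc, Sd)
  f <- oracle_vec(F); y <- oracle_vec(Y); p <- oracle_vec(P)
  q <- length(f)
  L <- diag(q) - S
  0.5 * drop(t(f) %*% L %*% f) +
    mu / 2 * sum((y * f - y)^2) +
    xi / 2 * sum(((1 - y) * f - p)^2)
}

# Independently coded HGBI-style propagation: normalized Kronecker
# similarity with self-loops, f <- alpha S f + (1 - alpha) y, dense algebra.
oracle_hgbi <- function(Sc, Sd, Y, mu, tol = 1e-10, max_iter = 10000) {
  S <- oracle_dense_S(Sc, Sd, selfloops = TRUE)
  alpha <- 1 / (1 + mu)
  y <- oracle_vec(Y)
  f <- y
  for (k in seq_len(max_iter)) {
    fn <- alpha * drop(S %*% f) + (1 - alpha) * y
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  oracle_field(f, nrow(Y), ncol(Y), dimnames(Y))
}

# Brute-force pairwise ranking probability (Mann-Whitney form).
oracle_rank_auc <- function(scores_pos, scores_neg) {
  wins <- 0
  for (sp in scores_pos)
    for (sn in scores_neg)
      wins <- wins + (sp > sn) + 0.5 * (sp == sn)
  wins / (length(scores_pos) * length(scores_neg))
}

small_fps <- function() {
  list(d1 = c(1L, 2L, 3L), d2 = c(2L, 3L, 4L), d3 = c(10L, 11L), d4 = integer(0))
}
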