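# The graph-cut solver: prior, implicit-operator correctness against dense
# oracles, loss/gradient, fixed-point agreement, and the HGBI reduction.

test_that("gene-overlap prior follows the two-branch definition", {
  genes <- paste0("g", 1:3)
  Sg <- diag(3); dimnames(Sg) <- list(genes, genes)
  C <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, dimnames = list(c("d1", "d2"), genes))
  D <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("x1", "x2"), genes))
  Y <- matrix(0, 2, 2, dimnames = list(c("d1", "d2"), c("x1", "x2")))
  P <- compute_prior(C, D, Sg, Y)
  expect_equal(P["d1", "x1"], 1)      # identical unit profiles, unlabeled
  expect_equal(P["d2", "x1"], 0)      # empty drug profile
  Y2 <- Y; Y2["d1", "x1"] <- 1
  expect_equal(compute_prior(C, D, Sg, Y2)["d1", "x1"], 0)  # labeled pair
})

test_that("pair degrees equal the dense row sums, with flooring on isolates", {
  ids <- c("a", "b")
  J <- matrix(1, 2, 2, dimnames = list(ids, ids))
  deg <- pair_degrees(J, J)
  expect_equal(unname(deg$a), matrix(3, 2, 2))      # 2*2 - 1
  expect_equal(deg$A_hat^2, deg$A_tilde)
  I2 <- diag(2); dimnames(I2) <- list(ids, ids)
  expect_warning(deg0 <- pair_degrees(I2, I2), "floored")
  expect_equal(unname(deg0$a), matrix(1e-12, 2, 2))

  set.seed(17)
  Sc <- rand_similarity(4); Sd <- rand_similarity(3)
  W <- kronecker(Sc, Sd); diag(W) <- 0
  expect_equal(oracle_vec(pair_degrees(Sc, Sd)$a), rowSums(W), tolerance = 1e-12)
})

test_that("implicit operator matches the dense normalized operator", {
  set.seed(23)
  for (rep in 1:10) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    inst <- rand_instance(m, n)
    F <- matrix(runif(m * n), m, n)
    deg <- pair_degrees(inst$Sc, inst$Sd)
    got <- apply_S(F, inst$Sc, inst$Sd, deg)
    S <- oracle_dense_S(inst$Sc, inst$Sd)
    want <- oracle_field(drop(S %*% oracle_vec(F)), m, n)
    expect_lt(max(abs(got - want)), 1e-10)
  }
  # linearity: zero field maps to zero
  inst <- rand_instance(3, 3)
  deg <- pair_degrees(inst$Sc, inst$Sd)
  expect_equal(unname(apply_S(matrix(0, 3, 3), inst$Sc, inst$Sd, deg)),
               matrix(0, 3, 3))
  # all-ones similarities: row sums of K - I are 3, degrees 3, output 1
  J <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  degJ <- pair_degrees(J, J)
  expect_equal(unname(apply_S(matrix(1, 2, 2), J, J, degJ)), matrix(1, 2, 2))
})

test_that("loss matches the explicit normalized-Laplacian construction", {
  set.seed(29)
  for (rep in 1:5) {
    inst <- rand_instance(4, 3)
    F <- matrix(runif(12), 4, 3)
    expect_equal(ssgc_loss(F, inst$Sc, inst$Sd, inst$Y, inst$P, 4, 0.67),
                 oracle_loss(F, inst$Sc, inst$Sd, inst$Y, inst$P, 4, 0.67),
                 tolerance = 1e-10)
  }
  inst <- rand_instance(3, 4, pos_rate = 1)  # fully labeled
  Z <- matrix(0, 3, 4)
  expect_equal(ssgc_loss(Z, inst$Sc, inst$Sd, Z, Z, 4, 0.67), 0)
})

test_that("iterative solver agrees with the closed form and is stationary", {
  set.seed(37)
  for (rep in 1:5) {
    m <- sample(3:6, 1); n <- sample(3:5, 1)
    inst <- rand_instance(m, n)
    res <- ssgc_solve(inst$Sc, inst$Sd, inst$Y, inst$P, tol = 1e-9,
                      max_iter = 5000)
    cf <- closed_form_solve(inst$Sc, inst$Sd, inst$Y, inst$P)
    expect_true(res$converged)
    expect_lt(max(abs(res$scores - cf)), 1e-8)
    g <- ssgc_gradient(cf, inst$Sc, inst$Sd, inst$Y, inst$P)
    expect_lt(max(abs(g)), 1e-8)
    expect_true(all(res$scores >= 0))
    expect_lte(res$final_loss, res$loss_trace[1])
  }
})

test_that("zero labels and prior give the zero fixed point immediately", {
  set.seed(41)
  inst <- rand_instance(4, 4, pos_rate = 0)
  Z <- matrix(0, 4, 4, dimnames = dimnames(inst$Y))
  res <- ssgc_solve(inst$Sc, inst$Sd, Z, Z)
  expect_equal(unname(res$scores), matrix(0, 4, 4))
  expect_equal(res$iterations, 1L)
  expect_equal(unname(closed_form_solve(inst$Sc, inst$Sd, Z, Z)),
               matrix(0, 4, 4))
})

test_that("solver guards: parameter ordering, dense cap, degenerate inputs", {
  inst <- rand_instance(3, 3)
  expect_error(ssgc_solve(inst$Sc, inst$Sd, inst$Y, inst$P, mu = 1, xi = 2),
               "mu > xi")
  expect_error(closed_form_solve(inst$Sc, inst$Sd, inst$Y, inst$P,
                                 dense_cap = 4), "too large")
})

test_that("iteration map contracts and label fidelity grows with mu", {
  set.seed(43)
  for (rep in 1:5) {
    inst <- rand_instance(4, 4)
    S <- oracle_dense_S(inst$Sc, inst$Sd)
    u <- 1 - oracle_vec(inst$Y)
    mu <- 4; xi <- 0.67
    M <- (1 / (1 + mu)) * (diag((mu - xi) * u) + S)
    expect_lt(max(Mod(eigen(M, only.values = TRUE)$values)), 1)
  }
  inst <- rand_instance(5, 4)
  fid <- sapply(c(1, 4, 16, 64), function(mu) {
    f <- closed_form_solve(inst$Sc, inst$Sd, inst$Y, inst$P, mu = mu, xi = 0.67)
    sqrt(sum((inst$Y * f - inst$Y)^2))
  })
  expect_true(all(diff(fid) <= 1e-9))
})

test_that("HGBI mode matches independent dense propagation and differs from SSGC", {
  set.seed(47)
  for (rep in 1:5) {
    inst <- rand_instance(4, 3)
    got <- hgbi_mode_solve(inst$Sc, inst$Sd, inst$Y, mu = 4, tol = 1e-11,
                           max_iter = 20000)
    want <- oracle_hgbi(inst$Sc, inst$Sd, inst$Y, mu = 4, tol = 1e-11)
    expect_lt(max(abs(got$scores - want)), 1e-8)
  }
  inst <- rand_instance(4, 4)
  ssgc <- ssgc_solve(inst$Sc, inst$Sd, inst$Y, inst$P)
  hgbi <- hgbi_mode_solve(inst$Sc, inst$Sd, inst$Y)
  expect_gt(max(abs(ssgc$scores - hgbi$scores)), 1e-6)
  Z <- matrix(0, 4, 4, dimnames = dimnames(inst$Y))
  expect_equal(unname(hgbi_mode_solve(inst$Sc, inst$Sd, Z)$scores),
               matrix(0, 4, 4))
})

test_that("known positives score above unknown pairs on planted structure", {
  aucs <- numeric(3)
  for (s in 1:3) {
    ds <- generate_network(synthetic_config(m = 24, n = 16, l = 60, seed = s))
    fit <- ssgc_pipeline(ds)
    pos <- fit$result$scores[ds$Y == 1]
    neg <- fit$result$scores[ds$Y == 0]
    expect_gt(mean(pos), mean(neg))
  }
})

test_that("hard cut utility thresholds the score field", {
  scores <- matrix(c(0.2, 0.04, 0.05, 0), 2, 2)
  expect_equal(unname(cut_pairs(scores, 0.05)),
               matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
})
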