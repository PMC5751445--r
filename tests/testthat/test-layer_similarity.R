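# Layer similarity computations: Tanimoto, shortest paths, exponential
# kernel, kernel-cosine profiles, projection, thresholding and fusion.

test_that("Tanimoto similarity matches the set definition", {
  S <- tanimoto_similarity(small_fps())
  expect_equal(S["d1", "d2"], 2 / 4)        # {1,2,3} vs {2,3,4}
  expect_equal(S["d1", "d3"], 0)            # disjoint
  expect_equal(S["d1", "d1"], 1)
  expect_equal(S["d4", "d4"], 1)            # empty fingerprint self-sim
  expect_equal(S["d4", "d1"], 0)            # empty vs non-empty
  expect_identical(S, t(S))
  fps2 <- list(a = c(5L, 9L), b = c(5L, 9L))
  expect_equal(tanimoto_similarity(fps2)["a", "b"], 1)
})

test_that("bipartite shortest paths count hops through the other side", {
  # chain drugA - disX - drugB - disY - drugC
  Y <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("X", "Yd")))
  Y["A", "X"] <- 1; Y["B", "X"] <- 1; Y["B", "Yd"] <- 1; Y["C", "Yd"] <- 1
  D <- shortest_path_distances(Y, "bipartite-rows")
  expect_equal(D["A", "B"], 2)   # share a disease
  expect_equal(D["A", "C"], 4)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  Dd <- shortest_path_distances(Y, "bipartite-cols")
  expect_equal(Dd["X", "Yd"], 2)

  # isolated drug is unreachable
  Y2 <- rbind(Y, Z = c(0, 0))
  D2 <- shortest_path_distances(Y2, "bipartite-rows")
  expect_true(all(is.infinite(D2["Z", c("A", "B", "C")])))
})

test_that("exponential kernel evaluates a*exp(-b*d) with unit diagonal", {
  D <- matrix(c(0, 1, 2, 1, 0, Inf, 2, Inf, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  S <- perlman_kernel(D, a = 0.3, b = 1.0)
  expect_equal(S["a", "b"], 0.3 * exp(-1), tolerance = 1e-12)
  expect_equal(S["a", "c"], 0.3 * exp(-2), tolerance = 1e-12)
  expect_equal(S["b", "c"], 0)            # unreachable
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  S9 <- perlman_kernel(D, a = 0.9, b = 1.0)
  expect_equal(S9["a", "c"], 0.9 * exp(-2), tolerance = 1e-12)

  # monotone decrease in distance
  set.seed(3)
  d <- sort(sample(1:10, 5))
  s <- 0.5 * exp(-0.7 * d)
  expect_true(all(diff(s) < 0))
})

test_that("treatment-layer similarity composes bipartite distances and kernel", {
  Y <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("X", "Yd")))
  Y["A", "X"] <- 1; Y["B", "X"] <- 1; Y["C", "Yd"] <- 1
  ts <- treatment_similarity(Y, a = 0.9, b = 1)
  expect_equal(ts$drug["A", "A"], 1)
  expect_equal(ts$drug["A", "B"], 0.9 * exp(-2), tolerance = 1e-12)
  expect_equal(ts$drug["A", "C"], 0)      # disconnected components
  # only drugs/diseases with at least one positive are covered
  Y2 <- Y; Y2["C", ] <- 0
  expect_identical(rownames(treatment_similarity(Y2)$drug), c("A", "B"))
})

test_that("profile kernel-cosine reduces to plain cosine under identity kernel", {
  genes <- paste0("g", 1:4)
  Sg <- diag(4); dimnames(Sg) <- list(genes, genes)
  profiles <- rbind(p1 = c(1, 0, 0, 0), p2 = c(1, 1, 0, 0), p3 = c(0, 0, 0, 0))
  colnames(profiles) <- genes
  S <- profile_kernel_similarity(profiles, Sg)
  expect_equal(S["p1", "p2"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(S["p1", "p1"], 1)
  expect_equal(S["p3", "p1"], 0)          # empty profile
  expect_equal(S["p3", "p3"], 1)

  # property: with identity Sg, equals cosine of binary vectors
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rbinom(6 * 8, 1, 0.4), 6, 8,
                dimnames = list(paste0("e", 1:6), paste0("h", 1:8)))
    I8 <- diag(8); dimnames(I8) <- list(colnames(X), colnames(X))
    S <- profile_kernel_similarity(X, I8)
    for (i in 1:5) for (j in (i + 1):6) {
      ni <- sqrt(sum(X[i, ])); nj <- sqrt(sum(X[j, ]))
      want <- if (ni == 0 || nj == 0) 0 else sum(X[i, ] * X[j, ]) / (ni * nj)
      expect_equal(S[i, j], want, tolerance = 1e-12)
    }
  }
})

test_that("identical non-empty profiles have similarity 1 under any kernel", {
  set.seed(5)
  Sg <- rand_similarity(6, "g")
  X <- matrix(rbinom(18, 1, 0.5), 3, 6,
              dimnames = list(c("a", "b", "c"), rownames(Sg)))
  X["b", ] <- X["a", ]; X["a", 1] <- 1; X["b", 1] <- 1
  S <- profile_kernel_similarity(X, Sg)
  expect_equal(S["a", "b"], 1, tolerance = 1e-9)
})

test_that("projection copies covered entries and kNN-averages the rest", {
  ids <- c("a", "b", "c")
  ref <- matrix(c(1, .8, .9, .8, 1, .1, .9, .1, 1), 3, 3,
                dimnames = list(ids, ids))
  Sp <- matrix(c(1, .4, .4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  # all covered: identity case
  expect_equal(project_to_full(Sp, ref[1:2, 1:2]), Sp)
  out <- project_to_full(Sp, ref, k_neighbors = 1)
  # c's single nearest covered neighbour is a (ref .9), weight renormalizes to 1:
  # row of c copies row of a
  expect_equal(out["c", "b"], Sp["a", "b"])
  expect_equal(out["c", "c"], 1)
  expect_equal(out, t(out))

  # uncovered entity with zero reference similarity to covered set
  ref0 <- diag(3); dimnames(ref0) <- list(ids, ids)
  out0 <- project_to_full(Sp, ref0, k_neighbors = 2)
  expect_equal(out0["c", "a"], 0)
  expect_equal(out0["c", "c"], 1)
})

test_that("thresholding zeroes strictly-below entries and keeps the diagonal", {
  S <- matrix(c(1, .05, .1, .05, 1, .2, .1, .2, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  out <- apply_threshold(S, 0.1)
  expect_equal(out["a", "b"], 0)
  expect_equal(out["a", "c"], 0.1)   # boundary value survives
  expect_equal(diag(out), c(a = 1, b = 1, c = 1))
  expect_equal(apply_threshold(S, 0), S)
})

test_that("equal-contribution weights follow the inverse-mean rule", {
  w <- weights_from_means(c(0.017, 0.028, 0.057))
  expect_equal(unname(w), c(0.5248, 0.3187, 0.1565), tolerance = 1e-3)
  expect_equal(sum(w), 1)
  # weight * mean is constant across layers
  expect_equal(diff(range(w * c(0.017, 0.028, 0.057))), 0, tolerance = 1e-12)

  w2 <- weights_from_means(c(0.006, 0.028, 0.038))
  expect_equal(unname(w2), c(0.7288, 0.1562, 0.1151), tolerance = 1e-3)
  expect_equal(unname(weights_from_means(c(2, 2, 2))), rep(1 / 3, 3))
  expect_error(weights_from_means(c(0, 0.1, 0.2)), "positive")

  # matrix version excludes the diagonal
  ids <- c("a", "b")
  mk <- function(v) matrix(c(1, v, v, 1), 2, 2, dimnames = list(ids, ids))
  w3 <- equal_contribution_weights(mk(0.1), mk(0.2), mk(0.4))
  expect_equal(unname(w3), unname(weights_from_means(c(0.1, 0.2, 0.4))))
})

test_that("layer fusion is a convex combination bounded by its inputs", {
  set.seed(9)
  Sb <- rand_similarity(5); Sg <- rand_similarity(5); St <- rand_similarity(5)
  dimnames(Sg) <- dimnames(St) <- dimnames(Sb)
  w <- c(0.53, 0.32, 0.15)
  S <- fuse_layers(Sb, Sg, St, w)
  expect_equal(S[2, 3], 0.53 * Sb[2, 3] + 0.32 * Sg[2, 3] + 0.15 * St[2, 3])
  expect_true(all(S >= pmin(Sb, Sg, St) - 1e-12))
  expect_true(all(S <= pmax(Sb, Sg, St) + 1e-12))
  expect_equal(fuse_layers(Sb, Sg, St, c(1, 0, 0)), Sb)
  expect_equal(fuse_layers(Sb, Sb, Sb, w), Sb)
  # worked scalar: 0.53*0.2 + 0.32*0.5 + 0.15*0.8 = 0.386
  expect_equal(drop(c(0.53, 0.32, 0.15) %*% c(0.2, 0.5, 0.8)), 0.386)
})

test_that("every produced similarity matrix satisfies the type invariants", {
  set.seed(31)
  fps <- lapply(1:6, function(i) sort(sample(0:40, sample(0:8, 1))))
  names(fps) <- paste0("d", 1:6)
  mats <- list(tanimoto_similarity(fps))
  D <- matrix(sample(c(1:4, Inf), 36, replace = TRUE), 6, 6)
  D <- pmin(D, t(D)); diag(D) <- 0
  dimnames(D) <- list(names(fps), names(fps))
  mats <- c(mats, list(perlman_kernel(D, 0.3, 1)))
  for (S in mats) {
    expect_identical(S, t(S))
    expect_equal(diag(S), setNames(rep(1, 6), rownames(S)))
    expect_true(all(S >= 0 & S <= 1))
  }
})
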