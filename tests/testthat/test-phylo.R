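test_that("parse_newick reads tips and branch lengths back exactly", {
  t2 <- tree_2tip()
  expect_equal(length(t2$tip.label), 2)
  expect_equal(sort(t2$edge.length), c(1, 1))

  t3 <- tree_3tip()
  expect_equal(length(t3$tip.label), 3)
  D <- patristic_distances(t3)
  expect_equal(unname(D["A", "C"]), 4)  # root-to-A depth 2 + root-to-C 2
})

test_that("parse_newick rejects malformed input with a character position", {
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "unclosed")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("(A,B);"), "branch length")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
})

test_that("patristic distances match hand sums and a path-tracing oracle", {
  expect_equal(unname(patristic_distances(tree_2tip())["A", "B"]), 2)
  D3 <- patristic_distances(tree_3tip())
  expect_equal(unname(D3["A", "B"]), 2)
  expect_equal(unname(D3["A", "C"]), 4)

  tr <- generate_yule_tree(10, seed = 42)
  expect_equal(patristic_distances(tr), brute_patristic(tr), tolerance = 1e-12)
})

test_that("PVR eigenvectors have the required structure", {
  # 2 taxa: a single positive eigenvalue with a sign-symmetric vector
  b2 <- pvr_eigenvectors(patristic_distances(tree_2tip()))
  expect_equal(length(b2$values), 1)
  expect_equal(b2$vectors[1, 1], -b2$vectors[2, 1])

  # 3-taxon star: rotationally degenerate pair of equal eigenvalues
  b3 <- pvr_eigenvectors(patristic_distances(tree_star3()))
  expect_equal(length(b3$values), 2)
  expect_equal(b3$values[1], b3$values[2], tolerance = 1e-10)

  # columns orthonormal and centered (double-centering removes the mean)
  b <- pvr_eigenvectors(patristic_distances(tree_14()))
  G <- crossprod(b$vectors)
  expect_lt(max(abs(G - diag(ncol(b$vectors)))), 1e-8)
  expect_lt(max(abs(colSums(b$vectors))), 1e-10)
  expect_true(all(diff(b$values) <= 1e-12))
  expect_true(all(b$values > 0))

  bad <- patristic_distances(tree_3tip()); bad[1, 2] <- 99
  expect_error(pvr_eigenvectors(bad), "symmetric")
})

test_that("phylogenetic weight matrices are row-standardized", {
  W2 <- phylo_weight_matrix(patristic_distances(tree_2tip()))
  expect_equal(W2, matrix(c(0, 1, 1, 0), 2,
                          dimnames = list(c("A", "B"), c("A", "B"))))
  W3 <- phylo_weight_matrix(patristic_distances(tree_star3()))
  expect_true(all(abs(W3[upper.tri(W3)] - 0.5) < 1e-12))
  W <- phylo_weight_matrix(patristic_distances(tree_14()))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)

  D0 <- patristic_distances(tree_3tip()); D0[1, 2] <- D0[2, 1] <- 0
  expect_error(phylo_weight_matrix(D0), "identical taxa")
})

test_that("Moran's I equals the brute-force double sum", {
  set.seed(5)
  for (rep in 1:5) {
    tr <- generate_yule_tree(10)
    W <- phylo_weight_matrix(patristic_distances(tr))
    x <- rnorm(10)
    expect_equal(morans_i(x, W)$I, brute_moran(x, W), tolerance = 1e-12)
  }
})

test_that("Moran's I matches a hand summation on a 4-cycle", {
  W <- matrix(0, 4, 4)
  for (i in 1:4) {
    W[i, (i %% 4) + 1] <- 0.5
    W[i, ((i + 2) %% 4) + 1] <- 0.5
  }
  x <- c(1, -1, 1, -1)
  # all 8 nonzero terms are w z_i z_j = 0.5 * (1)(-1) = -0.5; S0 = 4
  expect_equal(morans_i(x, W)$I, (4 / 4) * (8 * -0.5) / 4)
  expect_equal(morans_i(x, W)$expected, -1 / 3)
  expect_error(morans_i(rep(1, 4), W), "zero variance")
})

test_that("permutation mean of Moran's I is -1/(n-1)", {
  tr <- tree_14()
  W <- phylo_weight_matrix(patristic_distances(tr))
  set.seed(7)
  x <- rnorm(14)
  Is <- replicate(10000, morans_i(sample(x), W)$I)
  se <- sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / 13)), 3 * se)
})

test_that("eigenvector selection handles the boundary cases", {
  b <- pvr_eigenvectors(patristic_distances(tree_14()))
  W <- phylo_weight_matrix(patristic_distances(tree_14()))

  # trait equal to the first eigenvector: perfect fit by {1}
  sel <- select_eigenvectors(b$vectors[, 1], b, W)
  expect_equal(sel$selected, 1L)
  expect_true(sel$zero_residual)

  # raw trait already below the threshold: empty selection
  set.seed(11)
  x <- rnorm(14)
  I0 <- morans_i(x - mean(x), W)$I
  sel0 <- select_eigenvectors(x, b, W, threshold = I0 + 0.01)
  expect_equal(length(sel0$selected), 0)
  expect_equal(sel0$residual_moran, I0)
})

test_that("greedy selection agrees with exhaustive search at small sizes", {
  tr <- tree_14()
  b <- pvr_eigenvectors(patristic_distances(tr))
  W <- phylo_weight_matrix(patristic_distances(tr))
  m <- ncol(b$vectors)
  thr <- 0.06

  resid_I <- function(idx, y) {
    r <- if (length(idx) == 0) y - mean(y) else
      lm.fit(cbind(1, b$vectors[, idx, drop = FALSE]), y)$residuals
    morans_i(r, W)$I
  }
  checked <- 0
  for (s in 1:12) {
    y <- simulate_bm(tr, sigma2 = 1, seed = 100 + s)
    sel <- select_eigenvectors(y, b, W, threshold = thr)
    if (length(sel$selected) == 0) {
      expect_gte(resid_I(integer(0), y), -Inf)  # trivially consistent
      checked <- checked + 1
    } else if (length(sel$selected) == 1) {
      # exhaustive: no empty solution existed, and greedy took the best single
      expect_gte(resid_I(integer(0), y), thr)
      singles <- vapply(1:m, function(j) resid_I(j, y), numeric(1))
      expect_equal(sel$selected, which.min(singles))
      checked <- checked + 1
    } else if (length(sel$selected) == 2) {
      expect_lt(sel$residual_moran, thr)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 6)
})

test_that("PSR curve is exact for a perfect first-vector trait", {
  b <- pvr_eigenvectors(patristic_distances(tree_14()))
  p <- psr_curve(b$vectors[, 1], b)
  expect_true(all(abs(p$r_squared - 1) < 1e-10))
  expect_equal(p$mean_deviation, mean(1 - p$cum_eigenvalue_fraction))
  expect_gt(p$mean_deviation, 0)
  expect_equal(p$cum_eigenvalue_fraction[length(p$cum_eigenvalue_fraction)], 1)
  expect_error(psr_curve(rep(1, 14), b), "constant")
})

test_that("PSR R-squared is non-decreasing and matches sequential OLS", {
  tr <- tree_14()
  b <- pvr_eigenvectors(patristic_distances(tr))
  y <- simulate_bm(tr, sigma2 = 1, seed = 3)
  p <- psr_curve(y, b)
  expect_true(all(diff(p$r_squared) >= -1e-12))
  # independent sequential lm oracle
  r2_lm <- vapply(seq_along(b$values), function(k) {
    summary(lm(y ~ b$vectors[, 1:k, drop = FALSE]))$r.squared
  }, numeric(1))
  expect_equal(p$r_squared, r2_lm, tolerance = 1e-10)
})

test_that("Brownian simulation matches its closed-form moments", {
  tr <- tree_3tip()  # depths: A,B = 2; C = 2; shared(A,B) = 1
  X <- simulate_bm(tr, sigma2 = 2, root_value = 5, seed = 1, nsim = 20000)
  expect_equal(unname(apply(X, 1, var)), c(4, 4, 4), tolerance = 0.05)
  expect_equal(cov(X["A", ], X["B", ]), 2 * 1, tolerance = 0.06)
  expect_lt(abs(cov(X["A", ], X["C", ])), 0.1)
  expect_equal(unname(rowMeans(X)), c(5, 5, 5), tolerance = 0.05)

  # near-zero rate collapses to the root value
  x0 <- simulate_bm(tr, sigma2 = 1e-18, root_value = 3, seed = 2)
  expect_equal(unname(x0), c(3, 3, 3), tolerance = 1e-6)
  expect_error(simulate_bm(tr, sigma2 = 0), "sigma2")

  # seeded reproducibility
  expect_identical(simulate_bm(tr, seed = 9), simulate_bm(tr, seed = 9))
})

test_that("species scores broadcast to specimens", {
  scores <- c(A = 0.5, B = -0.2)
  expect_equal(assign_species_scores(c("A", "A", "A"), scores), rep(0.5, 3))
  expect_equal(assign_species_scores(character(0), scores), numeric(0))
  mixed <- c("A", "B", "A", "B", "B")
  expect_equal(assign_species_scores(mixed, scores),
               vapply(mixed, function(s) scores[[s]], numeric(1), USE.NAMES = FALSE))
  expect_error(assign_species_scores(c("A", "Z"), scores), "Z")
})
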