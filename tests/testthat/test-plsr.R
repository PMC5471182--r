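test_that("design encoding standardizes, expands factors, stores constants", {
  df <- data.frame(hab = c(120, 140, 160, 180), lat = c(20, 25, 30, 35),
                   coll = c("m1", "m2", "m1", "m2"),
                   orig = c("field", "museum", "museum", "museum"))
  d <- encode_design(df, log_continuous = "hab", continuous = "lat",
                     factors = c("coll", "orig"),
                     groups = c(hab = "habitat", lat = "geography",
                                coll = "origin", orig = "origin"))
  expect_equal(ncol(d$X), 4)  # hab, lat, 1 indicator each for 2-level factors
  expect_lt(max(abs(colMeans(d$X))), 1e-12)
  expect_equal(unname(apply(d$X, 2, sd)), rep(1, 4))
  expect_equal(d$col_groups, c("habitat", "geography", "origin", "origin"))

  # independent column-builder oracle for the continuous part
  lh <- log10(df$hab)
  expect_equal(unname(d$X[, "hab"]), (lh - mean(lh)) / sd(lh))
  # raw values reconstructible from the stored constants
  expect_equal(unname(d$X[, "lat"] * d$scale["lat"] + d$center["lat"]), df$lat)

  expect_warning(encode_design(data.frame(a = c(1, 2), f = c("x", "x")),
                               continuous = "a", factors = "f"), "single level")
  expect_error(encode_design(data.frame(a = c(1, NA)), continuous = "a"),
               "rows: 2")
  expect_error(encode_design(df, continuous = "nope"), "not found")
})

test_that("PLSR equals OLS at full rank and the standardized slope at p=q=1", {
  d <- rand_xy(40, 1, 1, seed = 41)
  f1 <- fit_plsr(d$X, d$Y, A = 1)
  ols <- unname(coef(lm(d$Y ~ d$X))[2])
  expect_equal(as.numeric(f1$beta), ols, tolerance = 1e-10)

  d2 <- rand_xy(50, 5, 3, seed = 43)
  f5 <- fit_plsr(d2$X, d2$Y, A = 5)
  beta_ols <- solve(crossprod(d2$X), crossprod(d2$X, d2$Y))
  expect_lt(max(abs(f5$beta - beta_ols)), 1e-6)

  expect_error(fit_plsr(d2$X, d2$Y, A = 6), "rank")
})

test_that("PLSR structural invariants hold", {
  d <- rand_xy(60, 6, 2, seed = 47)
  f <- fit_plsr(d$X, d$Y, A = 4)
  # orthogonal scores, unit-norm weights
  TtT <- crossprod(f$scores)
  expect_lt(max(abs(TtT - diag(diag(TtT)))), 1e-8)
  expect_equal(unname(sqrt(colSums(f$W^2))), rep(1, 4), tolerance = 1e-10)
  # explained variance non-decreasing cumulative, bounded by 100
  expect_true(all(diff(f$explained_cum) >= -1e-10))
  expect_lte(f$explained_cum[4], 100 + 1e-10)

  # first PLS1 weight proportional to X'y
  y <- d$Y[, 1]
  f1 <- fit_plsr(d$X, y, A = 2)
  w_expected <- crossprod(d$X, y)
  w_expected <- w_expected / sqrt(sum(w_expected^2))
  expect_lt(max(abs(abs(f1$W[, 1]) - abs(w_expected))), 1e-8)

  # Y orthogonal to the X column space: nothing explained
  set.seed(49)
  X <- scale(matrix(rnorm(30 * 3), 30))
  noise <- rnorm(30)
  y_orth <- residuals(lm(noise ~ X))
  f0 <- fit_plsr(X, scale(y_orth), A = 3)
  expect_lt(f0$explained_cum[3], 1e-8)
})

test_that("PLSR predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  d <- rand_xy(45, 6, 3, seed = 53)
  colnames(d$X) <- paste0("x", 1:6); colnames(d$Y) <- paste0("y", 1:3)
  f <- fit_plsr(d$X, d$Y, A = 2)
  m <- mixOmics::pls(d$X, d$Y, ncomp = 2, mode = "regression", scale = FALSE)
  pred <- predict(m, d$X)$predict[, , 2]
  expect_equal(unname(d$X %*% f$beta), unname(pred), tolerance = 1e-6)
})

test_that("Q2 cross-validation detects signal and matches a LOO oracle", {
  set.seed(59)
  n <- 80; p <- 5
  X <- scale(matrix(rnorm(n * p), n))
  w <- rnorm(p)
  y <- scale(X %*% w + rnorm(n, 0, 0.3))
  cv <- cross_validate_q2(X, y, A_max = 3, folds = 10, seed = 2)
  expect_gt(cv$q2[1], 0.9)
  expect_gte(cv$A, 1)

  # leave-one-out PRESS equals an exhaustive refit loop
  n2 <- 16
  X2 <- scale(matrix(rnorm(n2 * 3), n2))
  y2 <- scale(X2 %*% c(1, -1, 0.5) + rnorm(n2, 0, 0.5))
  cv2 <- cross_validate_q2(X2, y2, A_max = 2, folds = n2, seed = 3)
  press <- c(0, 0)
  for (i in seq_len(n2)) {
    for (a in 1:2) {
      fi <- fit_plsr(X2[-i, , drop = FALSE], y2[-i, , drop = FALSE], A = a)
      press[a] <- press[a] + (y2[i] - X2[i, , drop = FALSE] %*% fi$beta)^2
    }
  }
  expect_equal(cv2$press, press, tolerance = 1e-8)
  expect_equal(cv2$q2, 1 - press / cv2$rss[1:2], tolerance = 1e-8)
})

test_that("variable importance shares are variance-weighted squared weights", {
  d <- rand_xy(50, 1, 1, seed = 61)
  f1 <- fit_plsr(d$X, d$Y, A = 1)
  v1 <- variable_importance(f1)
  expect_equal(v1$share, 1)
  expect_true(v1$important)

  # two orthogonal, equally informative predictors
  set.seed(63)
  x1 <- scale(rnorm(200)); x2 <- scale(residuals(lm(rnorm(200) ~ x1)))
  y <- scale(x1 + x2)
  f2 <- fit_plsr(cbind(x1, x2), y, A = 2)
  v2 <- variable_importance(f2)
  expect_equal(v2$share, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(v2$share), 1, tolerance = 1e-9)

  # direct recomputation from W and per-component explained variance
  d3 <- rand_xy(60, 4, 2, seed = 67)
  f3 <- fit_plsr(d3$X, d3$Y, A = 3)
  v3 <- variable_importance(f3)
  manual <- (f3$W^2) %*% (f3$explained / sum(f3$explained))
  expect_equal(v3$share, as.numeric(manual), tolerance = 1e-12)
  expect_equal(v3$important, v3$share > 0.05)
})

test_that("bootstrap inference is seed-reproducible with sane uncertainty", {
  set.seed(71)
  n <- 200
  X <- scale(matrix(rnorm(n), n))
  y <- scale(0.5 * X[, 1] + rnorm(n, 0, 1))
  b1 <- bootstrap_coefficients(X, y, A = 1, B = 200, seed = 5)
  b2 <- bootstrap_coefficients(X, y, A = 1, B = 200, seed = 5)
  expect_identical(b1, b2)

  # analytic OLS slope SE oracle at full rank
  fit <- lm(y ~ X)
  se_ols <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(b1$se[1, 1] - se_ols) / se_ols, 0.2)

  # degenerate identity problem: essentially zero uncertainty
  Xi <- scale(matrix(rnorm(100), 100))
  bi <- bootstrap_coefficients(Xi, Xi, A = 1, B = 100, seed = 6)
  expect_lt(bi$se[1, 1], 1e-10)
  expect_lt(bi$p[1, 1], 1e-10)
  expect_error(bootstrap_coefficients(X, y, A = 1, B = 50), "B must be")
})
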