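#' Encode a specimen design matrix for PLSR
#'
#' Builds the predictor (or response) matrix: continuous columns optionally
#' `log10`-transformed, then centered and scaled by their sample standard
#' deviation; factor columns expanded to treatment-coded indicators (first
#' level dropped). Indicator columns are centered/scaled like the rest so
#' every column enters the PLS on a comparable footing. The centering and
#' scaling constants are stored so raw values can be reconstructed.
#'
#' @param data data.frame holding the named columns.
#' @param log_continuous Character: columns to log10-transform then
#'   standardize (must be positive).
#' @param continuous Character: columns to standardize as-is.
#' @param factors Character: factor columns to expand. Single-level factors
#'   are dropped with a warning.
#' @param groups Optional named character vector mapping each source column
#'   to a predictor block label (e.g. "habitat", "geography", "origin",
#'   "phylogeny") used by [variance_partition()].
#' @return Object of class `design_matrix`: `X`, `center`, `scale`,
#'   `col_groups`, `source_column`.
#' @export
encode_design <- function(data, log_continuous = character(),
                          continuous = character(), factors = character(),
                          groups = NULL) {
  data <- as.data.frame(data)
  all_cols <- c(log_continuous, continuous, factors)
  missing_cols <- setdiff(all_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in c(log_continuous, continuous)) {
    bad <- which(!is.finite(data[[cl]]))
    if (length(bad) > 0) {
      stop("missing values in '", cl, "' at rows: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  cols <- list(); src <- character()
  for (cl in log_continuous) {
    if (any(data[[cl]] <= 0)) stop("'", cl, "' must be positive for log10", call. = FALSE)
    cols[[cl]] <- log10(data[[cl]]); src <- c(src, cl)
  }
  for (cl in continuous) {
    cols[[cl]] <- data[[cl]]; src <- c(src, cl)
  }
  for (cl in factors) {
    f <- factor(data[[cl]])
    if (anyNA(f)) stop("missing values in factor '", cl, "'", call. = FALSE)
    if (nlevels(f) < 2) {
      warning("factor '", cl, "' has a single level and was dropped")
      next
    }
    mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cl, "_", levels(f)[-1])
    for (j in seq_len(ncol(mm))) {
      cols[[colnames(mm)[j]]] <- mm[, j]; src <- c(src, cl)
    }
  }
  if (length(cols) == 0) stop("empty design", call. = FALSE)
  X <- do.call(cbind, cols)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance columns: ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- scale(X, center = ctr, scale = scl)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  col_groups <- if (is.null(groups)) src else unname(groups[src])
  structure(
    list(X = Xs, center = ctr, scale = scl,
         col_groups = col_groups, source_column = src),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "rows x", ncol(x$X), "columns\n")
  cat("  ", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

.as_design <- function(X) {
  if (inherits(X, "design_matrix")) X$X else as.matrix(X)
}

#' Fit a partial least squares regression (NIPALS)
#'
#' PLS1/PLS2 by NIPALS with deflation of both blocks; for a single response
#' the component is closed-form (no inner iteration). Coefficients on the
#' standardized scale are recovered as `beta = W (P'W)^{-1} C'`, and the
#' per-component explained response variance comes from the drop in the
#' residual Y sum of squares under deflation. Inputs are expected centered
#' and scaled (see [encode_design()]); set `scale = TRUE` to have raw
#' matrices standardized internally.
#'
#' @param X n x p predictor matrix or `design_matrix`.
#' @param Y n x q response matrix (a vector is treated as one column) or
#'   `design_matrix`.
#' @param A Number of components (must not exceed the rank of X).
#' @param scale Standardize X and Y internally.
#' @param tol NIPALS convergence tolerance.
#' @param max_iter Inner-loop iteration cap (error on non-convergence).
#' @return Object of class `plsr_fit` with elements `W`, `scores` (T), `P`,
#'   `C`, `U`, `beta`, `explained` (per-component % of Y variance),
#'   `explained_cum`, `A`, and the dimension names.
#' @export
fit_plsr <- function(X, Y, A, scale = FALSE, tol = 1e-10, max_iter = 500) {
  X <- .as_design(X)
  Y <- .as_design(if (is.null(dim(Y))) matrix(Y, ncol = 1) else Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  if (scale) {
    X <- base::scale(X); Y <- base::scale(Y)
  }
  rk <- qr(X)$rank
  if (A > rk) stop("A = ", A, " exceeds rank(X) = ", rk, call. = FALSE)
  if (nrow(X) <= A) stop("need n > A", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  f <- nipals_fit(X, Y, as.integer(A), tol, as.integer(max_iter))
  expl <- -diff(f$ss_y) / f$ss_y[1] * 100
  dimnames(f$beta) <- list(colnames(X), colnames(Y))
  rownames(f$W) <- rownames(f$P) <- colnames(X)
  rownames(f$C) <- colnames(Y)
  structure(
    list(W = f$W, scores = f$T, P = f$P, C = f$C, U = f$U, beta = f$beta,
         explained = expl, explained_cum = cumsum(expl), A = A,
         predictors = colnames(X), responses = colnames(Y)),
    class = "plsr_fit"
  )
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR fit (NIPALS): %d predictors, %d responses, %d component(s)\n",
              length(x$predictors), length(x$responses), x$A))
  cat(sprintf("  explained Y variance: %s %% (cumulative %.1f %%)\n",
              paste(sprintf("%.1f", x$explained), collapse = " + "),
              x$explained_cum[x$A]))
  invisible(x)
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  .as_design(newdata) %*% object$beta
}

#' Q2 cross-validation for PLSR component selection
#'
#' SIMCA-style predictive relevance: `Q2(a) = 1 - PRESS(a) / RSS(a-1)`,
#' where `PRESS(a)` sums squared fold-held-out prediction errors of the
#' a-component model and `RSS(a-1)` is the training residual sum of squares
#' of the previous model (`RSS(0)` = total Y sum of squares). Components are
#' retained sequentially while `Q2(a) >= threshold`; the first failing
#' component stops the scan.
#'
#' @param X,Y Standardized matrices (or `design_matrix` objects).
#' @param A_max Largest component count to examine.
#' @param folds Number of cross-validation folds.
#' @param seed Optional seed for the fold shuffle.
#' @param threshold Retention threshold (default 0.0975, the conventional
#'   significance limit).
#' @param stratify Optional factor; folds are allocated within its levels
#'   (e.g. species) so each fold sees every stratum.
#' @return List `q2` (per component), `press`, `rss`, `A` (selected count,
#'   0 if the first component already fails), `folds`.
#' @export
cross_validate_q2 <- function(X, Y, A_max, folds = 10, seed = NULL,
                              threshold = 0.0975, stratify = NULL) {
  X <- .as_design(X)
  Y <- .as_design(if (is.null(dim(Y))) matrix(Y, ncol = 1) else Y)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A_max <- min(A_max, ncol(X), n - ceiling(n / folds) - 1)
  assign_folds <- function() {
    if (is.null(stratify)) {
      sample(rep(seq_len(folds), length.out = n))
    } else {
      fld <- integer(n)
      for (lv in split(seq_len(n), stratify)) {
        fld[lv] <- sample(rep(seq_len(folds), length.out = length(lv)))
      }
      fld
    }
  }
  # a training fold is degenerate when its response block loses all
  # variance (Q2 undefined); predictor columns constant within a fold are
  # tolerated because standardization happens once, globally
  ok_folds <- function(fld) {
    all(vapply(seq_len(folds), function(k) {
      tr <- Y[fld != k, , drop = FALSE]
      nrow(tr) > A_max && all(apply(tr, 2, stats::sd) > 0)
    }, logical(1)))
  }
  fld <- assign_folds()
  if (!ok_folds(fld)) {
    fld <- assign_folds()
    if (!ok_folds(fld)) stop("zero-variance training fold after reshuffle", call. = FALSE)
  }
  press <- matrix(0, A_max, 1)
  for (k in seq_len(folds)) {
    test <- fld == k
    preds <- nipals_cv_predict(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                               X[test, , drop = FALSE], as.integer(A_max),
                               1e-10, 500L)
    for (a in seq_len(A_max)) {
      press[a] <- press[a] + sum((Y[test, , drop = FALSE] - preds[[a]])^2)
    }
  }
  full <- nipals_fit(X, Y, as.integer(A_max), 1e-10, 500L)
  rss <- full$ss_y  # rss[a + 1] = RSS after a components; rss[1] = SS(Y)
  q2 <- 1 - press[, 1] / rss[seq_len(A_max)]
  A_sel <- 0L
  for (a in seq_len(A_max)) {
    if (q2[a] >= threshold) A_sel <- a else break
  }
  list(q2 = q2, press = press[, 1], rss = rss, A = A_sel, folds = fld)
}

#' Variable importance from squared PLS weights
#'
#' Share of the explained response variance attributed to predictor j:
#' `share_j = sum_a w_ja^2 EV_a / sum_a EV_a`, with `EV_a` the response
#' variance explained by component a. With one component this is simply the
#' squared weight. Predictors with share > 5% are flagged important.
#'
#' @param fit A `plsr_fit`.
#' @param cutoff Importance cutoff on the share scale (default 0.05).
#' @return data.frame `predictor`, `share`, `important`; shares sum to 1.
#' @export
variable_importance <- function(fit, cutoff = 0.05) {
  if (!inherits(fit, "plsr_fit")) stop("need a fitted plsr_fit", call. = FALSE)
  ev <- fit$explained
  share <- as.numeric((fit$W^2) %*% (ev / sum(ev)))
  data.frame(predictor = fit$predictors, share = share,
             important = share > cutoff, row.names = NULL)
}

#' Bootstrap inference for PLSR coefficients
#'
#' Case resampling of rows with replacement, refitting with the component
#' count held fixed; the coefficient standard error is the standard
#' deviation over replicates and the two-sided p-value comes from the
#' normal approximation `beta / se`. Percentile 95% intervals are also
#' returned. Replicates whose resampled predictor block collapses below
#' rank A (or loses all variance in a column) are redrawn, at most 10 times
#' each.
#'
#' @param X,Y Standardized matrices (or `design_matrix` objects).
#' @param A Components (held fixed across replicates).
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Optional seed.
#' @return Object of class `bootstrap_result`: `B`, `beta`, `se`, `p`,
#'   `ci_lower`, `ci_upper` (all p x q).
#' @export
bootstrap_coefficients <- function(X, Y, A, B = 1000, seed = NULL) {
  X <- .as_design(X)
  Y <- .as_design(if (is.null(dim(Y))) matrix(Y, ncol = 1) else Y)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  draw_ok <- function() {
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (qr(X[idx, , drop = FALSE])$rank >= A) return(idx)
    }
    stop("bootstrap replicate rank-deficient after 10 redraws", call. = FALSE)
  }
  idx <- vapply(seq_len(B), function(b) draw_ok(), integer(n))
  betas <- nipals_boot(X, Y, idx, as.integer(A), 1e-10, 500L)
  full <- fit_plsr(X, Y, A)
  p <- ncol(X); q <- ncol(Y)
  se <- matrix(apply(betas, 1, stats::sd), p, q)
  lo <- matrix(apply(betas, 1, stats::quantile, probs = 0.025), p, q)
  hi <- matrix(apply(betas, 1, stats::quantile, probs = 0.975), p, q)
  z <- full$beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  pv[se == 0] <- ifelse(full$beta[se == 0] == 0, 1, 0)
  dimnames(se) <- dimnames(lo) <- dimnames(hi) <- dimnames(pv) <- dimnames(full$beta)
  structure(list(B = B, beta = full$beta, se = se, p = pv,
                 ci_lower = lo, ci_upper = hi),
            class = "bootstrap_result")
}

# column SDs without extra dependencies
.col_sds <- function(m) {
  apply(m, 2, stats::sd)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (%d replicates): beta (+/- se)\n", x$B))
  for (j in seq_len(ncol(x$beta))) {
    cat(" ", colnames(x$beta)[j] %||% paste0("Y", j), ":\n")
    for (i in seq_len(nrow(x$beta))) {
      cat(sprintf("    %-24s %+.3f (+/-%.3f)  p = %.3g\n",
                  rownames(x$beta)[i] %||% paste0("X", i),
                  x$beta[i, j], x$se[i, j], x$p[i, j]))
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
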