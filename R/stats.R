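#' Intraclass correlation repeatability from one-way ANOVA
#'
#' One-way consistency ICC from the between- and within-group mean squares,
#' `tau = (MSB - MSW) / (MSB + (k - 1) MSW)`, with `F = MSB / MSW` and its
#' p-value. Used for repeatability of duplicated colour measurements
#' (re-sampled photo patches; period-split habitat extractions), so the
#' design must be balanced with `k` measurements per group.
#'
#' @param m Numeric g x k matrix: one row per group (specimen / point), one
#'   column per repeated measurement.
#' @return Object of class `icc_result`: `tau`, `df_between`, `df_within`,
#'   `F`, `p`.
#' @export
icc <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("unbalanced design: missing measurements", call. = FALSE)
  g <- nrow(m); k <- ncol(m)
  if (g < 2 || k < 2) stop("need >= 2 groups and >= 2 measurements per group", call. = FALSE)
  grand <- mean(m)
  group_means <- rowMeans(m)
  msb <- k * sum((group_means - grand)^2) / (g - 1)
  msw <- sum((m - group_means)^2) / (g * (k - 1))
  if (msw == 0) {
    tau <- 1; f <- Inf; p <- 0
  } else {
    tau <- (msb - msw) / (msb + (k - 1) * msw)
    f <- msb / msw
    p <- stats::pf(f, g - 1, g * (k - 1), lower.tail = FALSE)
  }
  structure(list(tau = tau, df_between = g - 1L, df_within = g * (k - 1L),
                 F = f, p = p),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC repeatability: tau = %.4f (F = %.2f, df = %d/%d, p = %.3g)\n",
              x$tau, x$F, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' Species effect ANOVA with covariates entered first
#'
#' Sequential (Type-I) linear-model ANOVA for the species effect on a trait,
#' with optional nuisance factors (e.g. collection/field origin) entered
#' before species, matching an "accounting for origin" design:
#' `F = (dRSS / ddf) / (RSS_full / df_resid)`.
#'
#' @param trait Numeric response per specimen.
#' @param species Factor (or coercible) of species labels.
#' @param covariates Optional data.frame of covariates entered first.
#' @return Object of class `anova_result`: `F`, `df_effect`, `df_resid`, `p`.
#' @export
anova_species <- function(trait, species, covariates = NULL) {
  species <- factor(species)
  if (nlevels(species) < 2) stop("need >= 2 species", call. = FALSE)
  if (stats::var(trait) == 0) {
    return(structure(list(F = 0, df_effect = nlevels(species) - 1L,
                          df_resid = length(trait) - nlevels(species),
                          p = 1), class = "anova_result"))
  }
  dat <- data.frame(.trait = trait, .species = species)
  rhs <- ".species"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(names(covariates), ".species"), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".trait ~", rhs)), data = dat)
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased) > 0) {
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  tab <- stats::anova(fit)
  i <- which(rownames(tab) == ".species")
  f <- tab$`F value`[i]
  if (is.nan(f)) f <- 0  # zero residual variance and zero effect SS
  structure(list(F = f, df_effect = tab$Df[i],
                 df_resid = tab$Df[nrow(tab)],
                 p = tab$`Pr(>F)`[i]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("species ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_effect, x$df_resid, x$F, x$p))
  invisible(x)
}

#' OLS residuals of a response on a predictor block
#'
#' Residuals from an intercept-included least-squares fit; factor columns
#' are expanded to indicators. Aliased columns are dropped with a warning.
#' With an empty predictor block this is simple mean-centering.
#'
#' @param y Numeric response.
#' @param X Optional data.frame / matrix of predictors.
#' @return Numeric residual vector (mean zero).
#' @export
residualize <- function(y, X = NULL) {
  if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0)) {
    return(y - mean(y))
  }
  X <- as.data.frame(X)
  mm <- stats::model.matrix(~ ., data = X)
  fit <- stats::lm.fit(mm, y)
  if (any(is.na(fit$coefficients))) {
    warning("dropping aliased predictor columns: ",
            paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", "))
  }
  unname(fit$residuals)
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after removing a
#' covariate block `Z` (e.g. museum vs field origin), with the t-based
#' p-value on `n - 2 - q` degrees of freedom, `q` the number of covariate
#' columns after expansion.
#'
#' @param x,y Numeric vectors.
#' @param Z Optional covariate data.frame.
#' @return List with `r`, `p`, `df`.
#' @export
partial_pearson <- function(x, y, Z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(Z)) 0L else ncol(stats::model.matrix(~ ., data = as.data.frame(Z))) - 1L
  if (n <= q + 2) stop("too few observations for the covariate block", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  rx <- residualize(x, Z)
  ry <- residualize(y, Z)
  if (stats::var(rx) <= 1e-14 * stats::var(x) ||
      stats::var(ry) <= 1e-14 * stats::var(y)) {
    stop("zero residual variance", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - q
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df)
}
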