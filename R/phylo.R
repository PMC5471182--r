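#' Parse a Newick tree with mandatory branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]. The comparative methods
#' in this package (patristic distances, eigenvector extraction, Brownian
#' simulation) are meaningless without branch lengths, so trees lacking them
#' are rejected rather than defaulted.
#'
#' @param text Newick string (used if `file` is missing).
#' @param file Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text, file = NULL) {
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable tree string", call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; branch lengths are mandatory", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tree
}

# Cheap structural scan so that malformed strings fail with a character
# position instead of an opaque downstream error.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unbalanced ')' at character %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf("malformed Newick: missing terminal ';' at character %d",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips, in tip
#' label order.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  .check_tree(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  invisible(TRUE)
}

.check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (any(D < 0)) stop("distance matrix has negative entries", call. = FALSE)
  invisible(TRUE)
}

#' Phylogenetic eigenvector extraction (PVR)
#'
#' Double-centers the patristic distance matrix, `G = -1/2 J D J` with
#' `J = I - 11'/n`, and eigendecomposes `G`. For tips at depths `t_i` with
#' shared path length `C_ij`, `d_ij = t_i + t_j - 2 C_ij`, so `-1/2 J D J`
#' equals the double-centered Brownian covariance `J C J`; the retained
#' eigenvectors are the principal axes of trait divergence expected under
#' Brownian motion, which is what gives the signal-representation curve its
#' 1:1 Brownian reference line (see [psr_curve()]). Gower centering of
#' squared distances is available via `squared = TRUE` for comparison with
#' classical PCoA output.
#'
#' Eigenvectors with eigenvalue below `tol * max(eigenvalue)` (and all
#' negative ones) are dropped; the number discarded is kept in the result.
#' Signs are fixed so the first non-negligible entry of each column is
#' positive, making outputs reproducible across platforms.
#'
#' @param D Patristic distance matrix (see [patristic_distances()]).
#' @param squared Double-center squared distances instead of raw ones.
#' @param tol Relative eigenvalue cutoff.
#' @return Object of class `pvr_basis`: list with `taxa`, `vectors` (n x m,
#'   orthonormal columns), `values` (descending, positive), `n_dropped`.
#' @export
pvr_eigenvectors <- function(D, squared = FALSE, tol = 1e-10) {
  .check_dist(D)
  n <- nrow(D)
  M <- if (squared) D^2 else D
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * (J %*% M %*% J)
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  vectors <- e$vectors[, keep, drop = FALSE]
  # sign convention: first entry with |v| > 1e-8 positive
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    lead <- which(abs(v) > 1e-8)[1]
    if (!is.na(lead) && v[lead] < 0) vectors[, j] <- -v
  }
  rownames(vectors) <- rownames(D)
  colnames(vectors) <- paste0("EV", seq_len(ncol(vectors)))
  structure(
    list(taxa = rownames(D), vectors = vectors, values = e$values[keep],
         n_dropped = sum(!keep), squared = squared),
    class = "pvr_basis"
  )
}

#' @export
print.pvr_basis <- function(x, ...) {
  cat("Phylogenetic eigenvector basis (PVR)\n")
  cat("  taxa:", length(x$taxa), "  eigenvectors retained:", ncol(x$vectors),
      "  dropped:", x$n_dropped, "\n")
  cat("  eigenvalue fractions:",
      paste(sprintf("%.3f", x$values / sum(x$values))[seq_len(min(5, length(x$values)))],
            collapse = " "), "...\n")
  invisible(x)
}

#' Phylogenetic proximity weight matrix for Moran's I
#'
#' Off-diagonal weights from patristic distances, row-standardized to sum
#' to one. `"inverse"` (the default, the dominant convention in phylogenetic
#' autocorrelation) uses `1/d`, `"inverse-squared"` uses `1/d^2`, and
#' `"binary-nn"` gives each taxon weight only on its nearest neighbour(s).
#'
#' @param D Patristic distance matrix.
#' @param type Weighting scheme.
#' @return Row-standardized weight matrix with zero diagonal.
#' @export
phylo_weight_matrix <- function(D, type = c("inverse", "inverse-squared", "binary-nn")) {
  .check_dist(D)
  type <- match.arg(type)
  n <- nrow(D)
  off <- D[upper.tri(D)]
  if (any(off == 0)) stop("zero off-diagonal distance: identical taxa in tree", call. = FALSE)
  W <- switch(type,
    "inverse" = 1 / D,
    "inverse-squared" = 1 / D^2,
    "binary-nn" = {
      B <- matrix(0, n, n)
      for (i in seq_len(n)) {
        d <- D[i, ]; d[i] <- Inf
        B[i, d == min(d)] <- 1
      }
      B
    })
  diag(W) <- 0
  W <- W / rowSums(W)
  dimnames(W) <- dimnames(D)
  W
}

#' Moran's I autocorrelation with phylogenetic weights
#'
#' Computes `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)`, its null expectation `-1/(n-1)`, the variance under
#' the normality assumption, and a two-sided p-value from the normal
#' approximation (delegated to [ape::Moran.I()]).
#'
#' @param values Numeric trait vector, one value per taxon.
#' @param W Weight matrix from [phylo_weight_matrix()].
#' @return Object of class `moran_result`: list `I`, `expected`, `variance`, `p`.
#' @export
morans_i <- function(values, W) {
  n <- length(values)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!is.matrix(W) || any(dim(W) != n)) stop("W must be an n x n matrix", call. = FALSE)
  if (stats::var(values) == 0) stop("zero variance: Moran's I undefined for constant values", call. = FALSE)
  m <- suppressWarnings(
    ape::Moran.I(values, weight = W, scaled = FALSE, alternative = "two.sided")
  )
  # at very small n the normality variance estimate can fail; the statistic
  # itself is still well-defined
  v <- if (is.finite(m$sd)) m$sd^2 else NA_real_
  structure(
    list(I = m$observed, expected = m$expected, variance = v,
         p = if (is.finite(m$p.value)) m$p.value else NA_real_),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f), p = %.4g\n",
              x$I, x$expected, sqrt(x$variance), x$p))
  invisible(x)
}

#' Greedy Moran's I eigenvector selection
#'
#' Starting from the raw trait, repeatedly regresses the trait on the
#' currently selected eigenvectors and computes Moran's I of the residuals;
#' if `I < threshold` the loop stops, otherwise the unselected eigenvector
#' whose inclusion most reduces residual I is added (ties broken by lower
#' column index). Deterministic given its inputs.
#'
#' @param trait Numeric vector, one value per taxon (basis order).
#' @param basis A `pvr_basis`.
#' @param W Weight matrix for Moran's I.
#' @param threshold Stop once residual Moran's I falls below this
#'   (default 0.06).
#' @return List with `selected` (integer column indices, possibly empty),
#'   `residual_moran` (`NA` if residuals were degenerate), `threshold_met`,
#'   and `zero_residual` (perfect fit reached).
#' @export
select_eigenvectors <- function(trait, basis, W, threshold = 0.06) {
  stopifnot(inherits(basis, "pvr_basis"))
  V <- basis$vectors
  n <- nrow(V)
  if (length(trait) != n) stop("trait length does not match basis taxa", call. = FALSE)
  selected <- integer(0)
  repeat {
    res <- if (length(selected) == 0) {
      trait - mean(trait)
    } else {
      stats::lm.fit(cbind(1, V[, selected, drop = FALSE]), trait)$residuals
    }
    if (stats::var(res) < 1e-12 * max(1, stats::var(trait))) {
      return(list(selected = selected, residual_moran = NA_real_,
                  threshold_met = TRUE, zero_residual = TRUE))
    }
    I <- morans_i(res, W)$I
    if (I < threshold) {
      return(list(selected = selected, residual_moran = I,
                  threshold_met = TRUE, zero_residual = FALSE))
    }
    candidates <- setdiff(seq_len(ncol(V)), selected)
    if (length(candidates) == 0) {
      warning("Moran's I threshold not met after including all eigenvectors")
      return(list(selected = selected, residual_moran = I,
                  threshold_met = FALSE, zero_residual = FALSE))
    }
    cand_I <- vapply(candidates, function(j) {
      r <- stats::lm.fit(cbind(1, V[, c(selected, j), drop = FALSE]), trait)$residuals
      if (stats::var(r) < 1e-12 * max(1, stats::var(trait))) -Inf else morans_i(r, W)$I
    }, numeric(1))
    selected <- c(selected, candidates[which.min(cand_I)])
  }
}

#' Phylogenetic signal-representation (PSR) curve
#'
#' Sequential PVR models with an increasing number of eigenvectors (in
#' descending-eigenvalue order): for each k the OLS R-squared of the trait on
#' the first k eigenvectors is plotted against the cumulative relative
#' eigenvalue. Under Brownian motion the curve tracks the 1:1 line; traits
#' dominated by non-phylogenetic variation fall below it. `mean_deviation`
#' is the mean of `R^2(k) - cumfrac(k)` and `area_deviation` the trapezoid
#' area between the curve (anchored at the origin) and the 1:1 line.
#'
#' @param trait Numeric vector per taxon (basis order).
#' @param basis A `pvr_basis` with at least 2 eigenvectors.
#' @return Object of class `psr_curve`.
#' @export
psr_curve <- function(trait, basis) {
  stopifnot(inherits(basis, "pvr_basis"))
  V <- basis$vectors
  if (ncol(V) < 2) stop("need at least 2 eigenvectors", call. = FALSE)
  if (length(trait) != nrow(V)) stop("trait length does not match basis", call. = FALSE)
  if (stats::var(trait) == 0) stop("constant trait: R-squared undefined", call. = FALSE)
  z <- trait - mean(trait)
  # columns are orthonormal and centered, so sequential R^2 is a cumulative
  # sum of squared projections
  proj2 <- as.numeric(crossprod(V, z))^2
  r2 <- cumsum(proj2) / sum(z^2)
  r2 <- pmin(r2, 1)
  cumfrac <- cumsum(basis$values) / sum(basis$values)
  dev <- r2 - cumfrac
  x <- c(0, cumfrac); y <- c(0, r2)
  area <- sum(diff(x) * (utils::head(y - x, -1) + utils::tail(y - x, -1)) / 2)
  structure(
    list(cum_eigenvalue_fraction = cumfrac, r_squared = r2,
         mean_deviation = mean(dev), area_deviation = area),
    class = "psr_curve"
  )
}

#' @export
print.psr_curve <- function(x, ...) {
  cat("PSR curve over", length(x$r_squared), "eigenvectors\n")
  cat(sprintf("  mean deviation from 1:1 (Brownian) line: %+.4f\n", x$mean_deviation))
  cat(sprintf("  area deviation: %+.4f\n", x$area_deviation))
  invisible(x)
}

#' @export
plot.psr_curve <- function(x, ...) {
  plot(c(0, x$cum_eigenvalue_fraction), c(0, x$r_squared), type = "b",
       xlab = "cumulative eigenvalue fraction", ylab = expression(R^2),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Independent Gaussian increments per branch with variance
#' `sigma2 * branch length`, accumulated from the root.
#'
#' @param tree An [ape::phylo] tree.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @param nsim Number of replicate traits.
#' @return If `nsim = 1`, a named vector of tip values; otherwise an
#'   n_tips x nsim matrix.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL, nsim = 1) {
  .check_tree(tree)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  inc <- matrix(stats::rnorm(nrow(ord$edge) * nsim, 0,
                             rep(sqrt(sigma2 * ord$edge.length), nsim)),
                nrow(ord$edge), nsim)
  val <- matrix(NA_real_, n_node, nsim)
  val[n_tip + 1L, ] <- root_value
  # reverse postorder: parents before children
  for (e in rev(seq_len(nrow(ord$edge)))) {
    val[ord$edge[e, 2], ] <- val[ord$edge[e, 1], ] + inc[e, ]
  }
  tips <- val[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  if (nsim == 1) tips[, 1] else tips
}

#' Broadcast species-level scores to specimens
#'
#' @param species Character vector of species labels, one per specimen.
#' @param scores Named numeric vector of species-level values (e.g.
#'   eigenvector scores).
#' @return Numeric vector, one value per specimen.
#' @export
assign_species_scores <- function(species, scores) {
  stopifnot(!is.null(names(scores)))
  species <- as.character(species)
  missing <- setdiff(unique(species), names(scores))
  if (length(missing) > 0) {
    stop("species missing from scores: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(scores[species])
}
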