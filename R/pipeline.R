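#' Pipeline configuration
#'
#' Bundles inputs and tuning parameters for [run_full()]. `tree` and
#' `specimens` may be in-memory objects ([ape::phylo]; data.frame) or file
#' paths (Newick; CSV). The specimen table must carry `id`, `species`,
#' `latitude`, `longitude`, `origin`, `collection`, fur colour columns
#' `fur_red/green/blue/L` and habitat colour columns `hab_red/green/blue/L`;
#' optional duplicate-measurement columns (`fur_*_2`) and period-split
#' habitat columns (`hab_*_p1`, `hab_*_p2`) feed the repeatability section.
#'
#' @param tree Tree object or Newick path.
#' @param specimens Specimen data.frame or CSV path.
#' @param moran_threshold Moran's I stopping threshold for eigenvector
#'   selection (default 0.06).
#' @param moran_weights Weighting scheme for [phylo_weight_matrix()].
#' @param q2_threshold Q2 component-retention threshold.
#' @param bootstrap_B Bootstrap replicate count (>= 100).
#' @param per_species_min_n Minimum per-species sample size for a separate
#'   within-species model (default 21, i.e. species with n > 20).
#' @param folds Cross-validation folds.
#' @param a_max Largest candidate component count.
#' @param seed Integer seed governing fold shuffles and bootstraps.
#' @param out_dir Optional directory; when set, [run_full()] writes the
#'   report there.
#' @return List of class `run_config`.
#' @export
run_config <- function(tree, specimens, moran_threshold = 0.06,
                       moran_weights = "inverse", q2_threshold = 0.0975,
                       bootstrap_B = 1000, per_species_min_n = 21,
                       folds = 10, a_max = 5, seed = 1, out_dir = NULL) {
  stopifnot(moran_threshold > 0, q2_threshold > 0, bootstrap_B >= 100,
            per_species_min_n >= 2)
  structure(list(tree = tree, specimens = specimens,
                 moran_threshold = moran_threshold,
                 moran_weights = moran_weights,
                 q2_threshold = q2_threshold, bootstrap_B = bootstrap_B,
                 per_species_min_n = per_species_min_n, folds = folds,
                 a_max = a_max, seed = seed, out_dir = out_dir),
            class = "run_config")
}

# stable FNV-1a hash of the scalar configuration, carried on every table so
# outputs are traceable to the run that produced them
.config_hash <- function(config) {
  scalars <- config[!(names(config) %in% c("tree", "specimens", "out_dir"))]
  s <- paste(deparse(scalars), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

.traits <- c("red", "green", "blue", "L")

# fit one PLSR model end to end: Q2 selection, fit, importance, bootstrap
.fit_model <- function(X, Y, config, seed_offset, stratify = NULL,
                       bootstrap = TRUE) {
  folds <- min(config$folds, nrow(.as_design(X)))
  cv <- cross_validate_q2(X, Y, A_max = config$a_max, folds = folds,
                          seed = .derive_seed(config$seed, seed_offset),
                          threshold = config$q2_threshold, stratify = stratify)
  if (cv$A == 0) {
    return(list(significant = FALSE, q2 = cv$q2, A = 0L, fit = NULL,
                importance = NULL, bootstrap = NULL, component_r = NA_real_))
  }
  fit <- fit_plsr(X, Y, A = cv$A)
  imp <- variable_importance(fit)
  bt <- if (bootstrap) {
    bootstrap_coefficients(X, Y, A = cv$A, B = config$bootstrap_B,
                           seed = .derive_seed(config$seed, seed_offset + 1))
  }
  list(significant = TRUE, q2 = cv$q2, A = cv$A, fit = fit,
       importance = imp, bootstrap = bt,
       component_r = stats::cor(fit$scores[, 1], fit$U[, 1]))
}

#' Run the full colour-matching analysis
#'
#' End-to-end orchestration: repeatability (ICC) of duplicated fur and
#' period-split habitat measurements; species ANOVA per trait (collection
#' origin entered first); PVR eigenvector extraction, Moran's I eigenvector
#' selection and PSR curves on species-mean log colour traits; a global
#' multi-response PLSR plus four single-response PLSRs of fur on habitat,
#' geography, origin and selected eigenvector scores, with Q2 component
#' selection, squared-weight importance and bootstrap coefficient inference;
#' separate per-species PLSRs for well-sampled species; partial and
#' residual fur-habitat correlations; and a variance partition of the
#' global model into habitat / geography / origin / phylogeny blocks.
#' Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return Object of class `crypsis_report`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- config$tree
  if (is.character(tree)) tree <- parse_newick(file = tree)
  .check_tree(tree)
  spec <- config$specimens
  if (is.character(spec)) spec <- utils::read.csv(spec, stringsAsFactors = FALSE)
  needed <- c("id", "species", "latitude", "longitude", "origin", "collection",
              paste0("fur_", .traits), paste0("hab_", .traits))
  miss <- setdiff(needed, names(spec))
  if (length(miss) > 0) stop("specimen table lacks columns: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  extra_sp <- setdiff(unique(spec$species), tree$tip.label)
  if (length(extra_sp) > 0) {
    stop("species missing from tree: ", paste(extra_sp, collapse = ", "),
         call. = FALSE)
  }
  # tips without specimens carry no data; prune them so species-level
  # stages work on the sampled taxa only
  if (length(setdiff(tree$tip.label, unique(spec$species))) > 0) {
    tree <- ape::keep.tip(tree, unique(spec$species))
  }
  set.seed(config$seed)
  hash <- .config_hash(config)
  stamp <- function(df) {
    attr(df, "config_hash") <- hash
    attr(df, "seed") <- config$seed
    df
  }

  ## repeatability
  rep_rows <- list()
  for (tr in .traits) {
    f2 <- paste0("fur_", tr, "_2")
    if (f2 %in% names(spec)) {
      r <- icc(cbind(spec[[paste0("fur_", tr)]], spec[[f2]]))
      rep_rows[[paste0("fur_", tr)]] <-
        data.frame(measure = "fur", trait = tr, tau = r$tau, F = r$F,
                   df_between = r$df_between, df_within = r$df_within, p = r$p)
    }
    p1 <- paste0("hab_", tr, "_p1"); p2 <- paste0("hab_", tr, "_p2")
    if (all(c(p1, p2) %in% names(spec))) {
      r <- icc(cbind(spec[[p1]], spec[[p2]]))
      rep_rows[[paste0("hab_", tr)]] <-
        data.frame(measure = "habitat", trait = tr, tau = r$tau, F = r$F,
                   df_between = r$df_between, df_within = r$df_within, p = r$p)
    }
  }
  repeatability <- stamp(do.call(rbind, c(rep_rows, list(make.row.names = FALSE))))

  ## species ANOVA (collection origin entered first)
  anova_tab <- stamp(do.call(rbind, lapply(.traits, function(tr) {
    a_fur <- anova_species(log10(spec[[paste0("fur_", tr)]]), spec$species,
                           covariates = data.frame(collection = spec$collection))
    a_hab <- anova_species(log10(spec[[paste0("hab_", tr)]]), spec$species,
                           covariates = data.frame(collection = spec$collection))
    data.frame(trait = tr,
               measure = c("fur", "habitat"),
               F = c(a_fur$F, a_hab$F),
               df_effect = c(a_fur$df_effect, a_hab$df_effect),
               df_resid = c(a_fur$df_resid, a_hab$df_resid),
               p = c(a_fur$p, a_hab$p))
  })))

  ## PVR, eigenvector selection, PSR curves on species-mean log traits
  D <- patristic_distances(tree)
  basis <- pvr_eigenvectors(D)
  W <- phylo_weight_matrix(D, type = config$moran_weights)
  sel_list <- list(); psr_list <- list()
  for (tr in .traits) {
    sp_mean <- tapply(log10(spec[[paste0("fur_", tr)]]), spec$species, mean)
    sp_mean <- sp_mean[tree$tip.label]
    sel <- select_eigenvectors(sp_mean, basis, W,
                               threshold = config$moran_threshold)
    psr <- psr_curve(sp_mean, basis)
    sel_list[[tr]] <- sel
    psr_list[[tr]] <- psr
  }
  selection <- stamp(do.call(rbind, lapply(.traits, function(tr) {
    data.frame(trait = tr,
               selected = paste(colnames(basis$vectors)[sel_list[[tr]]$selected],
                                collapse = ";"),
               n_selected = length(sel_list[[tr]]$selected),
               residual_moran = sel_list[[tr]]$residual_moran,
               threshold_met = sel_list[[tr]]$threshold_met)
  })))
  psr_tab <- stamp(do.call(rbind, lapply(.traits, function(tr) {
    data.frame(trait = tr,
               k = seq_along(psr_list[[tr]]$r_squared),
               cum_eigenvalue_fraction = psr_list[[tr]]$cum_eigenvalue_fraction,
               r_squared = psr_list[[tr]]$r_squared)
  })))
  psr_signal <- stamp(do.call(rbind, lapply(.traits, function(tr) {
    data.frame(trait = tr,
               mean_deviation = psr_list[[tr]]$mean_deviation,
               area_deviation = psr_list[[tr]]$area_deviation)
  })))

  ## specimen-level eigenvector scores (union over traits)
  sel_union <- sort(unique(unlist(lapply(sel_list, `[[`, "selected"))))
  ev_cols <- character(0)
  for (j in sel_union) {
    cn <- colnames(basis$vectors)[j]
    scores <- stats::setNames(basis$vectors[, j], basis$taxa)
    spec[[cn]] <- assign_species_scores(spec$species, scores)
    ev_cols <- c(ev_cols, cn)
  }

  ## global design
  grp <- c(stats::setNames(rep("habitat", 4), paste0("hab_", .traits)),
           latitude = "geography", longitude = "geography",
           collection = "origin", origin = "origin",
           stats::setNames(rep("phylogeny", length(ev_cols)), ev_cols))
  design <- encode_design(spec,
                          log_continuous = paste0("hab_", .traits),
                          continuous = c("latitude", "longitude", ev_cols),
                          factors = c("collection", "origin"),
                          groups = grp)
  Y <- vapply(.traits, function(tr) log_standardize(spec[[paste0("fur_", tr)]]),
              numeric(nrow(spec)))
  colnames(Y) <- paste0("fur_", .traits)

  ## global models: one multi-response + four single-response
  models <- list()
  models[["multi"]] <- .fit_model(design, Y, config, seed_offset = 100,
                                  stratify = factor(spec$species))
  for (i in seq_along(.traits)) {
    models[[.traits[i]]] <- .fit_model(design, Y[, i], config,
                                       seed_offset = 100 + 10 * i,
                                       stratify = factor(spec$species))
  }

  ## per-species models (no phylogeny block within a species)
  counts <- table(spec$species)
  sp_run <- names(counts)[counts >= config$per_species_min_n]
  per_species <- list()
  for (k in seq_along(sp_run)) {
    s <- sp_run[k]
    sub <- spec[spec$species == s, , drop = FALSE]
    dsub <- withCallingHandlers(
      encode_design(sub,
                    log_continuous = paste0("hab_", .traits),
                    continuous = c("latitude", "longitude"),
                    factors = c("collection", "origin"),
                    groups = grp),
      warning = function(w) invokeRestart("muffleWarning"))
    Ysub <- vapply(.traits, function(tr) log_standardize(sub[[paste0("fur_", tr)]]),
                   numeric(nrow(sub)))
    per_species[[s]] <- .fit_model(dsub, Ysub, config,
                                   seed_offset = 1000 + 10 * k)
    per_species[[s]]$n <- nrow(sub)
    per_species[[s]]$design <- dsub
  }

  ## partial and residual fur-habitat correlations
  # `collection` carries a "field" level, so it fully encodes origin;
  # including both would alias
  res_block <- data.frame(latitude = spec$latitude, longitude = spec$longitude,
                          collection = factor(spec$collection))
  for (cn in ev_cols) res_block[[cn]] <- spec[[cn]]
  correlations <- stamp(do.call(rbind, lapply(.traits, function(tr) {
    fur <- log10(spec[[paste0("fur_", tr)]])
    hab <- log10(spec[[paste0("hab_", tr)]])
    pp <- partial_pearson(fur, hab, Z = data.frame(origin = factor(spec$origin)))
    rr <- partial_pearson(fur, hab, Z = res_block)
    data.frame(trait = tr,
               type = c("partial_origin", "residual_full"),
               r = c(pp$r, rr$r), p = c(pp$p, rr$p), df = c(pp$df, rr$df))
  })))

  ## variance partition of the global multi-response model
  partition <- if (models$multi$significant) {
    stamp(variance_partition(models$multi$fit, models$multi$importance,
                             design$col_groups))
  }

  ## flat summary tables for the model lists
  weights_tab <- stamp(.weights_table(models, design))
  per_species_tab <- stamp(.per_species_table(per_species))

  structure(
    list(meta = list(config_hash = hash, seed = config$seed,
                     algorithm = "NIPALS",
                     moran_weights = config$moran_weights,
                     moran_threshold = config$moran_threshold,
                     q2_threshold = config$q2_threshold,
                     bootstrap_B = config$bootstrap_B,
                     n_specimens = nrow(spec),
                     n_species = length(tree$tip.label)),
         repeatability = repeatability, anova = anova_tab,
         selection = selection, psr = psr_tab, psr_signal = psr_signal,
         models = models, per_species = per_species,
         weights = weights_tab, per_species_summary = per_species_tab,
         correlations = correlations, partition = partition,
         design = design, basis = basis),
    class = "crypsis_report"
  )
}

# one row per predictor x model: first-component weight, importance,
# bootstrap coefficient stats (multi-response models report the mean |beta|
# column-wise maximum is not needed: coefficients are per response, so the
# table keeps the first response column and flags significance across all)
.weights_table <- function(models, design) {
  rows <- list()
  for (mn in names(models)) {
    m <- models[[mn]]
    if (!isTRUE(m$significant)) {
      rows[[mn]] <- data.frame(model = mn, predictor = NA_character_,
                               W = NA_real_, share = NA_real_,
                               important = NA, beta = NA_real_,
                               se = NA_real_, p = NA_real_,
                               significant_component = FALSE)
      next
    }
    b <- m$bootstrap
    rows[[mn]] <- data.frame(
      model = mn, predictor = m$fit$predictors,
      W = m$fit$W[, 1],
      share = m$importance$share,
      important = m$importance$important,
      beta = rowMeans(m$fit$beta),
      se = if (!is.null(b)) rowMeans(b$se) else NA_real_,
      p = if (!is.null(b)) apply(b$p, 1, min) else NA_real_,
      significant_component = TRUE, row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.per_species_table <- function(per_species) {
  if (length(per_species) == 0) {
    return(data.frame(species = character(), n = integer(), A = integer(),
                      habitat_share = numeric(), habitat_important = logical(),
                      explained = numeric()))
  }
  do.call(rbind, c(lapply(names(per_species), function(s) {
    m <- per_species[[s]]
    if (!m$significant) {
      return(data.frame(species = s, n = m$n, A = 0L, habitat_share = NA_real_,
                        habitat_important = FALSE, explained = NA_real_))
    }
    hab <- m$design$col_groups == "habitat"
    share <- sum(m$importance$share[hab])
    data.frame(species = s, n = m$n, A = m$A, habitat_share = share,
               habitat_important = share > 0.05,
               explained = m$fit$explained_cum[m$A])
  }), list(make.row.names = FALSE)))
}

#' Variance partition of a PLSR fit into predictor blocks
#'
#' Groups squared-weight importance shares by predictor block and multiplies
#' by the model's total explained response variance, giving the percentage
#' of trait variance attributable to each block (habitat colouration,
#' geography, collection origin, phylogenetic eigenvectors). Block
#' percentages sum to the model's explained percentage.
#'
#' @param fit A `plsr_fit`.
#' @param importance Its [variable_importance()] table.
#' @param col_groups Character vector of block labels, one per predictor
#'   column (see [encode_design()]).
#' @return data.frame `block`, `share`, `percent`.
#' @export
variance_partition <- function(fit, importance, col_groups) {
  if (length(col_groups) != nrow(importance)) {
    stop("col_groups length does not match predictors", call. = FALSE)
  }
  if (anyNA(col_groups)) stop("unknown column grouping", call. = FALSE)
  agg <- tapply(importance$share, col_groups, sum)
  total <- fit$explained_cum[fit$A]
  data.frame(block = names(agg), share = as.numeric(agg),
             percent = as.numeric(agg) * total, row.names = NULL)
}

#' @export
print.crypsis_report <- function(x, ...) {
  cat("Colour-matching analysis report\n")
  cat("  specimens:", x$meta$n_specimens, " species:", x$meta$n_species,
      " seed:", x$meta$seed, " config:", x$meta$config_hash, "\n")
  if (!is.null(x$repeatability)) {
    cat(sprintf("  repeatability: fur tau >= %.3f, habitat tau >= %.3f\n",
                min(x$repeatability$tau[x$repeatability$measure == "fur"]),
                min(x$repeatability$tau[x$repeatability$measure == "habitat"])))
  }
  cat(sprintf("  PSR mean deviation: %s\n",
              paste(sprintf("%s %+0.3f", x$psr_signal$trait,
                            x$psr_signal$mean_deviation), collapse = ", ")))
  m <- x$models$multi
  if (isTRUE(m$significant)) {
    cat(sprintf("  global PLSR: %d component(s), %.1f%% explained, r(T1,U1) = %.2f\n",
                m$A, m$fit$explained_cum[m$A], m$component_r))
  } else {
    cat("  global PLSR: no significant component\n")
  }
  if (!is.null(x$partition)) {
    cat("  variance partition:",
        paste(sprintf("%s %.1f%%", x$partition$block, x$partition$percent),
              collapse = ", "), "\n")
  }
  cat("  per-species models:", nrow(x$per_species_summary), "\n")
  invisible(x)
}

#' Write a report bundle as CSV tables plus JSON metadata
#'
#' @param report A `crypsis_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "crypsis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("repeatability", "anova", "selection", "psr", "psr_signal",
              "weights", "per_species_summary", "correlations", "partition")
  for (tb in tables) {
    if (!is.null(report[[tb]])) {
      utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report$meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sensitivity re-run under an alternative phylogeny
#'
#' Re-runs the phylogeny-dependent stages with another tree over the same
#' taxa and tabulates side-by-side deltas of the global multi-response
#' model's first-component weights and importance flags.
#'
#' @param config A [run_config()].
#' @param alternative_tree [ape::phylo] tree or Newick path with the same
#'   taxon set.
#' @return List with `report` (the re-run) and `deltas` (data.frame, one row
#'   per predictor).
#' @export
sensitivity_rerun <- function(config, alternative_tree) {
  if (is.character(alternative_tree)) {
    alternative_tree <- parse_newick(file = alternative_tree)
  }
  tree <- config$tree
  if (is.character(tree)) tree <- parse_newick(file = tree)
  if (!setequal(tree$tip.label, alternative_tree$tip.label)) {
    stop("alternative tree has a different taxon set", call. = FALSE)
  }
  main <- run_full(config)
  alt_config <- config
  alt_config$tree <- alternative_tree
  alt <- run_full(alt_config)
  w_main <- main$weights[main$weights$model == "multi", ]
  w_alt <- alt$weights[alt$weights$model == "multi", ]
  deltas <- merge(w_main[, c("predictor", "W", "share", "important")],
                  w_alt[, c("predictor", "W", "share", "important")],
                  by = "predictor", suffixes = c("_main", "_alt"),
                  all = TRUE)
  deltas$delta_W <- deltas$W_alt - deltas$W_main
  deltas$delta_share <- deltas$share_alt - deltas$share_main
  deltas$flag_changed <- deltas$important_alt != deltas$important_main
  list(report = alt, deltas = deltas)
}
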