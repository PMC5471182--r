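#' Simulation configuration for a synthetic colour-matching study
#'
#' Defines the generative model the analysis pipeline assumes: species on a
#' pure-birth (Yule) tree, a Brownian pigmentation effect shared by all
#' channels of a species, per-specimen habitat colour read from a smooth
#' longitudinal gradient with local heterogeneity, a latitude brightness
#' gradient, a field-collection brightness offset, and pixel-level
#' measurement noise. Defaults emulate a museum + field study of a desert
#' rodent radiation: 14 species, ~460 specimens with skewed per-species
#' sample sizes in 5-120, ~20% field-collected specimens spread over seven
#' museum collections, sandy substrate colours on the 0-255 reflectance
#' scale.
#'
#' @param n_species Number of species (>= 4).
#' @param n_total Total specimen count targeted across species.
#' @param count_range Per-species specimen count bounds.
#' @param birth_rate Yule speciation rate.
#' @param sigma2_phylo Brownian rate of the species pigmentation effect
#'   (reflectance units^2 per unit branch length).
#' @param b_hab Fur response per unit habitat reflectance deviation.
#' @param b_lat Fur response per degree latitude (negative: brighter at low
#'   latitudes).
#' @param field_offset Additive brightness of field-collected specimens
#'   (reflectance units, 0-255 scale).
#' @param noise_sd Residual per-specimen fur noise sd.
#' @param measurement_sd Sd of the repeated patch-measurement error (drives
#'   fur repeatability).
#' @param hab_local_sd Site-level habitat heterogeneity sd.
#' @param hab_period_sd Between-period habitat measurement sd (drives
#'   habitat repeatability).
#' @param hab_base,fur_base Baseline RGB levels (0-255).
#' @param hab_gradient RGB amplitude of the habitat gradient from the west
#'   to the east edge of the study window.
#' @param lat_range,lon_range Geographic window (degrees).
#' @param prop_field Proportion of field-collected specimens.
#' @param n_collections Number of museum collection labels.
#' @param b_hab_species Optional named per-species override of `b_hab`.
#' @param tree Optional user-supplied [ape::phylo] tree (bypasses the Yule
#'   generator; tip count must equal `n_species`).
#' @param seed Integer seed; recorded in the output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 14, n_total = 460, count_range = c(5, 120),
                       birth_rate = 1, sigma2_phylo = 25,
                       b_hab = 0.5, b_lat = -1.0, field_offset = 8,
                       noise_sd = 8, measurement_sd = 1,
                       hab_local_sd = 10, hab_period_sd = 4,
                       hab_base = c(180, 160, 120),
                       fur_base = c(150, 130, 100),
                       hab_gradient = c(50, 50, 40),
                       lat_range = c(18, 36), lon_range = c(-15, 30),
                       prop_field = 0.2, n_collections = 7,
                       b_hab_species = NULL, tree = NULL, seed = 1) {
  cfg <- list(n_species = n_species, n_total = n_total,
              count_range = count_range, birth_rate = birth_rate,
              sigma2_phylo = sigma2_phylo, b_hab = b_hab, b_lat = b_lat,
              field_offset = field_offset, noise_sd = noise_sd,
              measurement_sd = measurement_sd, hab_local_sd = hab_local_sd,
              hab_period_sd = hab_period_sd, hab_base = hab_base,
              fur_base = fur_base, hab_gradient = hab_gradient,
              lat_range = lat_range, lon_range = lon_range,
              prop_field = prop_field, n_collections = n_collections,
              b_hab_species = b_hab_species, tree = tree, seed = seed)
  stopifnot(cfg$n_species >= 4, cfg$noise_sd >= 0, cfg$sigma2_phylo >= 0,
            cfg$measurement_sd >= 0, cfg$hab_local_sd >= 0,
            cfg$hab_period_sd >= 0, cfg$prop_field >= 0, cfg$prop_field <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: while k lineages are extant the waiting time to the
#' next speciation is exponential with rate `k * birth_rate` and a uniformly
#' chosen lineage splits; the simulation stops at `n` tips and all pendant
#' branches are extended by a final exponential waiting time, giving an
#' ultrametric tree.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional seed.
#' @return An [ape::phylo] tree with tips `t1..tn`.
#' @export
generate_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (n < 2) stop("need n >= 2 tips", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # node bookkeeping in ape numbering: tips 1..n, internals n+1 .. 2n-1;
  # the crown root sits at time 0 (no stem edge)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  root <- n + 1L
  next_internal <- n + 2L
  pend_parent <- c(root, root)  # parent node of each extant, unsplit lineage
  t_now <- 0
  k <- 2L
  while (k < n) {
    t_now <- t_now + stats::rexp(1, k * birth_rate)
    i <- sample.int(k, 1)
    node <- next_internal; next_internal <- next_internal + 1L
    parent[node] <- pend_parent[i]; node_time[node] <- t_now
    # the split lineage becomes an internal node with two new pending ones
    pend_parent <- c(pend_parent[-i], node, node)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1, n * birth_rate)
  # remaining pending lineages are the tips, in random label order
  tip_ids <- sample.int(n)
  parent[tip_ids] <- pend_parent
  node_time[tip_ids] <- t_end
  edge <- cbind(parent[-root], seq_len(n_nodes)[-root])
  storage.mode(edge) <- "integer"
  len <- node_time[edge[, 2]] - node_time[edge[, 1]]
  tree <- list(edge = edge, edge.length = len,
               tip.label = sprintf("t%d", seq_len(n)), Nnode = n - 1L)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

# skewed per-species sample sizes clipped to the configured range and
# adjusted to hit the configured total
.species_counts <- function(cfg) {
  w <- stats::rlnorm(cfg$n_species, meanlog = 0, sdlog = 0.9)
  counts <- round(w / sum(w) * cfg$n_total)
  counts <- pmin(pmax(counts, cfg$count_range[1]), cfg$count_range[2])
  # nudge the largest adjustable counts until the total matches
  gap <- cfg$n_total - sum(counts)
  while (gap != 0) {
    if (gap > 0) {
      i <- which(counts < cfg$count_range[2])
      if (length(i) == 0) break
      i <- i[which.max(counts[i])]
      counts[i] <- counts[i] + 1L; gap <- gap - 1L
    } else {
      i <- which(counts > cfg$count_range[1])
      if (length(i) == 0) break
      i <- i[which.min(counts[i])]
      counts[i] <- counts[i] - 1L; gap <- gap + 1L
    }
  }
  counts
}

# habitat channel mean at a longitude (linear west-east gradient)
.habitat_mean <- function(cfg, lon, channel) {
  frac <- (lon - cfg$lon_range[1]) / diff(cfg$lon_range) - 0.5
  cfg$hab_base[channel] + cfg$hab_gradient[channel] * frac
}

#' Simulate a full synthetic specimen dataset
#'
#' Draws a species tree, per-species Brownian pigmentation effects, and a
#' specimen table with coordinates, collection origin, two-period habitat
#' colours and duplicated fur measurements, following the generative model
#' described in [sim_config()]. Fur channel values are
#' `fur_base + b_hab (habitat - hab_base) + b_lat (lat - mid_lat) +
#' field_offset 1[field] + BM(species) + N(0, noise_sd)`, truncated to
#' `[0, 255]` (a warning reports truncation affecting > 5% of values).
#' Total reflectance columns use BT.601 weights throughout.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_dataset`: list with `tree`, `specimens`
#'   (data.frame), `truth` (generative parameters incl. species effects),
#'   `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- generate_yule_tree(cfg$n_species, cfg$birth_rate)
  } else {
    .check_tree(tree)
    if (length(tree$tip.label) != cfg$n_species) {
      stop("supplied tree tip count != n_species", call. = FALSE)
    }
  }
  species <- tree$tip.label
  counts <- .species_counts(cfg)
  names(counts) <- species
  phylo_effect <- if (cfg$sigma2_phylo > 0) {
    simulate_bm(tree, sigma2 = cfg$sigma2_phylo, root_value = 0)
  } else {
    stats::setNames(rep(0, cfg$n_species), species)
  }
  b_hab_sp <- stats::setNames(rep(cfg$b_hab, cfg$n_species), species)
  if (!is.null(cfg$b_hab_species)) {
    b_hab_sp[names(cfg$b_hab_species)] <- cfg$b_hab_species
  }
  n <- sum(counts)
  sp <- rep(species, counts)
  lat <- stats::runif(n, cfg$lat_range[1], cfg$lat_range[2])
  lon <- stats::runif(n, cfg$lon_range[1], cfg$lon_range[2])
  origin <- ifelse(stats::runif(n) < cfg$prop_field, "field", "museum")
  collection <- ifelse(origin == "field", "field",
                       sprintf("museum_%02d",
                               sample.int(cfg$n_collections, n, replace = TRUE)))
  mid_lat <- mean(cfg$lat_range)
  chans <- c("red", "green", "blue")
  spec <- data.frame(id = sprintf("s%04d", seq_len(n)), species = sp,
                     latitude = lat, longitude = lon,
                     origin = origin, collection = collection,
                     stringsAsFactors = FALSE)
  n_trunc <- 0L
  for (k in seq_along(chans)) {
    hab_true <- .habitat_mean(cfg, lon, k) + stats::rnorm(n, 0, cfg$hab_local_sd)
    hab_true <- pmin(pmax(hab_true, 0), 255)
    p1 <- pmin(pmax(hab_true + stats::rnorm(n, 0, cfg$hab_period_sd), 0), 255)
    p2 <- pmin(pmax(hab_true + stats::rnorm(n, 0, cfg$hab_period_sd), 0), 255)
    hab <- (p1 + p2) / 2
    fur_latent <- cfg$fur_base[k] +
      b_hab_sp[sp] * (hab_true - cfg$hab_base[k]) +
      cfg$b_lat * (lat - mid_lat) +
      cfg$field_offset * (origin == "field") +
      phylo_effect[sp] +
      stats::rnorm(n, 0, cfg$noise_sd)
    m1 <- fur_latent + stats::rnorm(n, 0, cfg$measurement_sd)
    m2 <- fur_latent + stats::rnorm(n, 0, cfg$measurement_sd)
    n_trunc <- n_trunc + sum(m1 < 0 | m1 > 255 | m2 < 0 | m2 > 255)
    spec[[paste0("fur_", chans[k])]] <- pmin(pmax(m1, 0), 255)
    spec[[paste0("fur_", chans[k], "_2")]] <- pmin(pmax(m2, 0), 255)
    spec[[paste0("hab_", chans[k])]] <- hab
    spec[[paste0("hab_", chans[k], "_p1")]] <- p1
    spec[[paste0("hab_", chans[k], "_p2")]] <- p2
  }
  if (n_trunc > 0.05 * n * 6) {
    warning("truncation to [0, 255] affected ", n_trunc, " fur values")
  }
  for (suff in c("", "_2")) {
    spec[[paste0("fur_L", suff)]] <- total_reflectance(
      spec[[paste0("fur_red", suff)]], spec[[paste0("fur_green", suff)]],
      spec[[paste0("fur_blue", suff)]])
  }
  for (suff in c("", "_p1", "_p2")) {
    spec[[paste0("hab_L", suff)]] <- total_reflectance(
      spec[[paste0("hab_red", suff)]], spec[[paste0("hab_green", suff)]],
      spec[[paste0("hab_blue", suff)]])
  }
  structure(
    list(tree = tree, specimens = spec,
         truth = list(phylo_effect = phylo_effect, b_hab_species = b_hab_sp,
                      counts = counts, config = unclass(cfg)),
         config = cfg),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("synthetic colour-matching dataset\n")
  cat("  species:", length(x$tree$tip.label),
      "  specimens:", nrow(x$specimens),
      "  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain files
#'
#' Emits `tree.nwk`, `specimens.csv` and `truth.json` under `dir`.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(ds$specimens, file.path(dir, "specimens.csv"), row.names = FALSE)
  truth <- ds$truth
  truth$config$tree <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Render synthetic specimen patch photographs
#'
#' One image per specimen: a uniform fur patch next to white and black
#' reference swatches, with a known linear channel distortion
#' (`observed = gain * true + offset`) applied to everything, emulating
#' uncontrolled light conditions that [balance_correct()] must invert.
#' Float TIFF output is lossless, so with zero noise the extracted,
#' balance-corrected patch colour reproduces the input exactly; PNG output
#' is 8-bit quantized.
#'
#' @param colours data.frame with `id`, `red`, `green`, `blue` (0-255).
#' @param dir Output directory.
#' @param distortion List with numeric length-3 `gain` and `offset`.
#' @param patch_noise_sd Pixel noise sd inside the fur patch.
#' @param patch_px Patch side in pixels.
#' @param format `"tiff"` (32-bit float) or `"png"` (8-bit).
#' @param seed Optional seed.
#' @return data.frame manifest: `id`, `file`, observed chart references
#'   (`white_red`, ..., `black_blue`) and the patch region
#'   (`row0`, `col0`, `side`).
#' @export
render_patch_images <- function(colours, dir,
                                distortion = list(gain = c(1, 1, 1),
                                                  offset = c(0, 0, 0)),
                                patch_noise_sd = 0, patch_px = 100,
                                format = c("tiff", "png"), seed = NULL) {
  format <- match.arg(format)
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(all(c("id", "red", "green", "blue") %in% names(colours)))
  gain <- distortion$gain; offset <- distortion$offset
  h <- patch_px; w <- patch_px + 60
  rows <- list()
  for (i in seq_len(nrow(colours))) {
    img <- array(0, dim = c(h, w, 3))
    true_rgb <- as.numeric(colours[i, c("red", "green", "blue")])
    for (k in 1:3) {
      patch <- matrix(true_rgb[k], h, patch_px)
      if (patch_noise_sd > 0) {
        patch <- patch + matrix(stats::rnorm(h * patch_px, 0, patch_noise_sd), h)
      }
      img[, seq_len(patch_px), k] <- patch
      img[seq_len(floor(h / 2)), (patch_px + 1):w, k] <- 255        # white swatch
      img[(floor(h / 2) + 1):h, (patch_px + 1):w, k] <- 0           # black swatch
      img[, , k] <- gain[k] * img[, , k] + offset[k]
    }
    img <- pmin(pmax(img / 255, 0), 1)
    file <- file.path(dir, paste0(colours$id[i], ".",
                                  if (format == "tiff") "tif" else "png"))
    if (format == "tiff") {
      tiff::writeTIFF(img, file, bits.per.sample = 32)
    } else {
      png::writePNG(img, file)
    }
    rows[[i]] <- data.frame(
      id = colours$id[i], file = file,
      white_red = gain[1] * 255 + offset[1], white_green = gain[2] * 255 + offset[2],
      white_blue = gain[3] * 255 + offset[3],
      black_red = offset[1], black_green = offset[2], black_blue = offset[3],
      row0 = 0, col0 = 0, side = patch_px, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic habitat gradient raster
#'
#' Smooth linear gradient per band plus white noise, with optional nodata
#' holes; the building block for habitat-extraction tests and for the
#' two-period repeatability design (`period_shift` displaces all values to
#' emulate between-period change).
#'
#' @param nrow,ncol Raster shape in pixels.
#' @param origin,pixel_size,units Geotransform (see [habitat_raster()]).
#' @param base RGB baseline (0-255).
#' @param gradient RGB amplitude across the x extent (west to east edge).
#' @param noise_sd Per-pixel noise sd.
#' @param nodata_frac Fraction of cells set to nodata.
#' @param period_shift Additive RGB shift (e.g. for a second period).
#' @param seed Optional seed.
#' @return A `habitat_raster`.
#' @export
generate_raster <- function(nrow = 50, ncol = 50, origin = c(0, 0),
                            pixel_size = c(1, 1), units = "m",
                            base = c(180, 160, 120), gradient = c(50, 50, 40),
                            noise_sd = 0, nodata_frac = 0,
                            period_shift = c(0, 0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xfrac <- matrix(rep((seq_len(ncol) - 0.5) / ncol - 0.5, each = nrow), nrow)
  bands <- lapply(1:3, function(k) {
    b <- base[k] + period_shift[k] + gradient[k] * xfrac
    if (noise_sd > 0) b <- b + matrix(stats::rnorm(nrow * ncol, 0, noise_sd), nrow)
    b
  })
  # one shared nodata mask across bands (sensor dropouts hit all channels)
  if (nodata_frac > 0) {
    mask <- matrix(stats::runif(nrow * ncol) < nodata_frac, nrow)
    bands <- lapply(bands, function(b) { b[mask] <- NA; b })
  }
  habitat_raster(bands[[1]], bands[[2]], bands[[3]], origin = origin,
                 pixel_size = pixel_size, units = units)
}
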