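test_that("Yule trees have the requested size and ultrametric shape", {
  t2 <- generate_yule_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)

  tr <- generate_yule_tree(14, seed = 2)
  expect_equal(length(tr$tip.label), 14)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(all(tr$edge.length >= 0))
  expect_error(generate_yule_tree(1), "n >= 2")

  expect_identical(ape::write.tree(generate_yule_tree(8, 2, seed = 7)),
                   ape::write.tree(generate_yule_tree(8, 2, seed = 7)))
})

test_that("Yule tree depth matches the waiting-time-sum oracle", {
  lambda <- 1.5; n <- 10; reps <- 800
  set.seed(8)
  depths <- replicate(reps, {
    tr <- generate_yule_tree(n, lambda)
    max(ape::node.depth.edgelength(tr))
  })
  # independent oracle: crown age = sum of exponential inter-speciation
  # waits at 2..n lineages plus the final extension at n lineages
  oracle <- replicate(reps, sum(rexp(n - 1, (2:n) * lambda)) + rexp(1, n * lambda))
  se <- sqrt(var(depths) / reps + var(oracle) / reps)
  expect_lt(abs(mean(depths) - mean(oracle)), 3 * se)
})

test_that("synthetic datasets respect the configured structure", {
  cfg <- sim_config(seed = 5)
  ds <- simulate_dataset(cfg)
  spec <- ds$specimens

  expect_equal(nrow(spec), cfg$n_total)
  counts <- table(spec$species)
  expect_true(all(counts >= cfg$count_range[1] & counts <= cfg$count_range[2]))
  expect_setequal(unique(spec$species), ds$tree$tip.label)

  # channel bounds
  for (cl in grep("^(fur|hab)_", names(spec), value = TRUE)) {
    expect_true(all(spec[[cl]] >= 0 & spec[[cl]] <= 255), label = cl)
  }
  # origin structure: field share near 20%, museum split over 7 collections
  expect_lt(abs(mean(spec$origin == "field") - 0.2), 0.08)
  expect_equal(sort(unique(spec$collection[spec$origin == "museum"])),
               sprintf("museum_%02d", 1:7))
  # total reflectance columns are exact BT.601 combinations
  expect_equal(spec$fur_L,
               total_reflectance(spec$fur_red, spec$fur_green, spec$fur_blue))
})

test_that("generators are byte-reproducible for a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(sim_config(seed = 33)), d1)
  write_dataset(simulate_dataset(sim_config(seed = 33)), d2)
  for (f in c("tree.nwk", "specimens.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # truth round-trip holds every generative parameter
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_true(all(c("phylo_effect", "b_hab_species", "counts", "config")
                  %in% names(truth)))
  expect_equal(truth$config$b_hab, sim_config()$b_hab)
})

test_that("fur-habitat correlation matches the generative closed form", {
  cfg <- sim_config(n_total = 4000, sigma2_phylo = 0, seed = 44,
                    count_range = c(5, 2000))
  ds <- simulate_dataset(cfg)
  spec <- ds$specimens
  # channel variances implied by the linear model (red channel):
  v_ht <- cfg$hab_gradient[1]^2 / 12 + cfg$hab_local_sd^2
  v_hab_meas <- v_ht + cfg$hab_period_sd^2 / 2
  v_fur <- cfg$b_hab^2 * v_ht + cfg$b_lat^2 * diff(cfg$lat_range)^2 / 12 +
    cfg$field_offset^2 * cfg$prop_field * (1 - cfg$prop_field) +
    cfg$noise_sd^2 + cfg$measurement_sd^2
  rho <- cfg$b_hab * v_ht / sqrt(v_fur * v_hab_meas)
  expect_equal(cor(spec$fur_red, spec$hab_red), rho, tolerance = 0.05)
})

test_that("patch images round-trip through balance correction", {
  cols <- data.frame(id = c("a", "b"), red = c(150, 80), green = c(130, 90),
                     blue = c(100, 60))
  dir0 <- tempfile()

  # identity distortion, zero noise, float TIFF: exact recovery
  man <- render_patch_images(cols, dir0)
  for (i in 1:2) {
    img <- read_image(man$file[i])
    patch <- extract_patch_mean(img, c(man$row0[i], man$col0[i], man$side[i]))
    expect_equal(as.numeric(patch[1, 1:3]),
                 as.numeric(cols[i, c("red", "green", "blue")]),
                 tolerance = 1e-6)
  }

  # known gain/offset distortion is inverted by the chart references
  dist <- list(gain = c(0.8, 0.9, 0.7), offset = c(20, 10, 30))
  man2 <- render_patch_images(cols, tempfile(), distortion = dist)
  for (i in 1:2) {
    img <- read_image(man2$file[i])
    raw <- extract_patch_mean(img, c(man2$row0[i], man2$col0[i], man2$side[i]))
    ref <- list(white = as.numeric(man2[i, c("white_red", "white_green", "white_blue")]),
                black = as.numeric(man2[i, c("black_red", "black_green", "black_blue")]))
    fixed <- balance_correct(as.numeric(raw[1, 1:3]), ref)
    expect_equal(as.numeric(fixed[1, 1:3]),
                 as.numeric(cols[i, c("red", "green", "blue")]),
                 tolerance = 1e-4)
  }

  # pixel noise averages out at the standard-error rate
  man3 <- render_patch_images(cols[1, ], tempfile(), patch_noise_sd = 2,
                              patch_px = 100, seed = 9)
  img3 <- read_image(man3$file[1])
  patch3 <- extract_patch_mean(img3, c(0, 0, 100))
  expect_lt(abs(patch3$red - cols$red[1]), 3 * 2 / sqrt(100 * 100) + 1e-6)
})

test_that("gradient rasters expose the configured structure", {
  r0 <- generate_raster(nrow = 20, ncol = 20, gradient = c(0, 0, 0),
                        noise_sd = 0)
  expect_true(all(r0$bands$red == r0$bands$red[1, 1]))

  rg <- generate_raster(nrow = 20, ncol = 40, origin = c(0, 20),
                        gradient = c(40, 40, 40), noise_sd = 0)
  # two points 10 map units (= a quarter of the x extent) apart differ by
  # a quarter of the gradient amplitude
  b1 <- buffer_mean(rg, 10, 10, 0.4)
  b2 <- buffer_mean(rg, 20, 10, 0.4)
  expect_equal(b2$red - b1$red, 10, tolerance = 1e-9)

  # period shift moves every band additively
  rs <- generate_raster(nrow = 10, ncol = 10, gradient = c(0, 0, 0),
                        noise_sd = 0, period_shift = c(5, 5, 5))
  expect_equal(rs$bands$green, r0$bands$green[1:10, 1:10] + 5)
})

test_that("period-split ICC matches the variance-ratio closed form", {
  # between-point variance 15^2, within (period) variance 4^2
  set.seed(55)
  g <- 300
  truev <- rnorm(g, 150, 15)
  m <- cbind(truev + rnorm(g, 0, 4), truev + rnorm(g, 0, 4))
  tau_expect <- 15^2 / (15^2 + 4^2)
  expect_equal(icc(m)$tau, tau_expect, tolerance = 0.03)
})
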