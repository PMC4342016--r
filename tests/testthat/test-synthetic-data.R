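test_that("simulated trees are ultrametric with the requested tips", {
  set.seed(50)
  tr <- simulate_tree(24)
  expect_length(tr$tip.label, 24)
  depths <- ape::node.depth.edgelength(tr)[seq_len(24)]
  expect_lt(diff(range(depths)), 1e-9)
  tr2 <- simulate_tree(2)
  expect_length(tr2$tip.label, 2)
  expect_error(simulate_tree(1), "two tips")
  expect_error(simulate_tree(5, birth_rate = 0.2, death_rate = 0.5),
               "birth_rate")
})

test_that("posterior jitter behaves as configured", {
  set.seed(51)
  tr <- simulate_tree(10)
  p0 <- simulate_posterior(tr, n_trees = 5, jitter_cv = 0)
  expect_length(p0$trees, 5)
  for (t in unclass(p0$trees)) expect_identical(t$edge.length, tr$edge.length)
  # law of large numbers: mean matrix approaches the source tree's
  p <- simulate_posterior(tr, n_trees = 400, jitter_cv = 0.2)
  m <- mean_distance_matrix(p)
  m0 <- patristic_distances(tr)
  expect_lt(max(abs(m - m0) / m0[m0 > 0][1]), 0.2)
  expect_equal(mean(m / m0, na.rm = TRUE), 1, tolerance = 0.05)
  p1 <- simulate_posterior(tr, n_trees = 1)
  expect_length(p1$trees, 1)
})

test_that("Brownian traits carry phylogenetic covariance", {
  set.seed(52)
  # cherries should be more similar than random pairs, averaged over sims
  tr <- simulate_tree(30)
  d <- patristic_distances(tr)
  diffs_cherry <- diffs_rand <- numeric()
  for (i in 1:30) {
    x <- simulate_traits(tr, trait_sigma = 1)
    x <- x[rownames(d)]
    near <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
    diffs_cherry <- c(diffs_cherry, abs(x[near[1]] - x[near[2]]))
    pair <- sample(30, 2)
    diffs_rand <- c(diffs_rand, abs(x[pair[1]] - x[pair[2]]))
  }
  expect_lt(mean(diffs_cherry), mean(diffs_rand))
  expect_error(simulate_traits(tr, 0), "trait_sigma")
})

test_that("landscape generator recovers its own gradients and structure", {
  set.seed(53)
  cfg <- scenario_config("neutral", env_noise = 0.05)
  land <- simulate_landscape(cfg)
  expect_equal(nrow(land$env), 30)
  expect_equal(length(unique(land$truth$class)), 5)
  ax <- derive_axes(land$env)
  expect_gt(abs(cor(ax$scores$disturbance, land$truth$disturbance)), 0.95)
  # coordinates admit at least one positive PCNM axis
  pb <- pcnm_basis(euclidean_plot_distances(land$env))
  expect_gte(ncol(pb$vectors), 1)
  # percent covers in range
  biomass <- as.matrix(land$env[paste0("biomass_",
                                       c("0.0", "0.5", "1.0", "2.0",
                                         "4.0", "8.0", "16"))])
  expect_true(all(biomass >= 0 & biomass <= 100))
  expect_true(all(land$env$relative_light >= 0 & land$env$relative_light <= 1))
})

test_that("communities honour the configured assembly regimes", {
  set.seed(54)
  cfg <- scenario_config("repulsion", n_plots = 10, n_classes = 5,
                         n_plant_species = 80,
                         individuals = c(adult = 25, sapling = 10,
                                         seedling = 10, birds = 10))
  tr <- simulate_tree(60, prefix = "plant")
  trt <- simulate_traits(tr)
  land <- simulate_landscape(cfg)
  comm <- simulate_communities(tr, trt, land$truth, cfg, stages = "adult")
  d <- patristic_distances(tr)
  r <- alpha_pd_ses(comm, d, n_perm = 300)
  # strong repulsion: SES skewed positive
  expect_gt(mean(r$ses, na.rm = TRUE), 0.5)
  # neutral assembly: uniform draws
  cfg0 <- scenario_config("neutral", n_plots = 10, n_plant_species = 80,
                          individuals = c(adult = 25, sapling = 10,
                                          seedling = 10, birds = 10))
  comm0 <- simulate_communities(tr, trt, land$truth, cfg0, stages = "adult")
  r0 <- alpha_pd_ses(comm0, d, n_perm = 300)
  expect_lt(abs(mean(r0$ses, na.rm = TRUE)), 1.0)
  # counts respect the configured individuals per plot
  expect_true(all(rowSums(comm$adult) == cfg$individuals[["adult"]]))
})

test_that("fixture bundles round-trip and are seed-reproducible", {
  cfg <- scenario_config("neutral", n_plots = 6, n_classes = 3,
                         n_plant_species = 12, n_bird_species = 8,
                         n_bird_plots = 6,
                         individuals = c(adult = 10, sapling = 5,
                                         seedling = 5, birds = 8))
  set.seed(55)
  b <- simulate_dataset(cfg, n_posterior = 3, jitter_cv = 0.1)
  dir1 <- withr::local_tempdir()
  make_fixture(b, file.path(dir1, "fx"))
  expect_error(make_fixture(b, file.path(dir1, "fx")), "not empty")
  b2 <- read_bundle(file.path(dir1, "fx"))
  expect_setequal(names(b2$communities),
                  c("adult", "sapling", "seedling", "birds"))
  expect_equal(b2$communities$adult, b$communities$adult)
  expect_equal(sort(b2$plant_tree$tip.label), sort(b$plant_tree$tip.label))
  expect_length(b2$plant_posterior$trees, 3)
  expect_equal(as.data.frame(b2$env), as.data.frame(b$env),
               tolerance = 1e-12)
  # same seed, byte-identical bundle
  set.seed(55)
  b3 <- simulate_dataset(cfg, n_posterior = 3, jitter_cv = 0.1)
  make_fixture(b3, file.path(dir1, "fx2"))
  f1 <- list.files(file.path(dir1, "fx"), full.names = TRUE)
  f2 <- list.files(file.path(dir1, "fx2"), full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})
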