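#' Synthetic forest-modification landscapes
#'
#' Generates complete pipeline inputs mirroring the structure of a
#' subtropical forest-modification survey: a regional species pool on a
#' birth-death phylogeny with Brownian traits, ~30 plots in 5 forest
#' modification classes along a latent disturbance gradient (plus a weaker
#' loss gradient), plot coordinates in two spatial clusters, a plot-level
#' environmental table whose variables respond to the latent gradients, and
#' multi-life-stage communities assembled by trait-based environmental
#' filtering (or limiting-similarity repulsion) whose strength can depend on
#' disturbance.
#'
#' @name synthetic_data
NULL

#' Scenario configuration for the generator
#'
#' Defaults emulate a typical subtropical forest-modification survey: 30 plots in 5
#' modification classes, a 166-species plant pool observed as adults,
#' saplings and seedlings, an 85-species bird pool surveyed on 27 of the
#' plots, and plot coordinates clustered in two reserves. The named
#' scenarios fix the assembly regime: `"filtering"` (default) applies
#' stage-dependent environmental filtering that strengthens with
#' disturbance (weak for adults, strong for saplings/seedlings, very weak
#' for birds); `"neutral"` assembles all communities as uniform random
#' draws; `"repulsion"` applies limiting-similarity repulsion everywhere.
#'
#' @param scenario assembly regime preset.
#' @param n_plots,n_classes plots and forest-modification classes.
#' @param n_plant_species,n_bird_species regional pool sizes.
#' @param n_bird_plots plots with bird counts (the remainder lack birds).
#' @param stages plant life stage names (first = reference level).
#' @param filter_strength named per-stage baseline filtering strength
#'   (>= 0 filtering, < 0 repulsion); entry "birds" for the bird pool.
#' @param disturbance_effect increase in filtering strength per unit of
#'   latent disturbance, for plants and birds respectively.
#' @param individuals named individuals-per-plot for each stage and birds.
#' @param birth_rate,death_rate birth-death tree simulation rates.
#' @param trait_sigma Brownian-motion rate for the assembly trait.
#' @param opt_shift trait-optimum displacement (in trait SD units) per unit
#'   of latent disturbance; deeper shifts move filtered communities into
#'   the clade-structured tails of the trait distribution.
#' @param sad_sigma lognormal SD of the regional species abundance
#'   distribution multiplying all sampling weights (0 = even pool).
#' @param spatial_range within-cluster coordinate scatter (m).
#' @param env_noise SD of the noise on the observed environmental variables
#'   (on the latent gradient scale).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("filtering", "neutral", "repulsion"),
                            n_plots = 30, n_classes = 5,
                            n_plant_species = 166, n_bird_species = 85,
                            n_bird_plots = 27,
                            stages = c("adult", "sapling", "seedling"),
                            filter_strength = NULL,
                            disturbance_effect = NULL,
                            individuals = c(adult = 70, sapling = 23,
                                            seedling = 27, birds = 27),
                            birth_rate = 1, death_rate = 0.3,
                            trait_sigma = 1, opt_shift = 1.0,
                            sad_sigma = 0.5, spatial_range = 3000,
                            env_noise = 0.4) {
  scenario <- match.arg(scenario)
  if (is.null(filter_strength)) {
    filter_strength <- switch(scenario,
      filtering = c(adult = -0.3, sapling = 1.2, seedling = 2.4, birds = 0.2),
      neutral = c(adult = 0, sapling = 0, seedling = 0, birds = 0),
      repulsion = c(adult = -1.5, sapling = -1.5, seedling = -1.5, birds = -1.5)
    )
  }
  if (is.null(disturbance_effect)) {
    disturbance_effect <- switch(scenario,
      filtering = c(plants = 2.4, birds = 0.05),
      neutral = c(plants = 0, birds = 0),
      repulsion = c(plants = 0, birds = 0)
    )
  }
  if (n_plots < n_classes) abort("Need at least one plot per class.")
  stopifnot(length(stages) >= 1, all(stages %in% names(filter_strength)))
  structure(
    list(scenario = scenario, n_plots = n_plots, n_classes = n_classes,
         n_plant_species = n_plant_species, n_bird_species = n_bird_species,
         n_bird_plots = min(n_bird_plots, n_plots), stages = stages,
         filter_strength = filter_strength,
         disturbance_effect = disturbance_effect,
         individuals = individuals, birth_rate = birth_rate,
         death_rate = death_rate, trait_sigma = trait_sigma,
         opt_shift = opt_shift, sad_sigma = sad_sigma,
         spatial_range = spatial_range, env_noise = env_noise),
    class = "scenario_config"
  )
}

#' Simulate an ultrametric birth-death tree
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate,death_rate rates with `birth_rate > death_rate >= 0`.
#' @param prefix tip label prefix (labels `sp0001`...).
#' @return ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0.3,
                          prefix = "sp") {
  if (n_tips < 2) abort("Need at least two tips.")
  if (!(birth_rate > death_rate && death_rate >= 0)) {
    abort("Require birth_rate > death_rate >= 0.")
  }
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = death_rate)
  tree$tip.label <- sprintf("%s%04d", prefix, seq_len(n_tips))
  tree
}

#' Jittered posterior sample around a tree
#'
#' Multiplies every branch length by independent lognormal noise with unit
#' mean and coefficient of variation `jitter_cv`; topology fixed.
#'
#' @param tree `phylo`.
#' @param n_trees posterior size.
#' @param jitter_cv branch-length coefficient of variation (>= 0).
#' @return `tree_posterior`.
#' @export
simulate_posterior <- function(tree, n_trees = 100, jitter_cv = 0.1) {
  if (jitter_cv < 0) abort("`jitter_cv` must be >= 0.")
  sig2 <- log(1 + jitter_cv^2)
  trees <- lapply(seq_len(n_trees), function(i) {
    t <- tree
    if (jitter_cv > 0) {
      mult <- exp(rnorm(length(t$edge.length), -sig2 / 2, sqrt(sig2)))
      t$edge.length <- t$edge.length * mult
    }
    t
  })
  structure(
    list(trees = structure(trees, class = "multiPhylo"),
         tips = sort(tree$tip.label)),
    class = "tree_posterior"
  )
}

#' Brownian-motion trait values on a tree
#'
#' @param tree `phylo`.
#' @param trait_sigma Brownian rate (per unit branch length), > 0.
#' @return named numeric vector of tip trait values (root value 0).
#' @export
simulate_traits <- function(tree, trait_sigma = 1) {
  if (trait_sigma <= 0) abort("`trait_sigma` must be > 0.")
  ape::rTraitCont(tree, model = "BM", sigma = trait_sigma, root.value = 0)
}

#' Simulate the plot landscape and environment table
#'
#' Plots are assigned evenly to the modification classes; latent
#' disturbance (class means spanning roughly -1.2..1.2) and a weaker,
#' partially independent loss gradient drive the observed variables with
#' a realistic loading pattern: disturbance lowers canopy
#' cover, high-layer biomass and heterogeneity and raises low-layer biomass
#' and light; loss shrinks fragments and flips the matrix dummy.
#' Coordinates form two reserve clusters with Gaussian within-cluster
#' scatter.
#'
#' @param config a [scenario_config()].
#' @return list: `env` (environment tibble incl. easting/northing),
#'   `truth` (tibble plot, class, disturbance, loss).
#' @export
simulate_landscape <- function(config) {
  n <- config$n_plots
  k <- config$n_classes
  cls <- sort(rep(seq_len(k), length.out = n))
  plot_id <- sprintf("plot%02d", seq_len(n))
  dist_means <- seq(-1.2, 1.2, length.out = k)
  loss_means <- c(-1.2, 0.3, 0.6, 0.9, -0.2)[((cls - 1) %% 5) + 1]
  disturbance <- dist_means[cls] + rnorm(n, 0, 0.25)
  loss <- loss_means + rnorm(n, 0, 0.4)
  s <- config$env_noise
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  env <- tibble::tibble(
    plot = plot_id,
    forest_size = exp(4 - 1.0 * loss + rnorm(n, 0, s)),          # ha
    edge_length = NA_real_,
    perimeter_area_ratio = NA_real_,
    biomass_0.0 = clamp(35 + 12 * disturbance + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    biomass_0.5 = clamp(30 + 10 * disturbance + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    biomass_1.0 = clamp(28 + 6 * disturbance + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    biomass_2.0 = clamp(30 + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    biomass_4.0 = clamp(35 - 8 * disturbance + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    biomass_8.0 = clamp(30 - 10 * disturbance + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    biomass_16 = clamp(22 - 9 * disturbance + rnorm(n, 0, 8 * s / 0.4), 0, 100),
    canopy_cover = clamp(75 - 15 * disturbance + rnorm(n, 0, 10 * s / 0.4), 5, 100),
    relative_light = clamp(0.25 + 0.12 * disturbance + rnorm(n, 0, 0.1 * s / 0.4),
                           0.01, 1),
    forest_type_dummy = as.integer(cls == config$n_classes),
    matrix_dummy = as.integer(loss > 0.3)
  )
  # edge length grows with size but relatively faster for small fragments
  env$edge_length <- 400 * sqrt(env$forest_size) *
    exp(0.15 * loss + rnorm(n, 0, s / 2))
  env$perimeter_area_ratio <- env$edge_length / env$forest_size
  env$heterogeneity <- apply(
    as.matrix(env[paste0("biomass_", c("0.0", "0.5", "1.0", "2.0",
                                       "4.0", "8.0", "16"))]),
    1, shannon_heterogeneity
  )
  # two reserve clusters
  cluster <- rep(c(0, 1), length.out = n)[sample.int(n)]
  env$easting <- 320000 + cluster * 25000 +
    rnorm(n, 0, config$spatial_range)
  env$northing <- 6620000 + cluster * 40000 +
    rnorm(n, 0, config$spatial_range)
  list(
    env = env,
    truth = tibble::tibble(plot = plot_id, class = cls,
                           disturbance = disturbance, loss = loss)
  )
}

# sequential similarity-penalized species selection (limiting similarity)
repulsion_sample <- function(weights, d, richness, strength) {
  S <- length(weights)
  sim <- 1 - d / max(d)
  chosen <- integer(0)
  avail <- seq_len(S)
  for (i in seq_len(min(richness, S))) {
    w <- weights[avail]
    if (length(chosen) > 0) {
      pen <- apply(sim[avail, chosen, drop = FALSE], 1, max)
      w <- w * exp(-strength * pen)
    }
    pick <- avail[sample.int(length(avail), 1, prob = w)]
    chosen <- c(chosen, pick)
    avail <- setdiff(avail, pick)
  }
  chosen
}

#' Assemble communities along the disturbance gradient
#'
#' Per plot and stage, species sampling weights are
#' `exp(-lambda * (trait - optimum)^2)` with
#' `lambda = filter_strength[stage] + disturbance_effect * disturbance` and
#' the trait optimum tracking the plot's disturbance; abundances are drawn
#' multinomially with the configured individuals per plot. Negative lambda
#' switches to limiting-similarity repulsion: species are chosen
#' sequentially with a penalty on similarity to already-chosen species,
#' then individuals spread uniformly over the chosen set.
#'
#' @param tree pool phylogeny (defines the species labels and, via `d`,
#'   repulsion similarity).

#' @param traits named tip trait vector.
#' @param truth tibble with `plot` and `disturbance` (from
#'   [simulate_landscape()]).
#' @param config [scenario_config()].
#' @param stages which stage names to assemble (defaults to the plant
#'   stages); use `"birds"` for the bird pool.
#' @param taxon "plants" or "birds" (selects the disturbance effect).
#' @return named list of community count matrices (plots x species).
#' @export
simulate_communities <- function(tree, traits, truth, config,
                                 stages = config$stages, taxon = "plants") {
  d <- patristic_distances(tree)
  species <- colnames(d)
  traits <- traits[species]
  tsd <- sd(traits)
  if (tsd == 0) tsd <- 1
  de <- config$disturbance_effect[[taxon]]
  # regional species abundance distribution, shared across plots and stages
  sad <- exp(rnorm(length(species), 0, config$sad_sigma))
  sad <- sad / sum(sad)
  out <- list()
  for (stage in stages) {
    fs <- config$filter_strength[[stage]]
    n_ind <- config$individuals[[stage]]
    plots <- truth$plot
    cm <- matrix(0L, length(plots), length(species),
                 dimnames = list(plots, species))
    for (i in seq_along(plots)) {
      dist_i <- truth$disturbance[i]
      lambda <- fs + de * dist_i
      optimum <- mean(traits) + config$opt_shift * tsd * dist_i
      base <- sad * exp(-pmax(lambda, 0) * ((traits - optimum) / tsd)^2)
      if (sum(base) == 0) abort("Zero total sampling weight.")
      if (lambda >= 0) {
        cm[i, ] <- rmultinom(1, n_ind, prob = base)
      } else {
        # limiting similarity: sequential picks penalized by similarity to
        # the already-chosen, on top of mild habitat sorting toward the
        # same optimum; richness matched to a uniform multinomial draw
        richness <- max(2L, sum(rmultinom(1, n_ind,
                                          rep(1, length(species))) > 0))
        sort_strength <- 0.3 * max(0, 1 + lambda)
        sorting <- sad * exp(-sort_strength * ((traits - mean(traits)) / tsd)^2)
        chosen <- repulsion_sample(sorting, d, richness, -lambda * 3)
        cm[i, chosen] <- as.integer(rmultinom(1, n_ind,
                                              prob = rep(1, length(chosen))))
      }
    }
    out[[stage]] <- cm
  }
  out
}

#' Simulate a complete dataset bundle (in memory)
#'
#' Runs tree, trait, landscape and community simulation for plants (all
#' stages) and birds, returning the full input bundle the pipeline
#' consumes, plus the latent truth.
#'
#' @param config [scenario_config()].
#' @param n_posterior size of the jittered posterior stored alongside each
#'   tree (0 for none).
#' @param jitter_cv posterior branch-length jitter.
#' @return list of class `phylorao_bundle`: `plant_tree`, `bird_tree`,
#'   optional `plant_posterior`/`bird_posterior`, `communities` (named list:
#'   stages + birds), `env`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = scenario_config(),
                             n_posterior = 0, jitter_cv = 0.1) {
  plant_tree <- simulate_tree(config$n_plant_species, config$birth_rate,
                              config$death_rate, prefix = "plant")
  bird_tree <- simulate_tree(config$n_bird_species, config$birth_rate,
                             config$death_rate, prefix = "bird")
  plant_traits <- simulate_traits(plant_tree, config$trait_sigma)
  bird_traits <- simulate_traits(bird_tree, config$trait_sigma)
  land <- simulate_landscape(config)
  communities <- simulate_communities(plant_tree, plant_traits, land$truth,
                                      config, stages = config$stages,
                                      taxon = "plants")
  bird_truth <- land$truth[seq_len(config$n_bird_plots), ]
  communities$birds <- simulate_communities(
    bird_tree, bird_traits, bird_truth, config,
    stages = "birds", taxon = "birds"
  )$birds
  bundle <- list(
    plant_tree = plant_tree, bird_tree = bird_tree,
    communities = communities, env = land$env, truth = land$truth,
    config = config
  )
  if (n_posterior > 0) {
    bundle$plant_posterior <- simulate_posterior(plant_tree, n_posterior,
                                                 jitter_cv)
    bundle$bird_posterior <- simulate_posterior(bird_tree, n_posterior,
                                                jitter_cv)
  }
  structure(bundle, class = "phylorao_bundle")
}

#' Write a dataset bundle to disk
#'
#' Writes Newick trees (and one-tree-per-line posterior files), per-group
#' community CSVs, the environment CSV, the latent truth CSV and a JSON
#' manifest. Refuses to write into a non-empty directory unless `force`.
#'
#' @param bundle a `phylorao_bundle` (from [simulate_dataset()]).
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(bundle, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("Directory ", dir, " is not empty; use force = TRUE."))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(bundle$plant_tree, file.path(dir, "plant_tree.nwk"))
  ape::write.tree(bundle$bird_tree, file.path(dir, "bird_tree.nwk"))
  files <- c("plant_tree.nwk", "bird_tree.nwk")
  for (p in c("plant", "bird")) {
    post <- bundle[[paste0(p, "_posterior")]]
    if (!is.null(post)) {
      fn <- paste0(p, "_posterior.nwk")
      ape::write.tree(post$trees, file.path(dir, fn))
      files <- c(files, fn)
    }
  }
  for (g in names(bundle$communities)) {
    fn <- paste0("community_", g, ".csv")
    cm <- bundle$communities[[g]]
    df <- data.frame(plot = rownames(cm), cm, check.names = FALSE)
    write.csv(df, file.path(dir, fn), row.names = FALSE)
    files <- c(files, fn)
  }
  write.csv(bundle$env, file.path(dir, "environment.csv"), row.names = FALSE)
  write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  files <- c(files, "environment.csv", "truth.csv")
  manifest <- paste0(
    '{\n  "package": "phylorao",\n  "scenario": "',
    bundle$config$scenario, '",\n  "n_plots": ', bundle$config$n_plots,
    ',\n  "groups": [', paste0('"', names(bundle$communities), '"',
                               collapse = ", "),
    '],\n  "files": [', paste0('"', files, '"', collapse = ", "), ']\n}\n'
  )
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a dataset bundle from disk
#'
#' Counterpart of [make_fixture()].
#'
#' @param dir fixture directory.
#' @return a `phylorao_bundle` (without the config/truth semantics beyond
#'   what the files record).
#' @export
read_bundle <- function(dir) {
  stopifnot(dir.exists(dir))
  read_cm <- function(fn) as_community_matrix(read.csv(fn, check.names = FALSE))
  comm_files <- list.files(dir, pattern = "^community_.*\\.csv$",
                           full.names = TRUE)
  groups <- sub("^community_(.*)\\.csv$", "\\1", basename(comm_files))
  communities <- setNames(lapply(comm_files, read_cm), groups)
  bundle <- list(
    plant_tree = read_newick(readLines(file.path(dir, "plant_tree.nwk"))[1]),
    bird_tree = read_newick(readLines(file.path(dir, "bird_tree.nwk"))[1]),
    communities = communities,
    env = tibble::as_tibble(read.csv(file.path(dir, "environment.csv"),
                                     check.names = FALSE)),
    truth = if (file.exists(file.path(dir, "truth.csv"))) {
      tibble::as_tibble(read.csv(file.path(dir, "truth.csv")))
    }
  )
  for (p in c("plant", "bird")) {
    fn <- file.path(dir, paste0(p, "_posterior.nwk"))
    if (file.exists(fn)) bundle[[paste0(p, "_posterior")]] <- read_tree_set(fn)
  }
  structure(bundle, class = "phylorao_bundle")
}
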