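#' End-to-end analysis pipelines
#'
#' `run_alpha()` reproduces the local-scale workflow: corrected Rao
#' taxonomic alpha-diversity and tip-shuffle SES of phylogenetic
#' alpha-diversity per species group, followed by AICc dredging and model
#' averaging of the diversity regressions (mixed model with a plot random
#' intercept for the multi-stage plant data, OLS for birds).
#' `run_beta()` reproduces the landscape-scale workflow: pairwise
#' beta-diversity, partial Mantel tests against disturbance and loss
#' gradients conditioned on spatial distance, PCNM + double-stop forward
#' selection, and three-set variation partitioning.
#' `posterior_sweep()` repeats the phylogeny-dependent statistics over a
#' posterior sample of trees to quantify robustness to phylogenetic
#' uncertainty.
#'
#' @name pipeline
NULL

plant_groups <- function(bundle) {
  setdiff(names(bundle$communities), "birds")
}

regional_distance <- function(bundle, taxon = c("plant", "bird"),
                              tree_source = c("mean", "single")) {
  taxon <- match.arg(taxon)
  tree_source <- match.arg(tree_source)
  post <- bundle[[paste0(taxon, "_posterior")]]
  if (tree_source == "mean" && !is.null(post)) {
    mean_distance_matrix(post)
  } else {
    patristic_distances(bundle[[paste0(taxon, "_tree")]])
  }
}

model_terms_plants <- function() {
  c("life_stage", "disturbance", "life_stage:disturbance",
    "loss", "easting", "northing")
}

model_terms_birds <- function() c("disturbance", "loss", "easting", "northing")

#' Alpha-diversity analysis of a dataset bundle
#'
#' @param bundle a `phylorao_bundle` ([simulate_dataset()] /
#'   [read_bundle()]).
#' @param n_perm tip shuffles for the SES null model.
#' @param alpha per-tail dispersion level.
#' @param delta AICc window for model averaging.
#' @param corrected apply the Rao corrections.
#' @param tree_source use the posterior-mean distance matrix when a
#'   posterior is present ("mean"), or the single tree ("single").
#' @return list of class `alpha_report`: `ses` (per-plot SES tibble),
#'   `td` (per-plot corrected taxonomic alpha), `dispersion` (counts),
#'   `models` (named list of `averaged_model`), `coefficients` (combined
#'   Table-1-shaped tibble with response and provenance columns).
#' @export
run_alpha <- function(bundle, n_perm = 3000, alpha = 0.025, delta = 2.0,
                      corrected = TRUE, tree_source = c("mean", "single")) {
  tree_source <- match.arg(tree_source)
  pg <- plant_groups(bundle)
  d_plant <- regional_distance(bundle, "plant", tree_source)
  has_birds <- "birds" %in% names(bundle$communities)
  ses_tab <- alpha_pd_ses(bundle$communities[pg], d_plant,
                          n_perm = n_perm, alpha = alpha,
                          corrected = corrected)
  if (has_birds) {
    d_bird <- regional_distance(bundle, "bird", tree_source)
    ses_birds <- alpha_pd_ses(bundle$communities["birds"], d_bird,
                              n_perm = n_perm, alpha = alpha,
                              corrected = corrected)
    ses_tab <- dplyr::bind_rows(ses_tab, ses_birds)
  }
  td <- purrr::map_dfr(names(bundle$communities), function(g) {
    cm <- bundle$communities[[g]]
    dplyr::mutate(
      alpha_profile(cm, taxonomic_distances(colnames(cm)),
                    corrected = corrected),
      group = g, .before = 1
    )
  })
  axes <- derive_axes(bundle$env)
  covars <- dplyr::left_join(axes$scores,
                             dplyr::select(bundle$env, "plot", "easting",
                                           "northing"),
                             by = "plot")
  covars <- dplyr::mutate(covars,
                          dplyr::across(c("disturbance", "loss",
                                          "easting", "northing"),
                                        z_transform))
  make_data <- function(values) {
    df <- dplyr::inner_join(values, covars, by = "plot")
    df <- df[complete.cases(df$response), ]
    dropped <- setdiff(values$plot, df$plot)
    if (length(dropped) > 0) {
      inform(paste0("Dropped plots without a defined response: ",
                    paste(unique(dropped), collapse = ", ")))
    }
    df
  }
  td_col <- if (corrected) "corrected" else "raw_q"
  models <- list()
  # plants: long over stages, random plot intercept
  plant_pd <- ses_tab |>
    dplyr::filter(.data$group %in% pg) |>
    dplyr::transmute(plot = .data$plot,
                     life_stage = factor(.data$group, levels = pg),
                     response = .data$ses)
  df <- make_data(plant_pd)
  models$plants_pd <- average_models(
    dredge(df, "response", model_terms_plants(), random_intercept = "plot"),
    delta = delta
  )
  plant_td <- td |>
    dplyr::filter(.data$group %in% pg) |>
    dplyr::transmute(plot = .data$plot,
                     life_stage = factor(.data$group, levels = pg),
                     response = .data[[td_col]])
  models$plants_td <- average_models(
    dredge(make_data(plant_td), "response", model_terms_plants(),
           random_intercept = "plot"),
    delta = delta
  )
  if (has_birds) {
    bird_pd <- ses_tab |>
      dplyr::filter(.data$group == "birds") |>
      dplyr::transmute(plot = .data$plot, response = .data$ses)
    models$birds_pd <- average_models(
      dredge(make_data(bird_pd), "response", model_terms_birds()),
      delta = delta
    )
    bird_td <- td |>
      dplyr::filter(.data$group == "birds") |>
      dplyr::transmute(plot = .data$plot, response = .data[[td_col]])
    models$birds_td <- average_models(
      dredge(make_data(bird_td), "response", model_terms_birds()),
      delta = delta
    )
  }
  coefficients <- purrr::map_dfr(names(models), function(nm) {
    dplyr::mutate(tidy(models[[nm]]), response = nm,
                  n_models = nrow(attr(models[[nm]], "model_table")),
                  n_perm = n_perm, .before = 1)
  })
  structure(
    list(ses = ses_tab, td = td, dispersion = dispersion_summary(ses_tab),
         models = models, coefficients = coefficients),
    class = "alpha_report"
  )
}

#' @export
print.alpha_report <- function(x, ...) {
  cat("Alpha-diversity report\n")
  print(x$dispersion)
  cat("\nAveraged coefficients:\n")
  print(x$coefficients, n = 30)
  invisible(x)
}

# symmetric matrix from a beta SES tibble (one group); NA -> 0 with a note
ses_beta_matrix <- function(ses_tab, plots) {
  m <- matrix(0, length(plots), length(plots), dimnames = list(plots, plots))
  idx1 <- match(ses_tab$plot1, plots)
  idx2 <- match(ses_tab$plot2, plots)
  vals <- ses_tab$ses
  if (anyNA(vals)) {
    inform("Undefined pairwise SES set to 0 for matrix-based analyses.")
    vals[is.na(vals)] <- 0
  }
  m[cbind(idx1, idx2)] <- vals
  m[cbind(idx2, idx1)] <- vals
  m
}

#' Beta-diversity analysis of a dataset bundle
#'
#' @inheritParams run_alpha
#' @param mantel_n_perm permutations for (partial) Mantel tests and the
#'   variation-partitioning fraction tests.
#' @param ses_n_perm tip shuffles behind the pairwise beta SES (the beta-PD
#'   response of the Mantel/variation-partitioning analyses).
#' @param selection_alpha double-stop forward-selection threshold.
#' @return list of class `beta_report`: `mantel` (Table-2-shaped tibble:
#'   group, facet, predictor, r, p), `varpart` (combined fraction tibble),
#'   `varpart_objects`, `pcnm` (the basis), `selected_axes` (per
#'   group/facet).
#' @export
run_beta <- function(bundle, mantel_n_perm = 999, ses_n_perm = 3000,
                     alpha = 0.025, corrected = TRUE,
                     selection_alpha = 0.05,
                     tree_source = c("mean", "single")) {
  tree_source <- match.arg(tree_source)
  axes <- derive_axes(bundle$env)
  scores <- axes$scores
  coords <- dplyr::select(bundle$env, "plot", "easting", "northing")
  d_plant <- regional_distance(bundle, "plant", tree_source)
  has_birds <- "birds" %in% names(bundle$communities)
  if (has_birds) d_bird <- regional_distance(bundle, "bird", tree_source)
  groups <- names(bundle$communities)
  mantel_rows <- list()
  varpart_rows <- list()
  varpart_objects <- list()
  selected_axes <- list()
  pcnm_store <- list()
  for (g in groups) {
    cm <- bundle$communities[[g]]
    plots <- rownames(cm)
    dmat <- if (g == "birds" && has_birds) d_bird else d_plant
    sc <- scores[match(plots, scores$plot), ]
    dd <- gradient_distances(setNames(sc$disturbance, plots))
    dl <- gradient_distances(setNames(sc$loss, plots))
    dsp <- euclidean_plot_distances(coords[match(plots, coords$plot), ])
    pb <- pcnm_basis(dsp)
    pcnm_store[[g]] <- pb
    for (facet in c("td", "pd")) {
      if (facet == "td") {
        bm <- pairwise_beta(cm, taxonomic_distances(colnames(cm)),
                            corrected = corrected)
        bmat <- unclass(bm)
      } else {
        bses <- beta_pd_ses(stats::setNames(list(cm), g), dmat,
                            n_perm = ses_n_perm, alpha = alpha,
                            corrected = corrected)
        bmat <- ses_beta_matrix(bses, plots)
      }
      for (pred in c("disturbance", "loss")) {
        pm <- partial_mantel(bmat, if (pred == "disturbance") dd else dl,
                             dsp, n_perm = mantel_n_perm)
        mantel_rows[[length(mantel_rows) + 1]] <-
          dplyr::mutate(pm, group = g, facet = facet, predictor = pred,
                        .before = 1)
      }
      # variation partitioning: PCNM axes forward-selected per response
      Y <- beta_pcoa(bmat)
      sel <- forward_select(Y, as.data.frame(pb$vectors),
                            alpha = selection_alpha,
                            n_perm = mantel_n_perm)
      selected_axes[[paste(g, facet, sep = "_")]] <- sel
      space <- if (length(sel) > 0) pb$vectors[, sel, drop = FALSE] else NULL
      vp <- variation_partition(bmat, sc$disturbance, sc$loss, space,
                                n_perm = mantel_n_perm)
      varpart_objects[[paste(g, facet, sep = "_")]] <- vp
      varpart_rows[[length(varpart_rows) + 1]] <-
        dplyr::mutate(tidy(vp), group = g, facet = facet,
                      n_space_axes = length(sel), .before = 1)
    }
  }
  structure(
    list(mantel = dplyr::bind_rows(mantel_rows),
         varpart = dplyr::bind_rows(varpart_rows),
         varpart_objects = varpart_objects,
         selected_axes = selected_axes, pcnm = pcnm_store),
    class = "beta_report"
  )
}

#' @export
print.beta_report <- function(x, ...) {
  cat("Beta-diversity report\nPartial Mantel tests:\n")
  print(x$mantel, n = 20)
  cat("\nVariation partitioning (unique fractions):\n")
  print(dplyr::filter(x$varpart, grepl("unique|residual", .data$component)),
        n = 30)
  invisible(x)
}

#' Robustness sweep over a posterior sample of trees
#'
#' Re-runs the phylogeny-dependent alpha statistics (SES + model averaging
#' of the plant alpha-PD regression) and the beta-PD partial Mantel tests
#' for each of `n_sweep` trees from the stored posterior, and summarizes
#' the across-tree distribution of effect sizes.
#'
#' @inheritParams run_beta
#' @param n_sweep number of posterior trees to use (all if fewer).
#' @param ses_n_perm tip shuffles per sweep.
#' @return list of class `sweep_report`: `alpha_terms` (per-term mean/sd of
#'   averaged estimates and p, and inclusion count over sweeps),
#'   `mantel` (per group/predictor mean/sd of r and p), `n_sweep`.
#' @export
posterior_sweep <- function(bundle, n_sweep = 100, ses_n_perm = 500,
                            mantel_n_perm = 199, alpha = 0.025,
                            corrected = TRUE, delta = 2.0) {
  post <- bundle$plant_posterior
  if (is.null(post)) abort("Bundle has no plant posterior.")
  trees <- unclass(post$trees)
  if (length(trees) < n_sweep) {
    warn(paste0("Posterior has only ", length(trees),
                " trees; using all of them."))
    n_sweep <- length(trees)
  }
  pg <- plant_groups(bundle)
  axes <- derive_axes(bundle$env)
  covars <- dplyr::left_join(axes$scores,
                             dplyr::select(bundle$env, "plot", "easting",
                                           "northing"),
                             by = "plot")
  covars <- dplyr::mutate(covars,
                          dplyr::across(c("disturbance", "loss",
                                          "easting", "northing"),
                                        z_transform))
  plots_by_group <- lapply(bundle$communities[pg], rownames)
  dd <- gradient_distances(setNames(covars$disturbance, covars$plot))
  dl <- gradient_distances(setNames(covars$loss, covars$plot))
  dsp <- euclidean_plot_distances(
    dplyr::select(bundle$env, "plot", "easting", "northing"))
  term_rows <- list()
  mantel_rows <- list()
  base_seed <- sample.int(2^30, 1)   # common random numbers across sweeps
  for (s in seq_len(n_sweep)) {
    set.seed(base_seed)
    d_s <- patristic_distances(trees[[s]])
    ses_s <- alpha_pd_ses(bundle$communities[pg], d_s, n_perm = ses_n_perm,
                          alpha = alpha, corrected = corrected)
    df <- ses_s |>
      dplyr::transmute(plot = .data$plot,
                       life_stage = factor(.data$group, levels = pg),
                       response = .data$ses) |>
      dplyr::inner_join(covars, by = "plot")
    df <- df[complete.cases(df$response), ]
    avg <- average_models(
      dredge(df, "response", model_terms_plants(), random_intercept = "plot"),
      delta = delta
    )
    term_rows[[s]] <- dplyr::mutate(tidy(avg), sweep = s)
    for (g in pg) {
      plots <- plots_by_group[[g]]
      bses <- beta_pd_ses(stats::setNames(bundle$communities[g], g), d_s,
                          n_perm = ses_n_perm, alpha = alpha,
                          corrected = corrected)
      bmat <- ses_beta_matrix(bses, plots)
      for (pred in c("disturbance", "loss")) {
        dmx <- if (pred == "disturbance") dd else dl
        pm <- partial_mantel(bmat, dmx[plots, plots], dsp[plots, plots],
                             n_perm = mantel_n_perm)
        mantel_rows[[length(mantel_rows) + 1]] <-
          dplyr::mutate(pm, sweep = s, group = g, predictor = pred,
                        .before = 1)
      }
    }
  }
  terms_all <- dplyr::bind_rows(term_rows)
  alpha_terms <- terms_all |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      estimate_mean = mean(.data$estimate), estimate_sd = sd(.data$estimate),
      p_mean = mean(.data$p), p_sd = sd(.data$p),
      n_included = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(n_sweep = n_sweep)
  mantel_all <- dplyr::bind_rows(mantel_rows)
  mantel_sum <- mantel_all |>
    dplyr::group_by(.data$group, .data$predictor) |>
    dplyr::summarise(r_mean = mean(.data$r), r_sd = sd(.data$r),
                     p_mean = mean(.data$p), p_sd = sd(.data$p),
                     .groups = "drop")
  structure(
    list(alpha_terms = alpha_terms, mantel = mantel_sum, n_sweep = n_sweep),
    class = "sweep_report"
  )
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Posterior sweep over", x$n_sweep, "trees\n")
  print(x$alpha_terms)
  print(x$mantel)
  invisible(x)
}
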