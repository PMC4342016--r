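#' Environmental predictors: heterogeneity, PCA, disturbance/loss axes
#'
#' Plot-level forest characteristics (fragment geometry, vertical biomass
#' profile, canopy cover, light, vegetation heterogeneity, plus two binary
#' dummies for forest type and surrounding matrix) are condensed by a PCA on
#' the correlation matrix. The first two components are interpreted as
#' "forest disturbance" (oriented so that canopy cover loads negatively)
#' and "forest loss" (oriented so that fragment size loads negatively).
#'
#' @name environment_module
NULL

# the variable set entering the PCA, in canonical order
env_pca_vars <- function() {
  c("forest_size", "edge_length", "perimeter_area_ratio",
    paste0("biomass_", c("0.0", "0.5", "1.0", "2.0", "4.0", "8.0", "16")),
    "canopy_cover", "relative_light", "heterogeneity",
    "forest_type_dummy", "matrix_dummy")
}

#' Shannon heterogeneity of a vertical biomass profile
#'
#' H = -sum q_k log q_k over the (typically seven) biomass layers, with
#' q_k the layer's share of total biomass; zero layers contribute nothing.
#' Units: nats.
#'
#' @param biomass_layers non-negative layer values, at least one positive.
#' @return Shannon index.
#' @export
#' @examples
#' shannon_heterogeneity(rep(1, 7))  # log(7)
shannon_heterogeneity <- function(biomass_layers) {
  b <- as.numeric(biomass_layers)
  if (any(b < 0)) abort("Biomass values must be non-negative.")
  tot <- sum(b)
  if (tot == 0) abort("All biomass layers are zero; heterogeneity undefined.")
  q <- b[b > 0] / tot
  -sum(q * log(q))
}

#' PCA on the correlation matrix
#'
#' Columns are standardized, components ordered by decreasing eigenvalue,
#' and each loading column is sign-fixed so its largest-magnitude entry is
#' positive. Score variance per component equals the eigenvalue.
#'
#' @param x numeric matrix or data frame, plots in rows.
#' @return object of class `pca_corr`: list with `loadings` (variables x
#'   components), `eigenvalues`, `explained` (proportions summing to 1),
#'   `scores` (plots x components) and `retained` (broken-stick count).
#' @export
pca_correlation <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("PCA input must be numeric.")
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need >= 2 rows and >= 2 columns.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant columns: ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  explained <- eig / sum(eig)
  bs <- broken_stick(ncol(m))
  retained <- 0L
  for (k in seq_along(explained)) {
    if (explained[k] > bs[k]) retained <- k else break
  }
  structure(
    list(loadings = pc$rotation, eigenvalues = eig, explained = explained,
         scores = pc$x, retained = retained),
    class = "pca_corr"
  )
}

#' @export
print.pca_corr <- function(x, ...) {
  cat("Correlation-matrix PCA:", length(x$eigenvalues), "components;",
      "retained by broken stick:", x$retained, "\n")
  cat("Explained:", paste0(round(100 * x$explained[1:min(5, length(x$explained))], 1),
                           "%", collapse = ", "), "...\n")
  invisible(x)
}

#' @export
tidy.pca_corr <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    explained = x$explained,
    cumulative = cumsum(x$explained),
    broken_stick = broken_stick(length(x$eigenvalues))
  )
}

#' Broken-stick expected eigenvalue proportions
#'
#' b_k = (1/n) sum_{i=k}^{n} 1/i; a component is conventionally retained
#' while its explained proportion exceeds b_k.
#'
#' @param n_vars number of variables.
#' @return proportions per rank (sum to 1).
#' @export
broken_stick <- function(n_vars) {
  if (n_vars < 1) abort("`n_vars` must be >= 1.")
  rev(cumsum(1 / rev(seq_len(n_vars)))) / n_vars
}

#' Derive the forest disturbance and forest loss axes
#'
#' Runs [pca_correlation()] on the 15-column environmental variable set
#' (3 geometry, 7 biomass layers, canopy cover, relative light,
#' heterogeneity, 2 dummies), applies broken-stick retention (advisory; the
#' first two components are always returned because the downstream models
#' require a disturbance and a loss axis), and orients PC1 so canopy cover
#' loads negatively (more disturbance = less canopy) and PC2 so forest size
#' loads negatively (more loss = smaller fragments).
#'
#' @param env environment table with a `plot` column and the variables named
#'   by `env_pca_vars()` (extra columns such as easting/northing ignored).
#' @return list: `scores` (tibble plot, disturbance, loss) and `pca`
#'   (the full `pca_corr`).
#' @export
derive_axes <- function(env) {
  env <- tibble::as_tibble(env)
  vars <- env_pca_vars()
  missing <- setdiff(c("plot", vars), names(env))
  if (length(missing) > 0) {
    abort(paste0("Missing environment columns: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(env[vars])
  rownames(m) <- as.character(env$plot)
  pca <- pca_correlation(m)
  flip <- function(j, var, sign_wanted) {
    if (sign(pca$loadings[var, j]) != sign_wanted && pca$loadings[var, j] != 0) {
      pca$loadings[, j] <<- -pca$loadings[, j]
      pca$scores[, j] <<- -pca$scores[, j]
    }
  }
  flip(1, "canopy_cover", -1)
  flip(2, "forest_size", -1)
  list(
    scores = tibble::tibble(
      plot = as.character(env$plot),
      disturbance = unname(pca$scores[, 1]),
      loss = unname(pca$scores[, 2])
    ),
    pca = pca
  )
}
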