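#' Rao quadratic-entropy diversity
#'
#' Rao's quadratic entropy Q = sum_ij d_ij p_i p_j is the expected
#' dissimilarity between two individuals drawn at random with replacement.
#' With unit dissimilarities it reduces to the Gini-Simpson index (the
#' taxonomic facet, TD); with patristic distances it measures phylogenetic
#' diversity (PD). The "corrected" form first rescales dissimilarities to
#' [0, 1] by the regional maximum and then converts Q to an equivalent
#' number of species 1 / (1 - Q).
#'
#' @name diversity
NULL

# ---- community matrix handling ----------------------------------------------

#' Coerce a community table to a counts matrix
#'
#' Accepts a data frame whose first column (or a column named `plot`) holds
#' plot identifiers and whose remaining columns are per-species counts, or a
#' numeric matrix with plot rownames. Counts must be non-negative.
#'
#' @param x data frame or matrix.
#' @return numeric matrix, plots in rows, species in columns.
#' @export
as_community_matrix <- function(x) {
  if (is.data.frame(x)) {
    idcol <- if ("plot" %in% names(x)) "plot" else names(x)[1]
    m <- as.matrix(x[setdiff(names(x), idcol)])
    rownames(m) <- as.character(x[[idcol]])
  } else if (is.matrix(x)) {
    m <- x
  } else {
    abort("Community table must be a data frame or matrix.")
  }
  if (!is.numeric(m)) abort("Community counts must be numeric.")
  if (any(m < 0)) abort("Community counts must be non-negative.")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("Community matrix needs plot rownames and species colnames.")
  }
  if (anyDuplicated(rownames(m))) abort("Duplicate plot identifiers.")
  if (anyDuplicated(colnames(m))) abort("Duplicate species labels.")
  m
}

# align a counts matrix to the label set of D (species missing from D: error)
align_community <- function(cm, d) {
  cm <- as_community_matrix(cm)
  missing <- setdiff(colnames(cm), colnames(d))
  if (length(missing) > 0) {
    abort(paste0("Species absent from the distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  out <- matrix(0, nrow(cm), ncol(d),
                dimnames = list(rownames(cm), colnames(d)))
  out[, colnames(cm)] <- cm
  out
}

# ---- scalar operations ------------------------------------------------------

#' Rao quadratic entropy of one community
#'
#' @param p relative-abundance vector (must sum to one; normalization is the
#'   caller's explicit step).
#' @param d distance matrix matching `p` in order and length.
#' @return the quadratic entropy sum_ij d_ij p_i p_j.
#' @export
#' @examples
#' rao_entropy(c(0.5, 0.5), taxonomic_distances(c("A", "B")))
rao_entropy <- function(p, d) {
  p <- as.numeric(p)
  if (length(p) != nrow(d)) abort("`p` and `d` dimensions disagree.")
  if (any(p < 0)) abort("Relative abundances must be non-negative.")
  if (abs(sum(p) - 1) > 1e-8) abort("`p` must sum to 1 (normalize first).")
  drop(p %*% d %*% p)
}

#' Equivalent-number transform of Rao Q
#'
#' Converts a Rao quadratic entropy on [0, 1)-scaled dissimilarities into the
#' number of equally abundant, maximally distinct species giving the same Q.
#'
#' @param raw_q Rao Q in `[0, 1)`.
#' @return `1 / (1 - raw_q)`, always >= 1.
#' @export
equivalent_numbers <- function(raw_q) {
  if (any(raw_q < 0) || any(raw_q >= 1)) {
    abort("`raw_q` must lie in [0, 1); rescale dissimilarities to [0, 1] first.")
  }
  1 / (1 - raw_q)
}

#' Abundance-weighted mean pairwise distance (MPD)
#'
#' MPD = sum_{i != j} d_ij p_i p_j / sum_{i != j} p_i p_j. Undefined for a
#' single species.
#'
#' @inheritParams rao_entropy
#' @return weighted mean off-diagonal distance.
#' @export
mpd <- function(p, d) {
  p <- as.numeric(p)
  if (sum(p > 0) < 2) abort("MPD is undefined for fewer than two species.")
  q <- rao_entropy(p / sum(p), d)
  q / (1 - sum((p / sum(p))^2))
}

# ---- vectorized internals ---------------------------------------------------

# Rao Q per plot for a relative-abundance matrix P (plots x species)
rao_alpha_vec <- function(P, d) {
  rowSums((P %*% d) * P)
}

# relative abundances per row; errors on empty rows unless allow_empty
relabund <- function(cm, allow_empty = FALSE) {
  tot <- rowSums(cm)
  if (any(tot == 0)) {
    if (!allow_empty) {
      abort(paste0("Empty plot rows: ",
                   paste(rownames(cm)[tot == 0], collapse = ", ")))
    }
    tot[tot == 0] <- NA_real_
  }
  cm / tot
}

# ---- alpha profile ----------------------------------------------------------

#' Per-plot alpha-diversity profile
#'
#' Normalizes each plot's counts to relative abundances and computes Rao Q;
#' when `corrected = TRUE`, dissimilarities are first rescaled to [0, 1] by
#' the regional maximum of `d` and the equivalent-number transform applied.
#'
#' @param cm community table (see [as_community_matrix()]).
#' @param d species distance matrix covering all species in `cm`.
#' @param corrected apply the [0,1] rescale + equivalent-number correction.
#' @param facet label recorded in the output ("taxonomic"/"phylogenetic");
#'   inferred from `d` when `NULL` (all off-diagonal distances equal 1 is
#'   taken as taxonomic).
#' @return tibble: plot, facet, n_species, raw_q, corrected (equivalent
#'   numbers; `NA` when `corrected = FALSE`).
#' @export
alpha_profile <- function(cm, d, corrected = TRUE, facet = NULL) {
  d <- as_distance_matrix(d)
  P <- relabund(align_community(cm, d))
  if (is.null(facet)) {
    off <- d[upper.tri(d)]
    facet <- if (all(abs(off - 1) < 1e-12)) "taxonomic" else "phylogenetic"
  }
  dmax <- max(d)
  duse <- if (corrected && dmax > 0) d / dmax else d
  q <- rao_alpha_vec(P, duse)
  tibble::tibble(
    plot = rownames(P),
    facet = facet,
    n_species = as.integer(rowSums(P > 0)),
    raw_q = unname(q),
    corrected = if (corrected) unname(equivalent_numbers(q)) else NA_real_
  )
}

# ---- pairwise beta ----------------------------------------------------------

# all pairwise pooled Rao Q via the cross-product trick:
# Qpool(i,j) = (M_ii + 2 M_ij + M_jj) / (N_i + N_j)^2 with M = C d C'
beta_matrix_impl <- function(C, d, corrected, pooling) {
  n <- nrow(C)
  tot <- rowSums(C)
  W <- if (pooling == "counts") C else C / tot   # equal weight: pool p vectors
  wtot <- rowSums(W)
  M <- W %*% d %*% t(W)
  Qa <- diag(M) / wtot^2                         # per-plot alpha Q
  Tw <- outer(wtot, wtot, `+`)
  Qpool <- (outer(diag(M), diag(M), `+`) + 2 * M) / Tw^2
  if (corrected) {
    Ga <- equivalent_numbers(pmin(Qpool, 1 - 1e-12))
    Aa <- equivalent_numbers(pmin(Qa, 1 - 1e-12))
    amean <- (outer(Aa, Aa, `+`)) / 2
    beta_prop <- (Ga - amean) / Ga
    beta <- beta_prop / (1 - 1 / 2) * 100        # two-community maximum
  } else {
    amean <- (outer(Qa, Qa, `+`)) / 2
    beta <- ifelse(Qpool > 0, (Qpool - amean) / Qpool * 100, 0)
  }
  diag(beta) <- 0
  beta <- pmax(beta, 0)
  dimnames(beta) <- list(rownames(C), rownames(C))
  beta
}

#' Pairwise beta-diversity matrix
#'
#' For each pair of plots, the pooled (gamma) and mean per-plot (alpha) Rao
#' diversities are multiplicatively partitioned:
#' beta = (gamma_pair - alpha_mean) / gamma_pair x 100.
#' With `corrected = TRUE` the equivalent-number transform is applied to
#' gamma and both alphas first and beta is divided by its two-community
#' maximum (1/2), keeping the 0-100 scale.
#'
#' @inheritParams alpha_profile
#' @param pooling "counts" pools raw counts (plots weighted by sampling
#'   effort); "equal" averages the two relative-abundance vectors.
#' @return a `beta_matrix`: symmetric plot x plot matrix of beta percentages
#'   with attributes `facet`, `corrected`, `pooling`.
#' @export
pairwise_beta <- function(cm, d, corrected = TRUE, facet = NULL,
                          pooling = c("counts", "equal")) {
  pooling <- match.arg(pooling)
  d <- as_distance_matrix(d)
  C <- align_community(cm, d)
  if (nrow(C) < 2) abort("Need at least two plots.")
  if (any(rowSums(C) == 0)) {
    abort(paste0("Empty plot rows: ",
                 paste(rownames(C)[rowSums(C) == 0], collapse = ", ")))
  }
  if (is.null(facet)) {
    off <- d[upper.tri(d)]
    facet <- if (all(abs(off - 1) < 1e-12)) "taxonomic" else "phylogenetic"
  }
  dmax <- max(d)
  duse <- if (corrected && dmax > 0) d / dmax else d
  beta <- beta_matrix_impl(C, duse, corrected, pooling)
  if (!corrected) {
    P <- relabund(C)
    gz <- rao_alpha_vec(P, duse) == 0
    if (sum(gz) >= 2) {
      inform("Some plot pairs have zero pooled diversity; their beta is set to 0.")
    }
  }
  structure(beta, class = c("beta_matrix", class(beta)),
            facet = facet, corrected = corrected, pooling = pooling)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Pairwise beta-diversity (", attr(x, "facet"),
      if (isTRUE(attr(x, "corrected"))) ", corrected" else ", uncorrected",
      "): ", nrow(x), " plots\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' @export
tidy.beta_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    plot1 = rownames(m)[idx[, 1]],
    plot2 = colnames(m)[idx[, 2]],
    beta = m[idx],
    facet = attr(x, "facet"),
    corrected = attr(x, "corrected")
  )
}
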