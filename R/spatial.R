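#' Landscape-scale beta-diversity statistics
#'
#' Mantel and partial Mantel tests relate pairwise beta-diversity to
#' environmental and spatial distances; PCNM eigenvectors plus double-stop
#' forward selection provide a spatial predictor basis; and three-set
#' variation partitioning decomposes beta-diversity variance (via
#' distance-based RDA on principal coordinates) into unique and joint
#' adjusted-R-squared fractions of disturbance, loss and space.
#'
#' @name spatial_module
NULL

#' Euclidean plot-to-plot distances
#'
#' @param coords data frame with columns `plot`, `easting`, `northing`
#'   (metres), or a two-column matrix with plot rownames.
#' @return labelled distance matrix (duplicate coordinates allowed).
#' @export
euclidean_plot_distances <- function(coords) {
  if (is.data.frame(coords)) {
    m <- as.matrix(coords[c("easting", "northing")])
    rownames(m) <- as.character(coords$plot)
  } else {
    m <- as.matrix(coords)
  }
  if (nrow(m) < 2) abort("Need at least two plots.")
  d <- as.matrix(dist(m))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Distance matrix of absolute differences in a plot-level variable
#'
#' Builds the |x_i - x_j| matrix used as the "environmental distance" in
#' Mantel tests (e.g. differences in forest disturbance scores).
#'
#' @param x named numeric vector (names = plots) or data frame with columns
#'   `plot` and `value`.
#' @return labelled distance matrix.
#' @export
gradient_distances <- function(x) {
  if (is.data.frame(x)) x <- setNames(x[[2]], as.character(x[[1]]))
  d <- abs(outer(x, x, `-`))
  dimnames(d) <- list(names(x), names(x))
  d
}

lower_vec <- function(m) m[lower.tri(m)]

align_plots <- function(...) {
  mats <- list(...)
  plots <- rownames(mats[[1]])
  lapply(mats, function(m) {
    if (!setequal(rownames(m), plots)) abort("Distance matrices disagree on plots.")
    m[plots, plots]
  })
}

#' Mantel test
#'
#' Pearson correlation of the vectorized lower triangles of two distance
#' matrices; significance by random row/column permutation of `a`.
#'
#' @param a,b square distance matrices over the same plots.
#' @param n_perm number of permutations (>= 99).
#' @param alternative "greater" (default) or "two.sided".
#' @return tibble: r, p, n_perm, alternative.
#' @export
mantel_test <- function(a, b, n_perm = 999,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("Use at least 99 permutations.")
  al <- align_plots(a, b)
  a <- al[[1]]; b <- al[[2]]
  va <- lower_vec(a); vb <- lower_vec(b)
  if (sd(va) == 0 || sd(vb) == 0) abort("Zero-variance distance matrix.")
  r <- cor(va, vb)
  n <- nrow(a)
  rp <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(lower_vec(a[p, p]), vb)
  }, numeric(1))
  p <- switch(alternative,
    greater = mean(rp >= r),
    two.sided = mean(abs(rp) >= abs(r))
  )
  tibble::tibble(r = r, p = p, n_perm = n_perm, alternative = alternative)
}

partial_r <- function(rab, rac, rbc) {
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Partial Mantel test
#'
#' First-order partial correlation of `a` and `b` conditioned on `c`,
#' r_ab|c = (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2)); the
#' permutation null permutes rows/columns of `a` (with `b`, `c` fixed) and
#' recomputes the partial statistic.
#'
#' @inheritParams mantel_test
#' @param c conditioning distance matrix (e.g. spatial distances).
#' @return tibble: r, p, n_perm, alternative.
#' @export
partial_mantel <- function(a, b, c, n_perm = 999,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("Use at least 99 permutations.")
  al <- align_plots(a, b, c)
  a <- al[[1]]; b <- al[[2]]; cc <- al[[3]]
  va <- lower_vec(a); vb <- lower_vec(b); vc <- lower_vec(cc)
  if (sd(va) == 0 || sd(vb) == 0 || sd(vc) == 0) {
    abort("Zero-variance distance matrix.")
  }
  if (isTRUE(all.equal(vb, vc))) {
    # conditioning b on itself: the partial correlation vanishes by
    # construction and no permutation null is informative
    return(tibble::tibble(r = 0, p = NA_real_, n_perm = n_perm,
                          alternative = alternative))
  }
  rbc <- cor(vb, vc)
  rac <- cor(va, vc)
  if (abs(rac) >= 1 - 1e-12 || abs(rbc) >= 1 - 1e-12) {
    abort("Degenerate conditioning: |correlation with c| = 1.")
  }
  r <- partial_r(cor(va, vb), rac, rbc)
  n <- nrow(a)
  rp <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    vap <- lower_vec(a[p, p])
    partial_r(cor(vap, vb), cor(vap, vc), rbc)
  }, numeric(1))
  p <- switch(alternative,
    greater = mean(rp >= r),
    two.sided = mean(abs(rp) >= abs(r))
  )
  tibble::tibble(r = r, p = p, n_perm = n_perm, alternative = alternative)
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: the plot distance matrix is
#' truncated at the longest minimum-spanning-tree edge (entries beyond it
#' replaced by 4x the threshold), double-centered, and eigen-decomposed;
#' positive-eigenvalue eigenvectors (unit norm, ordered by eigenvalue) form
#' a multi-scale spatial predictor basis.
#'
#' @param d plot distance matrix (from [euclidean_plot_distances()]).
#' @param truncation distance threshold; `NULL` for the automatic MST rule.
#' @return object of class `pcnm_basis`: list with `vectors` (plots x axes),
#'   `values` (positive eigenvalues), `truncation`.
#' @export
pcnm_basis <- function(d, truncation = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("Need at least three plots.")
  if (max(d) == 0) abort("All plots identical; PCNM undefined.")
  res <- if (is.null(truncation)) vegan::pcnm(as.dist(d))
         else vegan::pcnm(as.dist(d), threshold = truncation)
  vec <- res$vectors
  rownames(vec) <- rownames(d)
  structure(
    list(vectors = vec, values = res$values[seq_len(ncol(vec))],
         truncation = res$threshold),
    class = "pcnm_basis"
  )
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat("PCNM basis:", ncol(x$vectors), "positive-eigenvalue axes,",
      "truncation", signif(x$truncation, 4), "\n")
  invisible(x)
}

#' Double-stop forward selection of predictors for an RDA
#'
#' Forward selection on a redundancy analysis of `y` on the candidate
#' columns with a double stopping rule: selection starts only if the
#' full-candidate model is itself significant at `alpha`; at each step the
#' candidate adding the most explained variance is admitted only if its
#' residual-permutation F-test p-value is <= `alpha`; and selection stops
#' once the cumulative adjusted R-squared of the selected model reaches
#' that of the full-candidate model (the admitted candidate that crosses
#' the ceiling is retained, so a single dominant predictor is still
#' selected). May return an empty selection.
#'
#' @param y numeric response matrix (rows = plots), centered internally.
#' @param candidates data frame or matrix of candidate predictors.
#' @param alpha significance threshold (default 0.05).
#' @param n_perm permutations for the selection tests.
#' @return integer vector of selected candidate column indices (possibly
#'   empty), with the candidate names as names.
#' @export
forward_select <- function(y, candidates, alpha = 0.05, n_perm = 999) {
  Y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  cand <- as.data.frame(candidates)
  if (ncol(cand) < 1) abort("Need at least one candidate.")
  X <- as.matrix(cand)
  n <- nrow(Y)
  p_all <- qr(scale(X, scale = FALSE))$rank
  if (p_all >= n - 1) abort("Too many candidates: p must be < n - 1.")
  # global double-stop prerequisite
  pg <- partial_rda_test(Y, X, NULL, n_perm)
  if (is.na(pg) || pg > alpha) return(integer(0))
  r2_global <- ezekiel(rda_r2(Y, X), n, p_all)
  chosen <- integer(0)
  remaining <- seq_len(ncol(X))
  repeat {
    if (length(remaining) == 0) break
    x0 <- if (length(chosen)) X[, chosen, drop = FALSE] else NULL
    added <- vapply(remaining, function(j) {
      rda_r2(Y, cbind(x0, X[, j]))
    }, numeric(1))
    best <- remaining[which.max(added)]
    pj <- partial_rda_test(Y, X[, best, drop = FALSE], x0, n_perm)
    if (is.na(pj) || pj > alpha) break
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    r2_cum <- ezekiel(rda_r2(Y, X[, chosen, drop = FALSE]), n,
                      length(chosen))
    if (r2_cum >= r2_global) break
  }
  setNames(chosen, names(cand)[chosen])
}

# principal coordinates of a beta (dissimilarity) matrix; Lingoes correction
# adds a constant to off-diagonal squared distances when negative
# eigenvalues occur.
beta_pcoa <- function(beta, correction = c("lingoes", "none")) {
  correction <- match.arg(correction)
  m <- as.matrix(unclass(beta))
  n <- nrow(m)
  center <- function(d2) {
    J <- diag(n) - matrix(1 / n, n, n)
    -0.5 * J %*% d2 %*% J
  }
  G <- center(m^2)
  e <- eigen(G, symmetric = TRUE)
  if (correction == "lingoes" && min(e$values) < -1e-8 * max(abs(e$values))) {
    c1 <- -min(e$values)
    d2 <- m^2 + 2 * c1
    diag(d2) <- 0
    G <- center(d2)
    e <- eigen(G, symmetric = TRUE)
  }
  keep <- which(e$values > 1e-8 * max(e$values))
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(m)
  coords
}

# R^2 of a multivariate regression of (centered) Y on design X
rda_r2 <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- as.matrix(X)
  qrx <- qr(cbind(1, X))
  fitted <- qr.fitted(qrx, Y)
  sum(fitted^2) / sum(Y^2)
}

ezekiel <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Distance-based RDA R-squared of a beta matrix on predictors
#'
#' Principal-coordinate decomposition of the beta-diversity matrix (Lingoes
#' correction for negative eigenvalues by default) followed by a redundancy
#' analysis of the coordinates on `x`; R-squared is the explained inertia
#' fraction, adjusted by Ezekiel's formula
#' 1 - (1 - R2)(n - 1)/(n - p - 1).
#'
#' @param beta `beta_matrix` (or any symmetric dissimilarity matrix).
#' @param x predictor matrix/data frame (rows matching the plots).
#' @param correction PCoA negative-eigenvalue handling.
#' @return tibble: r2, adj_r2, n, p.
#' @export
dbrda_r2 <- function(beta, x, correction = c("lingoes", "none")) {
  coords <- beta_pcoa(beta, match.arg(correction))
  X <- as.matrix(as.data.frame(x))
  n <- nrow(coords)
  p <- qr(scale(X, scale = FALSE))$rank
  if (p >= n - 1) abort("Too many predictors: p must be < n - 1.")
  r2 <- rda_r2(coords, X)
  tibble::tibble(r2 = r2, adj_r2 = ezekiel(r2, n, p), n = n, p = p)
}

# permutation test for the added effect of X1 given conditioning set X0
# (residuals-of-reduced-model permutation); returns p-value.
partial_rda_test <- function(Y, X1, X0 = NULL, n_perm = 999) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  if (is.null(X0) || ncol(as.matrix(X0)) == 0) {
    Fc <- matrix(0, n, ncol(Y))
    Rc <- Y
    r2_reduced <- function(Yp) 0
    p0 <- 0
  } else {
    X0 <- as.matrix(X0)
    qr0 <- qr(cbind(1, X0))
    Fc <- qr.fitted(qr0, Y)
    Rc <- qr.resid(qr0, Y)
    r2_reduced <- function(Yp) rda_r2(Yp, X0)
    p0 <- qr(scale(X0, scale = FALSE))$rank
  }
  X1 <- as.matrix(X1)
  Xfull <- if (p0 > 0) cbind(X0, X1) else X1
  p1 <- qr(scale(as.matrix(Xfull), scale = FALSE))$rank - p0
  pf <- p0 + p1
  stat <- function(Yp) {
    rf <- rda_r2(Yp, Xfull)
    rr <- r2_reduced(Yp)
    ((rf - rr) / p1) / ((1 - rf) / (n - 1 - pf))
  }
  f_obs <- stat(Y)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    stat(Fc + Rc[sample.int(n), , drop = FALSE])
  }, numeric(1))
  mean(f_perm >= f_obs)
}

#' Three-set variation partitioning of beta-diversity
#'
#' Fits the seven marginal distance-based RDA models (each predictor set
#' alone, each pair, all three), converts them to Ezekiel-adjusted
#' R-squared, and solves for the Venn fractions by inclusion-exclusion:
#' unique fractions of disturbance, loss and space, the pairwise and triple
#' joint fractions, and the residual. Unique fractions are tested by
#' partial db-RDA permutation tests. An empty space set contributes zero
#' fractions.
#'
#' @param beta `beta_matrix` over the plots.
#' @param disturbance,loss per-plot numeric vectors (plot order matching
#'   `beta`).
#' @param space matrix of selected spatial eigenvectors (possibly 0
#'   columns or `NULL`).
#' @param n_perm permutations for the fraction tests.
#' @param correction PCoA negative-eigenvalue handling.
#' @return object of class `varpart_rao`: tibble of fractions (component,
#'   adj_r2, p where testable) with attributes `r2_table` and `n`.
#' @export
variation_partition <- function(beta, disturbance, loss, space = NULL,
                                n_perm = 999,
                                correction = c("lingoes", "none")) {
  correction <- match.arg(correction)
  Y <- beta_pcoa(beta, correction)
  n <- nrow(Y)
  X1 <- matrix(as.numeric(disturbance), ncol = 1,
               dimnames = list(NULL, "disturbance"))
  X2 <- matrix(as.numeric(loss), ncol = 1, dimnames = list(NULL, "loss"))
  X3 <- if (is.null(space)) matrix(numeric(0), nrow = n, ncol = 0)
        else as.matrix(space)
  has_space <- ncol(X3) > 0
  adj <- function(X) {
    X <- as.matrix(X)
    if (ncol(X) == 0) return(0)
    p <- qr(scale(X, scale = FALSE))$rank
    ezekiel(rda_r2(Y, X), n, p)
  }
  R1 <- adj(X1); R2 <- adj(X2); R3 <- adj(X3)
  R12 <- adj(cbind(X1, X2))
  R13 <- if (has_space) adj(cbind(X1, X3)) else R1
  R23 <- if (has_space) adj(cbind(X2, X3)) else R2
  R123 <- if (has_space) adj(cbind(X1, X2, X3)) else R12
  a <- R123 - R23
  b <- R123 - R13
  c_ <- if (has_space) R123 - R12 else 0
  d <- R123 - R3 - a - b
  e <- if (has_space) R123 - R1 - b - c_ else 0
  f <- if (has_space) R123 - R2 - a - c_ else 0
  g <- R1 - a - d - f
  resid_frac <- 1 - R123
  p_a <- partial_rda_test(Y, X1, if (has_space) cbind(X2, X3) else X2, n_perm)
  p_b <- partial_rda_test(Y, X2, if (has_space) cbind(X1, X3) else X1, n_perm)
  p_c <- if (has_space) partial_rda_test(Y, X3, cbind(X1, X2), n_perm) else NA_real_
  p_tot <- partial_rda_test(Y, if (has_space) cbind(X1, X2, X3)
                               else cbind(X1, X2), NULL, n_perm)
  fractions <- tibble::tibble(
    component = c("disturbance_unique", "loss_unique", "space_unique",
                  "disturbance_loss_joint", "loss_space_joint",
                  "disturbance_space_joint", "triple_joint",
                  "total_explained", "residual"),
    adj_r2 = c(a, b, c_, d, e, f, g, R123, resid_frac),
    p = c(p_a, p_b, p_c, NA, NA, NA, NA, p_tot, NA)
  )
  structure(fractions, class = c("varpart_rao", class(fractions)),
            r2_table = tibble::tibble(
              set = c("X1", "X2", "X3", "X12", "X13", "X23", "X123"),
              adj_r2 = c(R1, R2, R3, R12, R13, R23, R123)
            ),
            n = n, has_space = has_space)
}

#' @export
tidy.varpart_rao <- function(x, ...) tibble::as_tibble(unclass(x))
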