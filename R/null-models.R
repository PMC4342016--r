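#' Tip-shuffle null models and standardized effect sizes
#'
#' The null model randomizes the mapping between species identities and tree
#' tips: labels are shuffled uniformly across the tips of the regional
#' phylogeny, which co-permutes rows and columns of the patristic distance
#' matrix while leaving community abundances, per-plot richness and the
#' multiset of distances untouched. Observed phylogenetic diversity is then
#' standardized as SES = (OBS - mean(EXP)) / sd(EXP), with sd the sample
#' (n - 1) standard deviation. Classification uses the null tail
#' frequencies at a per-tail level `alpha` (default 0.025): overdispersed
#' when the fraction of null values >= observed is below `alpha`,
#' underdispersed when the fraction <= observed is below `alpha`. Ties count
#' toward both tails; the observed value is not added to the null set.
#'
#' @name nullmodels
NULL

#' Shuffle species labels across a distance matrix
#'
#' @param d distance matrix.
#' @param perm optional integer permutation of `seq_len(nrow(d))`; drawn
#'   uniformly at random when `NULL`.
#' @return distance matrix with the same labels but co-permuted values.
#' @export
shuffle_tip_labels <- function(d, perm = NULL) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (is.null(perm)) perm <- sample.int(n)
  out <- d[perm, perm]
  dimnames(out) <- dimnames(d)
  out
}

classify_ses <- function(ses, p_high, p_low, alpha) {
  dplyr::case_when(
    is.na(ses) ~ "undefined",
    p_high < alpha ~ "overdispersed",
    p_low < alpha ~ "underdispersed",
    TRUE ~ "random"
  )
}

#' Standardized effect size against a null distribution
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of null statistics (length >= 2).
#' @param alpha per-tail significance level for classification.
#' @return one-row tibble: observed, null_mean, null_sd, ses, p_high, p_low,
#'   n_perm, classification. `ses` is `NA` (classification "undefined") when
#'   the null standard deviation is zero.
#' @export
ses <- function(observed, null_values, alpha = 0.025) {
  null_values <- as.numeric(null_values)
  if (length(null_values) < 2) abort("Need at least two null values.")
  m <- mean(null_values)
  s <- sd(null_values)
  z <- if (s > 0) (observed - m) / s else NA_real_
  p_high <- mean(null_values >= observed)
  p_low <- mean(null_values <= observed)
  tibble::tibble(
    observed = observed, null_mean = m, null_sd = s, ses = z,
    p_high = p_high, p_low = p_low, n_perm = length(null_values),
    classification = classify_ses(z, p_high, p_low, alpha)
  )
}

# normalize `groups` to a named list of aligned count matrices
align_groups <- function(groups, d) {
  if (!is.list(groups) || is.data.frame(groups)) groups <- list(community = groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  out <- lapply(groups, align_community, d = d)
  for (g in names(out)) {
    empty <- rowSums(out[[g]]) == 0
    if (any(empty)) {
      abort(paste0("Empty plot rows in group ", g, ": ",
                   paste(rownames(out[[g]])[empty], collapse = ", ")))
    }
  }
  out
}

# observed + null alpha statistics for one metric under shared tip shuffles.
# Returns per group: obs vector and running null summaries.
alpha_null_engine <- function(Cs, d, n_perm, metric, corrected) {
  dmax <- max(d)
  duse <- if (corrected && dmax > 0) d / dmax else d
  stat <- function(C, dm) {
    P <- relabund(C, allow_empty = TRUE)
    q <- rao_alpha_vec(P, dm)
    if (metric == "mpd") {
      denom <- 1 - rowSums(P^2)
      q <- ifelse(rowSums(C > 0) >= 2, q / denom, NA_real_)
    } else if (corrected) {
      q <- equivalent_numbers(pmin(q, 1 - 1e-12))
    }
    q
  }
  obs <- lapply(Cs, stat, dm = duse)
  acc <- lapply(obs, function(o) {
    list(sum = 0 * o, sumsq = 0 * o, ge = 0 * o, le = 0 * o)
  })
  n <- nrow(d)
  for (it in seq_len(n_perm)) {
    perm <- sample.int(n)
    for (g in seq_along(Cs)) {
      null_g <- stat(Cs[[g]][, perm, drop = FALSE], duse)
      a <- acc[[g]]
      a$sum <- a$sum + null_g
      a$sumsq <- a$sumsq + null_g^2
      a$ge <- a$ge + as.numeric(null_g >= obs[[g]])
      a$le <- a$le + as.numeric(null_g <= obs[[g]])
      acc[[g]] <- a
    }
  }
  list(obs = obs, acc = acc)
}

ses_from_acc <- function(obs, a, n_perm, alpha) {
  m <- a$sum / n_perm
  s <- sqrt(pmax(a$sumsq - n_perm * m^2, 0) / (n_perm - 1))
  # a null that is constant up to floating noise has no defined SES; the
  # running-sums variance has a cancellation floor near m * sqrt(eps)
  degenerate <- s <= 1e-6 * pmax(abs(m), 1)
  z <- ifelse(is.na(obs) | degenerate, NA_real_, (obs - m) / s)
  p_high <- a$ge / n_perm
  p_low <- a$le / n_perm
  tibble::tibble(
    observed = unname(obs), null_mean = unname(m), null_sd = unname(s),
    ses = unname(z), p_high = unname(p_high), p_low = unname(p_low),
    n_perm = n_perm,
    classification = classify_ses(z, p_high, p_low, alpha)
  )
}

#' SES of per-plot phylogenetic alpha-diversity
#'
#' Standardizes each plot's alpha-PD (corrected Rao by default, or
#' abundance-weighted MPD) against tip shuffles of the regional distance
#' matrix. By default one shuffle per iteration is shared across all species
#' groups so cross-group comparisons see a common null
#' (`shared_shuffle = FALSE` draws independent shuffles per group).
#'
#' @param groups a community table or named list of community tables (one
#'   per species group / life stage). All species must be present in
#'   `regional_d`.
#' @param regional_d regional species distance matrix (the pooled phylogeny
#'   of all groups).
#' @param n_perm number of tip shuffles; defaults to 3000 for Rao and 999
#'   for MPD.
#' @param alpha per-tail dispersion level.
#' @param metric "rao" (corrected Rao alpha) or "mpd".
#' @param corrected equivalent-number correction (Rao metric only).
#' @param shared_shuffle share one shuffle per iteration across groups.
#' @return tibble with one row per group x plot: group, plot, observed,
#'   null_mean, null_sd, ses, p_high, p_low, n_perm, classification.
#' @export
alpha_pd_ses <- function(groups, regional_d, n_perm = NULL, alpha = 0.025,
                         metric = c("rao", "mpd"), corrected = TRUE,
                         shared_shuffle = TRUE) {
  metric <- match.arg(metric)
  if (is.null(n_perm)) n_perm <- if (metric == "mpd") 999 else 3000
  d <- as_distance_matrix(regional_d)
  Cs <- align_groups(groups, d)
  run <- function(cset) alpha_null_engine(cset, d, n_perm, metric, corrected)
  res <- if (shared_shuffle) run(Cs) else NULL
  out <- purrr::map_dfr(seq_along(Cs), function(g) {
    eng <- if (shared_shuffle) res else run(Cs[g])
    gi <- if (shared_shuffle) g else 1
    dplyr::bind_cols(
      tibble::tibble(group = names(Cs)[g], plot = rownames(Cs[[g]])),
      ses_from_acc(eng$obs[[gi]], eng$acc[[gi]], n_perm, alpha)
    )
  })
  class(out) <- c("ses_result", class(out))
  attr(out, "metric") <- metric
  attr(out, "level") <- "alpha"
  attr(out, "alpha") <- alpha
  attr(out, "shared_shuffle") <- shared_shuffle
  out
}

#' SES of pairwise phylogenetic beta-diversity
#'
#' Observed pairwise beta (multiplicative Rao partition) standardized
#' against the same tip-shuffle null as [alpha_pd_ses()].
#'
#' @inheritParams alpha_pd_ses
#' @inheritParams pairwise_beta
#' @return tibble with one row per group x plot pair.
#' @export
beta_pd_ses <- function(groups, regional_d, n_perm = 3000, alpha = 0.025,
                        corrected = TRUE, pooling = "counts",
                        shared_shuffle = TRUE) {
  d <- as_distance_matrix(regional_d)
  Cs <- align_groups(groups, d)
  dmax <- max(d)
  duse <- if (corrected && dmax > 0) d / dmax else d
  ut <- function(m) m[upper.tri(m)]
  pair_ids <- lapply(Cs, function(C) {
    idx <- which(upper.tri(diag(nrow(C))), arr.ind = TRUE)
    tibble::tibble(plot1 = rownames(C)[idx[, 1]], plot2 = rownames(C)[idx[, 2]])
  })
  obs <- lapply(Cs, function(C) ut(beta_matrix_impl(C, duse, corrected, pooling)))
  acc <- lapply(obs, function(o) list(sum = 0 * o, sumsq = 0 * o,
                                      ge = 0 * o, le = 0 * o))
  n <- nrow(d)
  draw <- function() sample.int(n)
  for (it in seq_len(n_perm)) {
    perm <- if (shared_shuffle) draw() else NULL
    for (g in seq_along(Cs)) {
      pg <- if (shared_shuffle) perm else draw()
      null_g <- ut(beta_matrix_impl(Cs[[g]][, pg, drop = FALSE], duse,
                                    corrected, pooling))
      a <- acc[[g]]
      a$sum <- a$sum + null_g
      a$sumsq <- a$sumsq + null_g^2
      a$ge <- a$ge + as.numeric(null_g >= obs[[g]])
      a$le <- a$le + as.numeric(null_g <= obs[[g]])
      acc[[g]] <- a
    }
  }
  out <- purrr::map_dfr(seq_along(Cs), function(g) {
    dplyr::bind_cols(
      tibble::tibble(group = names(Cs)[g]), pair_ids[[g]],
      ses_from_acc(obs[[g]], acc[[g]], n_perm, alpha)
    )
  })
  class(out) <- c("ses_result", class(out))
  attr(out, "metric") <- "rao"
  attr(out, "level") <- "beta"
  attr(out, "alpha") <- alpha
  attr(out, "shared_shuffle") <- shared_shuffle
  out
}

#' Tabulate dispersion classifications
#'
#' @param results a tibble from [alpha_pd_ses()] or [beta_pd_ses()].
#' @return tibble of counts per group and classification, with all four
#'   classes always present.
#' @export
dispersion_summary <- function(results) {
  lev <- c("overdispersed", "underdispersed", "random", "undefined")
  if (nrow(results) == 0) {
    return(tibble::tibble(group = character(),
                          classification = character(), n = integer()))
  }
  results |>
    dplyr::mutate(classification = factor(.data$classification, levels = lev)) |>
    dplyr::count(.data$group, .data$classification, .drop = FALSE) |>
    dplyr::mutate(classification = as.character(.data$classification)) |>
    tibble::as_tibble()
}
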