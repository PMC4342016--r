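# shared fixture builders; everything generated in code under fixed seeds

random_distance_matrix <- function(n, labels = sprintf("sp%02d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

random_counts <- function(n_plots, n_species, lambda = 4,
                          species = sprintf("sp%02d", seq_len(n_species))) {
  m <- matrix(rpois(n_plots * n_species, lambda), n_plots, n_species,
              dimnames = list(sprintf("p%02d", seq_len(n_plots)), species))
  # guarantee no empty plot row
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  m
}

# brute-force double-loop Rao Q (independent of the matrix-algebra path)
rao_loop <- function(p, d) {
  s <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    s <- s + d[i, j] * p[i] * p[j]
  }
  unname(s)
}

# brute-force abundance-weighted MPD
mpd_loop <- function(p, d) {
  p <- p / sum(p)
  num <- den <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i != j) {
      num <- num + d[i, j] * p[i] * p[j]
      den <- den + p[i] * p[j]
    }
  }
  unname(num / den)
}

lower_vec <- function(m) m[lower.tri(m)]
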