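test_that("rao_entropy handles the minimal cases and rejects bad input", {
  d2 <- taxonomic_distances(c("A", "B"))
  expect_equal(rao_entropy(c(0.5, 0.5), d2), 0.5)
  expect_equal(rao_entropy(1, taxonomic_distances("A")), 0)
  d2p <- d2 * 3
  expect_equal(rao_entropy(c(0.5, 0.5), d2p), 1.5)
  expect_error(rao_entropy(c(0.5, 0.4), d2), "sum to 1")
  expect_error(rao_entropy(c(1.5, -0.5), d2), "non-negative")
})

test_that("Rao with unit distances is the Gini-Simpson index", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    p <- runif(k); p <- p / sum(p)
    q <- rao_entropy(p, taxonomic_distances(letters[1:k]))
    expect_equal(q, 1 - sum(p^2), tolerance = 1e-12)
  }
})

test_that("equivalent numbers behave as effective species counts", {
  expect_equal(equivalent_numbers(0), 1)
  expect_equal(equivalent_numbers(0.5), 2)
  for (k in 2:10) {
    q <- 1 - 1 / k  # k even, maximally distinct species
    expect_equal(equivalent_numbers(q), k, tolerance = 1e-12)
  }
  expect_error(equivalent_numbers(1), "\\[0, 1\\)")
  expect_error(equivalent_numbers(-0.1), "\\[0, 1\\)")
})

test_that("rao_entropy is bounded and permutation-invariant", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    d <- random_distance_matrix(n)
    p <- runif(n); p <- p / sum(p)
    q <- rao_entropy(p, d)
    expect_gte(q, 0)
    expect_lte(q, max(d))
    perm <- sample(n)
    expect_equal(rao_entropy(p[perm], d[perm, perm]), q, tolerance = 1e-12)
  }
})

test_that("alpha_profile matches the double-loop oracle", {
  set.seed(3)
  cm <- random_counts(10, 15)
  d <- random_distance_matrix(15, colnames(cm))
  prof <- alpha_profile(cm, d, corrected = FALSE)
  for (i in seq_len(nrow(cm))) {
    p <- cm[i, ] / sum(cm[i, ])
    expect_equal(prof$raw_q[i], rao_loop(p, d), tolerance = 1e-9)
  }
  # corrected applies the [0,1] rescale then equivalent numbers
  prof_c <- alpha_profile(cm, d, corrected = TRUE)
  for (i in seq_len(nrow(cm))) {
    p <- cm[i, ] / sum(cm[i, ])
    q <- rao_loop(p, d / max(d))
    expect_equal(prof_c$corrected[i], 1 / (1 - q), tolerance = 1e-9)
  }
})

test_that("alpha_profile simple cases and errors", {
  cm <- rbind(p1 = c(a = 5, b = 5), p2 = c(a = 3, b = 0))
  d <- taxonomic_distances(c("a", "b"))
  prof <- alpha_profile(cm, d, corrected = TRUE)
  expect_equal(prof$raw_q, c(0.5, 0))
  expect_equal(prof$corrected, c(2, 1))
  expect_equal(prof$n_species, c(2L, 1L))
  cm_bad <- rbind(p1 = c(a = 1, b = 1), p2 = c(a = 0, b = 0))
  expect_error(alpha_profile(cm_bad, d), "p2")
  cm_extra <- rbind(p1 = c(a = 1, x = 1))
  expect_error(alpha_profile(cm_extra, d), "absent from the distance matrix")
})

test_that("pairwise beta: identical plots give 0, disjoint monocultures 100", {
  d <- taxonomic_distances(c("a", "b"))
  cm <- rbind(p1 = c(a = 4, b = 6), p2 = c(a = 4, b = 6))
  b <- pairwise_beta(cm, d, corrected = FALSE)
  expect_equal(unname(b["p1", "p2"]), 0)
  cm2 <- rbind(p1 = c(a = 5, b = 0), p2 = c(a = 0, b = 5))
  b2 <- pairwise_beta(cm2, d, corrected = FALSE)
  # gamma_pair = 0.5, alpha_mean = 0 -> beta = 100
  expect_equal(unname(b2["p1", "p2"]), 100)
  # corrected beta also treats complete turnover as 100
  b2c <- pairwise_beta(cm2, d, corrected = TRUE)
  expect_equal(unname(b2c["p1", "p2"]), 100, tolerance = 1e-6)
})

test_that("pairwise beta matches a per-pair brute-force oracle", {
  set.seed(4)
  cm <- random_counts(6, 12)
  d <- random_distance_matrix(12, colnames(cm))
  for (corrected in c(FALSE, TRUE)) {
    b <- pairwise_beta(cm, d, corrected = corrected)
    duse <- if (corrected) d / max(d) else d
    for (i in 1:5) for (j in (i + 1):6) {
      pooled <- cm[i, ] + cm[j, ]
      g <- rao_loop(pooled / sum(pooled), duse)
      a1 <- rao_loop(cm[i, ] / sum(cm[i, ]), duse)
      a2 <- rao_loop(cm[j, ] / sum(cm[j, ]), duse)
      if (corrected) {
        g <- 1 / (1 - g); a1 <- 1 / (1 - a1); a2 <- 1 / (1 - a2)
        expected <- (g - (a1 + a2) / 2) / g * 2 * 100
      } else {
        expected <- (g - (a1 + a2) / 2) / g * 100
      }
      expect_equal(unname(b[i, j]), max(expected, 0), tolerance = 1e-9)
    }
  }
})

test_that("pooling two copies of a plot reproduces its alpha", {
  set.seed(5)
  cm1 <- random_counts(1, 8)
  cm <- rbind(cm1, cm1)
  rownames(cm) <- c("p1", "p2")
  d <- random_distance_matrix(8, colnames(cm1))
  b <- pairwise_beta(cm, d, corrected = FALSE)
  expect_equal(unname(b["p1", "p2"]), 0, tolerance = 1e-12)
})

test_that("uncorrected beta lies in [0, 100] and is 0 iff compositions equal", {
  set.seed(6)
  cm <- random_counts(8, 10)
  d <- random_distance_matrix(10, colnames(cm))
  b <- pairwise_beta(cm, d, corrected = FALSE)
  expect_true(all(b >= 0 & b <= 100))
  # construct two plots with identical relative abundances
  cm2 <- cm
  cm2[2, ] <- cm2[1, ] * 3L
  b2 <- pairwise_beta(cm2, d, corrected = FALSE)
  expect_equal(unname(b2[1, 2]), 0, tolerance = 1e-10)
})

test_that("mpd matches its oracle and picante", {
  d3 <- taxonomic_distances(letters[1:4])
  expect_equal(mpd(c(0.3, 0.7), taxonomic_distances(c("a", "b")) * 3), 3)
  expect_equal(mpd(rep(0.25, 4), d3), 1)
  expect_error(mpd(c(1, 0), taxonomic_distances(c("a", "b"))), "undefined")
  set.seed(7)
  for (i in 1:20) {
    d <- random_distance_matrix(8)
    p <- runif(8)
    expect_equal(mpd(p / sum(p), d), mpd_loop(p, d), tolerance = 1e-9)
  }
  set.seed(8)
  d <- random_distance_matrix(9)
  cm <- random_counts(4, 9, species = colnames(d))
  ours <- vapply(seq_len(4), function(i) mpd(cm[i, ] / sum(cm[i, ]), d),
                 numeric(1))
  # picante's abundance-weighted MPD includes conspecific pairs and equals
  # Rao's Q; ours excludes them, so theirs = ours * (1 - sum(p^2))
  theirs <- picante::mpd(cm, d, abundance.weighted = TRUE)
  simpson <- apply(cm, 1, function(x) 1 - sum((x / sum(x))^2))
  expect_equal(unname(ours * simpson), unname(theirs), tolerance = 1e-9)
  q <- vapply(seq_len(4), function(i)
    rao_entropy(cm[i, ] / sum(cm[i, ]), d), numeric(1))
  expect_equal(unname(q), unname(theirs), tolerance = 1e-9)
})

test_that("tidy.beta_matrix returns one row per unordered pair", {
  set.seed(9)
  cm <- random_counts(5, 6)
  b <- pairwise_beta(cm, taxonomic_distances(colnames(cm)))
  tb <- tidy(b)
  expect_equal(nrow(tb), choose(5, 2))
  expect_true(all(tb$beta >= 0))
  expect_equal(unique(tb$facet), "taxonomic")
})
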