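test_that("euclidean plot distances are metric and translation-invariant", {
  co <- data.frame(plot = c("a", "b"), easting = c(0, 3), northing = c(0, 4))
  d <- euclidean_plot_distances(co)
  expect_equal(unname(d["a", "b"]), 5)
  co2 <- co; co2$easting <- co2$easting + 1000; co2$northing <- co2$northing - 50
  expect_equal(euclidean_plot_distances(co2), d)
  # brute-force loop oracle
  set.seed(40)
  co3 <- data.frame(plot = sprintf("p%d", 1:8),
                    easting = runif(8, 0, 100), northing = runif(8, 0, 100))
  d3 <- euclidean_plot_distances(co3)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(d3[i, j],
                 sqrt((co3$easting[i] - co3$easting[j])^2 +
                      (co3$northing[i] - co3$northing[j])^2),
                 tolerance = 1e-12)
  }
})

test_that("mantel statistic matches vegan and has affine invariance", {
  set.seed(41)
  a <- random_distance_matrix(10)
  b <- random_distance_matrix(10, labels = rownames(a))
  r1 <- mantel_test(a, b, n_perm = 99)
  expect_equal(r1$r, vegan::mantel(as.dist(a), as.dist(b),
                                   permutations = 9)$statistic,
               tolerance = 1e-12)
  # self-correlation is 1
  expect_equal(mantel_test(a, a, n_perm = 99)$r, 1)
  # affine rescaling of b leaves r unchanged
  r2 <- mantel_test(a, b * 7 + 2 - diag(2, nrow(b)), n_perm = 99)
  r2b <- mantel_test(a, b * 7, n_perm = 99)
  expect_equal(r2b$r, r1$r, tolerance = 1e-12)
  expect_error(mantel_test(a, a * 0, n_perm = 99), "Zero-variance")
  expect_error(mantel_test(a, b, n_perm = 10), "99")
})

test_that("partial mantel equals the residual-correlation oracle and vegan", {
  set.seed(42)
  a <- random_distance_matrix(10)
  b <- random_distance_matrix(10, labels = rownames(a))
  cc <- random_distance_matrix(10, labels = rownames(a))
  r <- partial_mantel(a, b, cc, n_perm = 99)$r
  va <- lower_vec(a); vb <- lower_vec(b); vc <- lower_vec(cc)
  ra <- resid(lm(va ~ vc)); rb <- resid(lm(vb ~ vc))
  expect_equal(r, cor(ra, rb), tolerance = 1e-10)
  expect_equal(r, vegan::mantel.partial(as.dist(a), as.dist(b), as.dist(cc),
                                        permutations = 9)$statistic,
               tolerance = 1e-10)
  # conditioning a~b on c = b gives 0 by construction
  expect_equal(partial_mantel(a, b, b, n_perm = 99)$r, 0, tolerance = 1e-10)
  # r_ac = r_bc = 0 reduces to the simple mantel r (construct orthogonal c)
  vc0 <- resid(lm(lower_vec(cc) ~ va + vb))
  c0 <- matrix(0, 10, 10, dimnames = dimnames(a))
  c0[lower.tri(c0)] <- vc0 - min(vc0) + 0.1
  c0 <- c0 + t(c0)
  expect_equal(partial_mantel(a, b, c0, n_perm = 99)$r,
               mantel_test(a, b, n_perm = 99)$r, tolerance = 1e-10)
})

test_that("pcnm basis is orthonormal with sinusoid-like leading axes", {
  # equally spaced points on a line: eigenvectors ordered by sign changes
  co <- data.frame(plot = sprintf("p%02d", 1:20),
                   easting = seq(0, 1900, by = 100), northing = 0)
  d <- euclidean_plot_distances(co)
  pb <- pcnm_basis(d)
  expect_true(all(pb$values > 0))
  gram <- crossprod(pb$vectors)
  expect_equal(gram, diag(ncol(pb$vectors)), tolerance = 1e-8,
               ignore_attr = TRUE)
  sign_changes <- apply(pb$vectors, 2, function(v) sum(diff(sign(v)) != 0))
  k <- min(5, length(sign_changes) - 1)
  expect_true(all(diff(sign_changes[1:k]) >= 0))
  # truncation = longest MST edge (here the spacing)
  expect_equal(pb$truncation, 100, tolerance = 1e-9)
  # plot-order invariance
  perm <- sample(20)
  pb2 <- pcnm_basis(d[perm, perm])
  expect_equal(abs(pb2$vectors[rownames(d), 1]), abs(pb$vectors[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcnm_basis(matrix(0, 3, 3)), "identical")
})

test_that("pcnm orthogonality holds across random configurations", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    co <- data.frame(plot = sprintf("p%02d", 1:n),
                     easting = runif(n, 0, 1e4), northing = runif(n, 0, 1e4))
    pb <- pcnm_basis(euclidean_plot_distances(co))
    expect_true(all(pb$values > 0))
    gram <- crossprod(pb$vectors)
    expect_lt(max(abs(gram - diag(ncol(pb$vectors)))), 1e-8)
  }
})

test_that("forward selection finds true predictors and rejects pure noise", {
  set.seed(44)
  n <- 30
  cand <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  both <- first_true <- 0
  for (i in 1:20) {
    cand_i <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    y <- 2 * cand_i[[2]] + 2 * cand_i[[7]] + rnorm(n, 0, 1)
    sel <- unname(forward_select(cbind(y), cand_i, n_perm = 199))
    both <- both + all(c(2, 7) %in% sel)
    first_true <- first_true + (length(sel) > 0 && sel[1] %in% c(2, 7))
  }
  # both generating variables recovered, and always entered first
  expect_gte(both, 19)
  expect_equal(first_true, 20)
  # a single dominant candidate comes first (and the ceiling then stops)
  y2 <- cand[[3]] + rnorm(n, 0, 0.1)
  sel2 <- forward_select(cbind(y2), cand, n_perm = 199)
  expect_equal(unname(sel2)[1], 3)
})

test_that("forward selection has roughly nominal type-I behaviour", {
  set.seed(45)
  n <- 25
  nonempty <- 0
  for (i in 1:40) {
    cand <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    y <- rnorm(n)
    sel <- forward_select(cbind(y), cand, n_perm = 99)
    if (length(sel) > 0) nonempty <- nonempty + 1
  }
  # global pre-test at alpha = 0.05 keeps false selections near 5%
  expect_lte(nonempty / 40, 0.15)
})

test_that("dbrda R2: closed-form Ezekiel and self-explanation limits", {
  expect_equal(phylorao:::ezekiel(0.5, 11, 1), 4 / 9, tolerance = 1e-12)
  set.seed(46)
  cm <- random_counts(12, 10)
  beta <- pairwise_beta(cm, taxonomic_distances(colnames(cm)))
  coords <- phylorao:::beta_pcoa(beta)
  r <- dbrda_r2(beta, coords[, 1:4])
  expect_gt(r$r2, 0.6)  # leading coordinates explain most inertia
  rfull <- dbrda_r2(beta, coords[, seq_len(min(ncol(coords), 9))])
  expect_gt(rfull$r2, 0.95)
  expect_error(dbrda_r2(beta, matrix(rnorm(12 * 11), 12)), "p must be")
  # random predictors: adjusted R2 centred near zero
  adjs <- replicate(30, dbrda_r2(beta, matrix(rnorm(24), 12, 2))$adj_r2)
  expect_lt(abs(mean(adjs)), 0.15)
})

test_that("variation partitioning fractions sum to one and respect structure", {
  set.seed(47)
  n <- 24
  x1 <- rnorm(n); x2 <- rnorm(n)
  sp <- matrix(rnorm(n * 2), n, 2)
  # response driven by x1 only
  coords <- cbind(2 * x1 + rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
  beta <- as.matrix(dist(coords))
  dimnames(beta) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  vp <- variation_partition(beta, x1, x2, sp, n_perm = 199)
  tb <- tidy(vp)
  fr <- tb$adj_r2[tb$component != "total_explained"]
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  a <- tb$adj_r2[tb$component == "disturbance_unique"]
  expect_gt(a, 0.3)
  expect_gt(a, tb$adj_r2[tb$component == "loss_unique"])
  expect_lt(tb$p[tb$component == "disturbance_unique"], 0.05)
  # empty space set contributes zero fractions
  vp0 <- variation_partition(beta, x1, x2, NULL, n_perm = 99)
  tb0 <- tidy(vp0)
  expect_equal(tb0$adj_r2[grepl("space", tb0$component)], rep(0, 3))
  expect_equal(sum(tb0$adj_r2[tb0$component != "total_explained"]), 1,
               tolerance = 1e-6)
})

test_that("orthogonal predictors yield near-zero joint fractions", {
  set.seed(48)
  n <- 32
  x1 <- rep(c(-1, 1), 16)
  x2 <- rep(c(-1, -1, 1, 1), 8)
  coords <- cbind(x1 + 0.5 * x2 + rnorm(n, 0, 0.2), rnorm(n, 0, 0.2))
  beta <- as.matrix(dist(coords))
  dimnames(beta) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  vp <- variation_partition(beta, x1, x2, NULL, n_perm = 99)
  tb <- tidy(vp)
  expect_lt(abs(tb$adj_r2[tb$component == "disturbance_loss_joint"]), 0.05)
})

test_that("variation partitioning broadly agrees with vegan::varpart", {
  set.seed(49)
  n <- 20
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
  coords <- cbind(x1 + x2 + rnorm(n), rnorm(n))
  beta <- as.matrix(dist(coords))
  dimnames(beta) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  Y <- phylorao:::beta_pcoa(beta, "none")
  vp <- variation_partition(beta, x1, x2, NULL, n_perm = 99,
                            correction = "none")
  vv <- vegan::varpart(Y, ~ x1, ~ x2, data = data.frame(x1 = x1, x2 = x2))
  # vegan two-set indfract rows: [a] X1 unique, [b] X2 unique, [c] joint
  ind <- vv$part$indfract$Adj.R.square
  tb <- tidy(vp)
  expect_equal(tb$adj_r2[tb$component == "disturbance_unique"], ind[1],
               tolerance = 1e-6)
  expect_equal(tb$adj_r2[tb$component == "loss_unique"], ind[2],
               tolerance = 1e-6)
  expect_equal(tb$adj_r2[tb$component == "disturbance_loss_joint"], ind[3],
               tolerance = 1e-6)
})
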