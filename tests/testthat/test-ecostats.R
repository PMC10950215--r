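test_that("Shannon diversity reproduces the published survey indices", {
  mu <- lafac_cover_means()
  expect_equal(round(shannon(mu[, "2015"])$H, 2), 1.14)
  expect_equal(round(shannon(mu[, "2017"])$H, 2), 1.27)
  expect_equal(round(shannon(mu[, "2019-PQ"])$H, 2), 0.82)
  expect_equal(round(shannon(mu[, "2017"])$E, 2), 0.55)
})

test_that("Shannon index obeys its analytic bounds and matches vegan", {
  u <- shannon(rep(10, 10))
  expect_equal(u$H, log(10))
  expect_equal(u$E, 1)
  s <- shannon(c(42, rep(0, 9)))
  expect_equal(s$H, 0)
  expect_equal(s$E, 0)
  set.seed(8)
  for (i in 1:10) {
    v <- runif(10, 0, 30)
    dv <- shannon(v)
    expect_equal(dv$H, as.numeric(vegan::diversity(v, "shannon")),
                 tolerance = 1e-12)
    expect_lte(dv$H, log(10) + 1e-12)
    expect_gte(dv$H, 0)
  }
  expect_error(shannon(rep(0, 10)), "all-zero")
  expect_error(shannon(c(-1, 2)), "nonnegative")
})

test_that("square-root transform is guarded against double
          application", {
  m <- matrix(c(0, 81, 4, 25), 2)
  tm <- sqrt_transform(m)
  expect_equal(as.vector(tm), c(0, 9, 2, 5))
  expect_error(sqrt_transform(tm), "already")
  expect_error(sqrt_transform(matrix(-1)), "negative")
})

test_that("normality test wraps Shapiro-Wilk with guarded input", {
  expect_error(normality_test(rep(3, 10)), "constant")
  expect_error(normality_test(1:2), "3 <= n")
  set.seed(1)
  r <- normality_test(rnorm(30))
  expect_lte(r$W, 1)
  expect_gt(r$p, 0)
})

test_that("one-way ANOVA with Tukey letters matches textbook
          arithmetic", {
  ## hand-computed 3 x 3 example: groups (1,2,3), (2,3,4), (6,7,8);
  ## SSB = 42, SSW = 6, F = (42/2)/(6/6) = 21
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- anova_tukey(y, g, transform = "none")
  expect_equal(fit$F, 21, tolerance = 1e-12)
  expect_equal(fit$p, stats::pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  ## identical groups: F = 0, no significant pairs, one shared letter
  same <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3),
                      transform = "none")
  expect_equal(same$F, 0)
  expect_true(all(same$tukey$p_adj > 0.05))
  expect_equal(unname(same$letters["x"]), unname(same$letters["y"]))
  ## two groups: F equals the squared two-sample t statistic
  set.seed(2)
  y2 <- c(rnorm(5), rnorm(5, 1))
  g2 <- rep(c("u", "v"), each = 5)
  f2 <- anova_tukey(y2, g2, transform = "none")
  t2 <- stats::t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(f2$F, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(f2$p, t2$p.value, tolerance = 1e-10)
  ## clearly separated groups get distinct letters
  far <- anova_tukey(c(1, 1.1, 0.9, 5, 5.1, 4.9, 9, 9.1, 8.9),
                     rep(c("a", "b", "c"), each = 3), transform = "none")
  expect_length(unique(far$letters), 3)
  expect_error(anova_tukey(1:3, c("a", "a", "b"), transform = "none"),
               "replicates")
})

test_that("Bray-Curtis dissimilarity matches its definition", {
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2, 3), c(1, 2, 3)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(5, 0, 2), c(0, 3, 0)))), 1)
  set.seed(4)
  m <- matrix(runif(100, 0, 20), 10)
  expect_equal(as.matrix(bray_curtis(m)), unname(brute_bray_curtis(m)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(bray_curtis(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("ANOSIM reproduces rank algebra, permutation null and
          monotone invariance", {
  ## complete separation: all within-distances below all between ->
  ## R = 1
  m <- rbind(matrix(rnorm(30, 0, 0.01), 3), matrix(rnorm(30, 50, 0.01), 3))
  m <- abs(m)
  grp <- rep(c("A", "B"), each = 3)
  a <- anosim(m, grp, n_perm = 999, seed = 1)
  expect_equal(a$R, 1)
  expect_lte(a$p, 0.15)            # only 10 distinct relabelings at n=6
  ## brute-force R on random data
  set.seed(5)
  m2 <- matrix(runif(60, 0, 10), 6)
  d2 <- bray_curtis(m2)
  grp2 <- rep(c("A", "B"), 3)
  a2 <- anosim(d2, grp2, n_perm = 99, seed = 2)
  expect_equal(a2$R, brute_anosim_R(d2, grp2), tolerance = 1e-12)
  ## exhaustive enumeration of all 20 labelings for n = 6 (two groups
  ## of 3): permutation p within Monte-Carlo error of the exact p
  Rnull <- apply(utils::combn(6, 3), 2, function(ix) {
    g <- rep("B", 6); g[ix] <- "A"
    brute_anosim_R(d2, g)
  })
  p_exact <- mean(Rnull >= a2$R - 1e-12)
  a3 <- anosim(d2, grp2, n_perm = 9999, seed = 3)
  expect_lt(abs(a3$p - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 9999) +
              2e-4)
  ## rank-based: invariant under monotone transforms of dissimilarity
  a_sq <- anosim(stats::as.dist(as.matrix(d2)^2), grp2, n_perm = 99,
                 seed = 2)
  expect_equal(a_sq$R, a2$R, tolerance = 1e-12)
  ## reproducible bit-exactly per seed
  expect_identical(anosim(d2, grp2, n_perm = 999, seed = 7)$p,
                   anosim(d2, grp2, n_perm = 999, seed = 7)$p)
  expect_error(anosim(d2, c("A", rep("B", 5)), seed = 1), ">= 2")
})

test_that("nMDS recovers exact embeddings and preserves dissimilarity
          ranks", {
  set.seed(6)
  pts <- matrix(rnorm(20), 10, 2)
  d <- stats::dist(pts)
  ## vegan warns that a perfect embedding has near-zero stress; that is
  ## exactly the property under test
  fit <- suppressWarnings(nmds(d, k = 2, n_restarts = 10, seed = 1))
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$coordinates), c(10L, 2L))
  ## Shepard check on a simulated community set: 15 samples drifting
  ## smoothly between three community states (a structured gradient, as
  ## in a multi-year survey)
  profiles <- rbind(c(30, 50, 5, 5, 5, 5), c(5, 10, 50, 25, 5, 5),
                    c(2, 5, 10, 3, 50, 30))
  wts <- cbind(seq(1, 0, length.out = 15)^2,
               2 * seq(1, 0, length.out = 15) *
                 seq(0, 1, length.out = 15),
               seq(0, 1, length.out = 15)^2)
  m <- wts %*% profiles * (1 + matrix(rnorm(15 * 6, 0, 0.05), 15))
  m <- pmax(m, 0)
  dbc <- bray_curtis(sqrt_transform(m))
  fit2 <- nmds(dbc, k = 2, n_restarts = 20, seed = 2)
  rc <- stats::cor(as.numeric(dbc), as.numeric(stats::dist(fit2$coordinates)),
                   method = "spearman")
  expect_gt(rc, 0.95)
  expect_error(nmds(d, k = 9), "k \\+ 2")
})

test_that("community matrices reshape cover tables faithfully", {
  sch <- scheme10()
  cfgt <- scene_config(transect_length_m = 1, pixel_size_m = 0.02,
                       seed = 1)
  sim <- simulate_survey_set(lafac_cover_means()[, c("2015", "2019-PQ")],
                             n_transects = 3, between_sd = 1,
                             cfg_template = cfgt, scheme = sch, seed = 6)
  m <- community_matrix(sim$truth)
  expect_equal(dim(m), c(6L, 10L))
  expect_equal(unname(rowSums(m)), rep(100, 6), tolerance = 1e-9)
  ## round-trip one record
  r1 <- sim$truth[1, ]
  expect_equal(m[paste(r1$survey, "truth", r1$transect, sep = "."),
                 r1$category], r1$cover_pct)
  rep <- survey_report(sim$truth, n_perm = 499, seed = 3)
  expect_equal(nrow(rep$diversity), 2)
  expect_true(all(c("H", "E") %in% names(rep$diversity)))
  expect_equal(nrow(rep$anosim), 1)
  expect_gte(rep$anosim$R, -1)
  expect_lte(rep$anosim$R, 1)
})
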