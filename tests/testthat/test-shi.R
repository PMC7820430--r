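# Soil health index pipeline: standardization, PCA, retention, MDS
# selection, scoring, weighting, SHI and yield regression.

test_that("standardization gives exact z-scores and flags degeneracy", {
  d <- as.data.frame(generate_trial(synthetic_config(rng_seed = 50)))
  z <- standardize(d)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-12)

  two <- data.frame(ph_s = c(3, 9))
  expect_equal(as.numeric(standardize(two, "ph_s")),
               c(-1, 1) / sqrt(2), tolerance = 1e-9)

  d$ph_s <- 7.5
  expect_error(standardize(d), "ph_s")
  expect_error(standardize(d, c("ec_e", "bogus")), "bogus")
})

test_that("PCA matches closed forms and the prcomp oracle", {
  # two columns with correlation r -> eigenvalues 1 + r, 1 - r
  set.seed(61)
  n <- 4000
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  z <- scale(cbind(a = x, b = y))
  p2 <- run_pca(z)
  r <- cor(x, y)
  expect_equal(p2$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-9)

  # near-identity correlation: all eigenvalues approach 1
  z0 <- scale(matrix(rnorm(5000 * 4), ncol = 4,
                     dimnames = list(NULL, letters[1:4])))
  expect_equal(run_pca(z0)$eigenvalues, rep(1, 4), tolerance = 0.15)

  # random 30 x 5: agreement with prcomp to 1e-8 (up to loading sign)
  z5 <- scale(matrix(rnorm(150), 30, 5,
                     dimnames = list(NULL, paste0("v", 1:5))))
  p5 <- run_pca(z5)
  oracle <- prcomp(z5, center = FALSE, scale. = FALSE)
  expect_equal(p5$eigenvalues, unname(oracle$sdev^2 * 29 / 29),
               tolerance = 1e-8)
  for (k in 1:5) {
    a <- p5$loadings[, k]; b <- oracle$rotation[, k]
    expect_lt(min(sum(abs(a - b)), sum(abs(a + b))), 1e-8)
  }
  # sign convention: dominant loading positive
  expect_true(all(apply(p5$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))

  expect_error(run_pca(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("eigenvalue trace identity holds on every generated season", {
  for (seed in c(3, 17)) {
    d <- as.data.frame(generate_trial(synthetic_config(rng_seed = seed)))
    for (s in c("sorghum", "wheat")) {
      p <- run_pca(standardize(d[d$season == s, ]))
      expect_equal(sum(p$eigenvalues), 14, tolerance = 1e-8)
      expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
    }
  }
})

test_that("PC retention applies both thresholds in order", {
  pca <- fake_pca(c(3.0, 1.2, 0.99, 0.41, 0.40))
  expect_identical(retain_pcs(pca, eigen_min = 1.0, var_min = 0.05), 1:2)
  expect_identical(retain_pcs(pca, eigen_min = 0.99, var_min = 0.05), 1:3)
  # variance-share gate is strict: eigenvalue 1.0 passes the eigenvalue
  # rule but its share (1/96) sits below var_min
  tiny <- fake_pca(c(rep(8, 8), rep(1, 8), rep(0.3, 80)))
  expect_identical(retain_pcs(tiny, eigen_min = 1.0, var_min = 0.0105), 1:8)
  expect_warning(empty <- retain_pcs(pca, eigen_min = 10), "no principal")
  expect_length(empty, 0)
})

test_that("within-10% loading rule selects top loaders per retained PC", {
  L <- matrix(0, 5, 5,
              dimnames = list(c("alpha_glu", "mbc", "ec_e", "ph_s", "wboc"),
                              paste0("PC", 1:5)))
  L[, 1] <- c(0.41, 0.39, 0.30, 0.2, 0.1)
  L[, 2] <- c(0.05, 0.1, -0.44, 0.44 * 0.89, 0.2)
  pca <- fake_pca(c(2.5, 1.5, 0.5, 0.3, 0.2), loadings = L)

  sel <- select_indicators(pca, retained = 1:2, within_frac = 0.10)
  expect_identical(sel$indicator[sel$pc == 1], c("alpha_glu", "mbc"))
  # 0.39 >= 0.9 * 0.41; |-0.44| leads PC2, 0.3916 just misses 0.396
  expect_identical(sel$indicator[sel$pc == 2], "ec_e")

  # an attribute taken from an earlier PC is excluded later; ties at the
  # maximum keep input-attribute order
  L2 <- L
  L2[, 2] <- c(0.5, 0.1, 0.5, 0.5, 0.1)   # alpha_glu ties ec_e and ph_s
  pca2 <- fake_pca(c(2.5, 1.5, 0.5, 0.3, 0.2), loadings = L2)
  sel2 <- select_indicators(pca2, retained = 1:2)
  expect_identical(sel2$indicator[sel2$pc == 2], c("ec_e", "ph_s"))

  # single dominant loading -> single attribute
  sel3 <- select_indicators(pca, retained = 2)
  expect_identical(sel3$indicator, "ec_e")

  expect_error(select_indicators(pca, retained = integer(0)), "retained")
})

test_that("redundancy pruning keeps the highest loader among correlates", {
  L <- matrix(0, 3, 3, dimnames = list(c("mbc", "mbn", "ec_e"),
                                       paste0("PC", 1:3)))
  L[, 1] <- c(0.60, 0.58, 0.1)
  pca <- fake_pca(c(2, 0.7, 0.3), loadings = L)
  pca$correlation <- matrix(c(1, 0.95, 0, 0.95, 1, 0, 0, 0, 1), 3, 3,
                            dimnames = list(rownames(L), rownames(L)))
  sel <- select_indicators(pca, retained = 1, redundancy_r = 0.7)
  expect_identical(sel$indicator, "mbc")
  sel_off <- select_indicators(pca, retained = 1)
  expect_identical(sel_off$indicator, c("mbc", "mbn"))
})

test_that("linear scoring functions hit their closed-form values", {
  d <- data.frame(mbc = c(2, 4, 6), ec_e = c(4, 6, 8), mbcn = c(2, 6, 10))
  sel <- structure(data.frame(indicator = c("mbc", "ec_e", "mbcn"),
                              pc = 1:3, loading = 0.5, weight = NA_real_),
                   class = c("mds_selection", "data.frame"), retained = 1:3)
  sc <- score_indicators(d, sel, scoring_spec(
    optimum_midpoints = c(mbcn = 6)))
  expect_equal(unname(sc[, "mbc"]), c(0, 0.5, 1))
  expect_equal(unname(sc[, "ec_e"]), c(1, 0.5, 0))
  expect_equal(unname(sc[, "mbcn"]), c(0, 1, 0))
  expect_true(all(sc >= 0 & sc <= 1))

  # observed-bounds scoring attains 0 and 1 per indicator
  expect_true(all(apply(sc, 2, min) == 0) && all(apply(sc, 2, max) == 1))

  # ratio variant
  sc_r <- score_indicators(d, sel, scoring_spec(), method = "ratio")
  expect_equal(unname(sc_r[, "mbc"]), c(2, 4, 6) / 6)
  expect_equal(unname(sc_r[, "ec_e"]), 4 / c(4, 6, 8))

  d$mbc <- 5
  expect_error(score_indicators(d, sel, scoring_spec()), "degenerate")
})

test_that("min-max scores are invariant to affine indicator rescaling", {
  set.seed(71)
  d <- data.frame(mbc = runif(40, 50, 300), ec_e = runif(40, 2, 12))
  sel <- structure(data.frame(indicator = c("mbc", "ec_e"), pc = 1:2,
                              loading = 0.5, weight = NA_real_),
                   class = c("mds_selection", "data.frame"), retained = 1:2)
  s1 <- score_indicators(d, sel, scoring_spec())
  d2 <- data.frame(mbc = 3.7 * d$mbc + 12, ec_e = 0.25 * d$ec_e + 1.1)
  s2 <- score_indicators(d2, sel, scoring_spec())
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PC-variance weights are whole shares, normalized only on request", {
  L <- matrix(0, 3, 3, dimnames = list(c("mbc", "mbn", "ec_e"),
                                       paste0("PC", 1:3)))
  L[, 1] <- c(0.7, 0.69, 0.1); L[, 2] <- c(0.1, 0.2, 0.9)
  pca <- fake_pca(c(0.9, 0.6, 1.5), loadings = L)
  pca$proportion <- c(0.30, 0.20, 0.50)   # fixed shares for the arithmetic
  pca$eigenvalues <- pca$proportion * 3
  pca$cumulative <- cumsum(pca$proportion)
  sel <- select_indicators(pca, retained = 1:2)
  expect_identical(sel$indicator, c("mbc", "mbn", "ec_e"))

  raw <- compute_weights(pca, sel, normalize = FALSE)
  expect_equal(raw$weight, c(0.30, 0.30, 0.20))  # full share per indicator

  norm <- compute_weights(pca, sel, normalize = TRUE)
  expect_equal(norm$weight, c(0.6, 0.6, 0.4))
  distinct <- tapply(norm$weight, norm$pc, unique)
  expect_equal(sum(distinct), 1)
})

test_that("the weighted sum reproduces the printed-index arithmetic", {
  w <- c(0.10, 0.10, 0.09, 0.09, 0.07, 0.07)
  sel <- structure(data.frame(indicator = paste0("i", 1:6),
                              pc = c(1, 1, 2, 2, 3, 4), loading = 0.4,
                              weight = w),
                   class = c("mds_selection", "data.frame"), retained = 1:4)
  ones <- matrix(1, 3, 6, dimnames = list(NULL, paste0("i", 1:6)))
  expect_equal(compute_shi(ones, sel), rep(0.52, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  zeros <- 0 * ones
  expect_equal(compute_shi(zeros, sel), rep(0, 3), ignore_attr = TRUE)

  set.seed(81)
  sc <- matrix(runif(60), 10, 6, dimnames = list(NULL, paste0("i", 1:6)))
  loop <- sapply(1:10, function(i) sum(w * sc[i, ]))
  expect_equal(compute_shi(sc, sel), loop, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(compute_shi(sc[, 1:5], sel), "missing")
  sel$weight <- NA_real_
  expect_error(compute_shi(sc, sel), "weights")
})

test_that("SHI stays within [0, sum(w)] on generated tables", {
  for (seed in c(2, 27)) {
    tab <- generate_trial(synthetic_config(rng_seed = seed))
    for (s in c("sorghum", "wheat")) {
      res <- build_shi(tab, s)
      expect_true(all(res$shi >= -1e-12))
      expect_true(all(res$shi <= res$max_shi + 1e-12))
      expect_equal(res$max_shi, sum(res$selection$weight))
    }
  }
})

test_that("lowering a stressor under fixed bounds never lowers the index", {
  tab <- generate_trial(synthetic_config(rng_seed = 33))
  res <- build_shi(tab, "sorghum")
  if (!"ec_e" %in% res$selection$indicator) skip("ec_e not in this MDS")
  d <- res$data
  b <- attr(res$scores, "bounds")
  s1 <- score_indicators(d, res$selection, scoring_spec(), bounds = b)
  shi1 <- compute_shi(s1, res$selection)
  d2 <- d
  set.seed(1)
  d2$ec_e <- pmax(d2$ec_e - runif(nrow(d2), 0, 1), b[["ec_e"]]["min"])
  s2 <- score_indicators(d2, res$selection, scoring_spec(), bounds = b)
  shi2 <- compute_shi(s2, res$selection)
  expect_true(all(shi2 >= shi1 - 1e-12))
})

test_that("yield regression matches the normal-equations oracle", {
  shi <- c(0.2, 0.35, 0.4, 0.55, 0.6)
  y_exact <- 2 * shi + 1
  fit <- shi_yield_regression(shi, y_exact)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  expect_equal(shi_yield_regression(shi, rep(4, 5))$r_squared, 0,
               tolerance = 1e-12)

  set.seed(91)
  y <- 3 - 2 * shi + rnorm(5, sd = 0.3)
  fit2 <- shi_yield_regression(shi, y)
  oracle <- bf_ols(shi, y)
  expect_equal(fit2$slope, unname(oracle$slope), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(oracle$intercept), tolerance = 1e-10)
  expect_equal(fit2$r_squared, oracle$r_squared, tolerance = 1e-10)

  expect_error(shi_yield_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(shi_yield_regression(rep(0.4, 5), y_exact), "zero variance")
})

test_that("build_shi assembles a coherent end-to-end result", {
  tab <- generate_trial(synthetic_config(rng_seed = 44))
  res <- build_shi(tab, "wheat")
  expect_s3_class(res, "shi_result")
  expect_equal(nrow(res$data), 108)
  expect_identical(colnames(res$scores), res$selection$indicator)
  expect_equal(res$data$shi, res$shi)
  # indicators from the same PC share a weight
  for (k in unique(res$selection$pc)) {
    expect_length(unique(res$selection$weight[res$selection$pc == k]), 1L)
  }
  expect_error(suppressWarnings(build_shi(tab, "wheat", eigen_min = 99)),
               "no PCs retained")
})
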