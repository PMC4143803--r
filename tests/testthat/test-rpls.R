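# The two-step rPLS test: screening, supervariant, GLM inference.

test_that("elastic-net screening honors forced penalties and single-variant genes", {
  X <- toy_dosages(60, 5, seed = 21)
  y <- rnorm(60) + X[, 2]
  expect_identical(elastic_net_screen(X, y, lambda = Inf), integer(0))
  # p = 1: the lone variant is the candidate set
  expect_identical(elastic_net_screen(X[, 1, drop = FALSE], y), 1L)
  # unpenalized fit keeps a marginally associated variant
  sel0 <- elastic_net_screen(X, y, lambda = 1e-8)
  expect_true(2L %in% sel0)
})

test_that("screening recovers a strong causal variant among nulls", {
  # one causal variant (effect 1.0, maf 0.3) among 20 nulls, n = 500
  hits <- 0L
  for (i in 1:100) {
    set.seed(1000 + i)
    X <- cbind(rbinom(500, 2, 0.3),
               vapply(runif(20, 0.05, 0.4),
                      function(m) rbinom(500, 2, m), numeric(500)))
    y <- X[, 1] * 1.0 + rnorm(500)
    sel <- elastic_net_screen(X, y, seed = i)
    hits <- hits + (1L %in% sel)
  }
  expect_gte(hits, 95L)
})

test_that("the first PLS loading is the normalized covariance vector", {
  # two exactly orthogonal centered columns with crossproducts 0.4 and 0.3
  x1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  x2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  stopifnot(sum(x1 * x2) == 0)
  y <- 0.4 / sum(x1^2) * x1 + 0.3 / sum(x2^2) * x2
  fit <- pls_supervariant(cbind(x1, x2), y)
  expect_equal(fit$loading_w, c(0.8, 0.6), tolerance = 1e-12)
  expect_equal(fit$supervariant_t, as.numeric(cbind(x1, x2) %*% c(0.8, 0.6)),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(fit$loading_w^2)), 1, tolerance = 1e-12)
  # k = 1 reduces to the (sign-normalized) centered column
  f1 <- pls_supervariant(cbind(x1), y)
  expect_true(all(abs(f1$loading_w) == 1))
  # orthogonal working response is degenerate
  expect_error(pls_supervariant(cbind(x1, x2), rep(1, 8)),
               class = "rpls_degenerate")
})

test_that("the supervariant GLM equals classical slope inference", {
  set.seed(22)
  t <- rnorm(80)
  y <- 0.3 * t + rnorm(80)
  g <- glm_test_supervariant(t, NULL, y, "gaussian")
  lmfit <- summary(lm(y ~ t))$coefficients
  expect_equal(g$p_value, lmfit["t", 4], tolerance = 1e-12)
  expect_equal(g$beta_star, lmfit["t", 1], tolerance = 1e-12)
  # binomial perfect separation returns p = 1 with a flag
  ts <- c(rep(-2, 10), rep(2, 10))
  ys <- c(rep(0, 10), rep(1, 10))
  gs <- glm_test_supervariant(ts, NULL, ys, "binomial")
  expect_true(gs$separation)
  expect_equal(gs$p_value, 1)
})

test_that("rPLS is deterministic and scale-equivariant", {
  X <- toy_dosages(120, 8, seed = 23)
  set.seed(99)
  y <- 0.5 * X[, 3] + rnorm(120)
  Z <- cbind(age = runif(120, 20, 80))
  f1 <- rpls_test(X, y, Z, "gaussian", config = rpls_config(seed = 5))
  f2 <- rpls_test(X, y, Z, "gaussian", config = rpls_config(seed = 5))
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$selected_idx, f2$selected_idx)
  expect_identical(f1$loading_w, f2$loading_w)
  f3 <- rpls_test(X, y * 7, Z, "gaussian", config = rpls_config(seed = 5))
  expect_identical(f3$selected_idx, f1$selected_idx)
  expect_equal(f3$p_value, f1$p_value, tolerance = 1e-9)
})

test_that("a single-variant gene reduces rPLS to the single-variant GLM test", {
  X <- toy_dosages(100, 1, seed = 24)
  set.seed(100)
  y <- 0.4 * X[, 1] + rnorm(100)
  Z <- cbind(age = runif(100, 20, 80), sex = rbinom(100, 1, 0.5))
  fit <- rpls_test(X, y, Z, "gaussian")
  expect_equal(fit$k, 1L)
  ref <- summary(glm(y ~ X[, 1] + Z))$coefficients[2, 4]
  expect_equal(fit$p_value, ref, tolerance = 1e-7)
  expect_equal(fit$snv_ranking, "v1")
})

test_that("degenerate genes return p = 1 with an empty ranking", {
  # constant gene: nothing selectable
  Xc <- matrix(1, 50, 1, dimnames = list(NULL, "v1"))
  set.seed(25)
  fit <- rpls_test(Xc, rnorm(50), NULL, "gaussian")
  expect_equal(fit$k, 0L)
  expect_equal(fit$p_value, 1)
  expect_identical(fit$snv_ranking, character(0))
  expect_identical(rank_snvs(fit), character(0))
})

test_that("variants are ranked by |loading| with positional tie-break", {
  expect_equal(rpls:::rank_by_loading(c(0.8, -0.6), c(10, 20)), c(1L, 2L))
  expect_equal(rpls:::rank_by_loading(c(-0.6, 0.8), c(10, 20)), c(2L, 1L))
  expect_equal(rpls:::rank_by_loading(c(0.6, -0.6, 0.3), c(30, 20, 10)),
               c(2L, 1L, 3L))
  # end-to-end: the strong variant leads the ranking
  set.seed(26)
  X <- toy_dosages(300, 6, seed = 26)
  y <- 0.9 * X[, 4] + rnorm(300)
  fit <- rpls_test(X, y, NULL, "gaussian")
  expect_equal(fit$snv_ranking[1], "v4")
})
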