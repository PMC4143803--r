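# SUM, SKAT, and SKAT-O comparison tests.

test_that("SUM collapses to the burden supervariant GLM", {
  X <- toy_dosages(90, 4, seed = 31)
  set.seed(31)
  y <- rnorm(90) + 0.2 * rowSums(X)
  Z <- cbind(age = runif(90, 20, 80))
  r <- sum_test(X, y, Z, "gaussian")
  s <- rowSums(X)
  ref <- summary(glm(y ~ s + Z))$coefficients["s", ]
  expect_equal(r$p_value, unname(ref[4]), tolerance = 1e-12)
  expect_equal(r$df_or_params$df, 1L)
  # all-zero gene: constant burden
  r0 <- sum_test(matrix(0, 90, 3), y, Z, "gaussian")
  expect_equal(r0$p_value, 1)
  expect_equal(r0$flags, "constant_burden")
  # one-variant gene: identical to the single-variant GLM test
  r1 <- sum_test(X[, 2, drop = FALSE], y, Z, "gaussian")
  ref1 <- summary(glm(y ~ X[, 2] + Z))$coefficients[2, 4]
  expect_equal(r1$p_value, ref1, tolerance = 1e-12)
})

test_that("single-variant SKAT equals the single-variant regression test", {
  X <- toy_dosages(150, 1, seed = 32)
  set.seed(32)
  y <- rnorm(150) + 0.3 * X[, 1]
  Z <- cbind(age = runif(150, 20, 80), sex = rbinom(150, 1, 0.5))
  r <- skat_test(X, y, Z, "gaussian", weights = 1)
  # the exact finite-sample score test is the classical t-test of the
  # variant's slope
  ref <- summary(glm(y ~ X[, 1] + Z))$coefficients[2, 4]
  expect_equal(r$p_value, ref, tolerance = 1e-5)
  expect_true(isTRUE(r$df_or_params$exact))
  # and the asymptotic chi-square version is recovered in the large-n
  # limit: at n = 150 the two differ by a small finite-sample amount
  nm <- skat_null_model(y, Z, "gaussian")
  u <- sum(X[, 1] * nm$resid)
  v <- sum(qr.resid(nm$qr, X[, 1])^2)
  p_asym <- pchisq(u^2 / (nm$sigma2 * v), 1, lower.tail = FALSE)
  expect_lt(abs(r$p_value - p_asym), 0.02)
})

test_that("SKAT is degenerate when the kernel carries no signal", {
  set.seed(33)
  y <- rnorm(40)
  Xc <- matrix(2, 40, 3)  # constant columns: zero projected kernel
  r <- skat_test(Xc, y, NULL, "gaussian")
  expect_equal(r$p_value, 1)
  expect_equal(r$flags, "degenerate")
})

test_that("binomial SKAT agrees with a permutation oracle", {
  set.seed(34)
  n <- 120; p <- 6
  X <- toy_dosages(n, p, seed = 34)
  y <- rbinom(n, 1, 0.35)
  r <- skat_test(X, y, NULL, "binomial")
  w <- dbeta(colMeans(X) / 2, 1, 25)
  A <- sweep(X, 2, w, `*`)
  rc <- y - mean(y)
  Q0 <- sum(crossprod(A, rc)^2)
  B <- 20000
  perm <- matrix(rc[replicate(B, sample.int(n))], n, B)
  Qp <- colSums(crossprod(A, perm)^2)
  pp <- mean(Qp >= Q0)
  # the analytic null treats the binomial residual variance as known, so
  # at this n a small systematic gap from the exact permutation law remains
  expect_lt(abs(r$p_value - pp), 3 * sqrt(pp * (1 - pp) / B) + 0.03)
})

test_that("SKAT-O degenerates to SKAT on a single-point grid", {
  X <- toy_dosages(100, 7, seed = 35)
  set.seed(35)
  y <- rnorm(100) + 0.25 * X[, 1]
  Z <- cbind(age = runif(100, 20, 80))
  expect_equal(skat_o_test(X, y, Z, "gaussian", rho_grid = 0)$p_value,
               skat_test(X, y, Z, "gaussian")$p_value, tolerance = 1e-12)
})

test_that("pure-burden SKAT-O with flat weights equals the burden regression test", {
  X <- toy_dosages(100, 5, seed = 36)
  set.seed(36)
  y <- rnorm(100) + 0.15 * rowSums(X)
  r1 <- skat_o_test(X, y, NULL, "gaussian", rho_grid = 1,
                    weights = rep(1, 5))
  # exact burden score test == t-test of the burden supervariant
  s <- rowSums(X)
  ref <- summary(lm(y ~ s))$coefficients["s", 4]
  expect_equal(r1$p_value, ref, tolerance = 1e-5)
  # which is the SUM test itself
  expect_equal(r1$p_value, sum_test(X, y, NULL, "gaussian")$p_value,
               tolerance = 1e-5)
})

test_that("SKAT-O sits between the minimum p and its Bonferroni bound", {
  grid <- c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)
  for (s in 1:6) {
    X <- toy_dosages(80, 6, seed = 40 + s)
    set.seed(40 + s)
    y <- rnorm(80) + runif(1, 0, 0.4) * X[, 1]
    r <- skat_o_test(X, y, NULL, "gaussian", rho_grid = grid)
    minp <- r$df_or_params$min_p
    expect_gte(r$p_value, minp - 1e-9)
    expect_lte(r$p_value, min(1, length(grid) * minp) + 1e-3)
    expect_true(r$df_or_params$rho_opt %in% grid)
  }
})

test_that("mixed effect directions cost SUM power but aligned ones do not", {
  # matched-size comparison at alpha = 0.05 over re-simulated phenotypes
  set.seed(50)
  n <- 300
  maf <- c(0.1, 0.15, 0.2, 0.25)
  X <- vapply(maf, function(m) rbinom(n, 2, m), numeric(n))
  b <- 0.35
  reps <- 60
  det <- matrix(0, reps, 2, dimnames = list(NULL, c("mixed", "aligned")))
  for (i in 1:reps) {
    e <- rnorm(n)
    det[i, "mixed"] <- sum_test(X, X %*% (b * c(1, 1, -1, -1)) + e,
                                NULL, "gaussian")$p_value <= 0.05
    det[i, "aligned"] <- sum_test(X, X %*% (b * c(1, 1, 1, 1)) + e,
                                  NULL, "gaussian")$p_value <= 0.05
  }
  expect_gt(mean(det[, "aligned"]), mean(det[, "mixed"]))
})
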