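test_that("pearson correlation handles exact linearity and affine invariance", {
  expect_equal(pearson_cor(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(1:3, c(3, 2, 1))$r, -1)
  set.seed(71)
  x <- rnorm(100); y <- 0.3 * x + rnorm(100)
  r0 <- pearson_cor(x, y)
  r1 <- pearson_cor(10 + 5 * x, y)
  expect_equal(r0$r, r1$r)
  expect_equal(r0$p, r1$p)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "degenerate-input")
})

test_that("pearson p agrees with a permutation oracle", {
  set.seed(72)
  x <- rnorm(50); y <- 0.25 * x + rnorm(50)
  res <- pearson_cor(x, y)
  xc <- (x - mean(x)) / sd(x); yc <- (y - mean(y)) / sd(y)
  perms <- replicate(1e5, abs(sum(xc * sample(yc)) / 49))
  p_perm <- mean(perms >= abs(res$r))
  expect_lt(abs(res$p - p_perm), 0.02)
})

test_that("Box-Cox matches its closed forms and finds lambda near 0 on lognormal data", {
  expect_equal(boxcox_transform(c(1, 2, 3), lambda = 1)$y, c(0, 1, 2))
  expect_equal(boxcox_transform(c(1, exp(1)), lambda = 0)$y, c(0, 1))
  set.seed(73)
  x <- exp(rnorm(1e4))
  bc <- boxcox_transform(x)
  expect_lt(abs(bc$lambda), 0.1)
  # agrees with the MASS profile-likelihood maximizer
  mb <- MASS::boxcox(x ~ 1, lambda = seq(-0.5, 0.5, 0.01), plotit = FALSE)
  expect_lt(abs(bc$lambda - mb$x[which.max(mb$y)]), 0.02)
  # auto-lambda on already-normal positive data stays near 1
  z <- rnorm(1e4, 100, 5)
  expect_gt(boxcox_transform(z)$lambda, 0.5)
  expect_lt(boxcox_transform(z)$lambda, 1.5)
  # zeros get the half-minimum shift
  expect_equal(boxcox_transform(c(0, 2, 4), lambda = 1)$shift, 1)
  expect_error(boxcox_transform(c(-1, 2)), "domain-error")
})

test_that("VIF equals 1/(1-R2) and matches the car reference", {
  set.seed(74)
  X <- cbind(a = rnorm(200), b = rnorm(200))
  v <- vif(X)
  r2 <- cor(X[, 1], X[, 2])^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-10)
  X3 <- cbind(X, c = 0.7 * X[, 1] + rnorm(200))
  y <- rnorm(200)
  ref <- car::vif(lm(y ~ a + b + c, data.frame(y, X3)))
  expect_equal(unname(vif(X3)), unname(ref), tolerance = 1e-8)
  expect_warning(vd <- vif(cbind(X, dup = X[, 1])), "collinearity")
  expect_true(any(is.infinite(vd)))
})

test_that("standardized regression is scale-invariant with unit beta on y = x", {
  set.seed(75)
  x <- rnorm(50)
  fit <- suppressWarnings(ols_standardized(x, cbind(x1 = x)))  # exact fit
  expect_equal(unname(fit$beta), 1)
  expect_equal(fit$adjusted_r2, 1)

  X <- cbind(x1 = rnorm(200), x2 = rnorm(200))
  y <- 0.5 * X[, 1] + rnorm(200)
  f1 <- ols_standardized(y, X)
  X2 <- X; X2[, 1] <- X2[, 1] * 1000
  f2 <- ols_standardized(y, X2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)

  # null: no predictive signal
  set.seed(76)
  yn <- rnorm(1e4); Xn <- cbind(x1 = rnorm(1e4))
  fn <- ols_standardized(yn, Xn)
  expect_lt(abs(fn$beta), 0.05)
  expect_lt(fn$adjusted_r2, 0.01)
  expect_error(ols_standardized(rnorm(3), cbind(rnorm(3), rnorm(3))),
               "underdetermined")
})

test_that("backward stepwise drops noise predictors and keeps the planted one", {
  set.seed(77)
  x1 <- rnorm(300); x2 <- rnorm(300)
  y <- x1 + rnorm(300, sd = 0.5)
  st <- backward_stepwise(y, cbind(x1 = x1, x2 = x2))
  expect_equal(st$retained, "x1")
  # single strong predictor: identical to the plain fit
  solo <- ols_standardized(y, cbind(x1 = x1))
  expect_equal(st$beta[["x1"]], solo$beta[["x1"]])
  # pure noise often retains nothing
  drops <- sum(vapply(1:20, function(s) {
    set.seed(1000 + s)
    length(backward_stepwise(rnorm(100),
                             cbind(a = rnorm(100), b = rnorm(100)))$retained) == 0
  }, logical(1)))
  expect_gte(drops, 15)
})

test_that("Fisher exact p follows the probability-mass two-sided rule", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10))
  # random tables vs enumeration oracle and stats::fisher.test
  set.seed(78)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 6) + 1, 2)
    p <- fisher_exact_2x2(tb)
    expect_equal(p, fisher_enum(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]))
    expect_equal(p, fisher.test(tb)$p.value, tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "degenerate-table")
})

test_that("Welch t and one-way ANOVA behave on degenerate and separated input", {
  x <- rnorm(20)
  tt <- two_sample_t(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  set.seed(79)
  expect_lt(two_sample_t(rnorm(100), rnorm(100, 5))$p, 1e-9)

  g <- list(1:5 * 1.0, 1:5 * 1.0, 1:5 * 1.0)
  a <- one_way_anova(g)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # two groups: F = t^2 of the pooled t-test
  g2 <- list(rnorm(20), rnorm(20, 0.5))
  a2 <- one_way_anova(g2)
  t2 <- t.test(g2[[1]], g2[[2]], var.equal = TRUE)$statistic^2
  expect_equal(a2$F, unname(t2))
  expect_error(one_way_anova(list(1:3)), "insufficient-data")
  expect_error(one_way_anova(list(1:3, 2)), "insufficient-data")
})

test_that("one-way ANOVA type-I error is calibrated at the nominal level", {
  set.seed(80)
  rej <- mean(vapply(1:2000, function(i) {
    one_way_anova(list(rnorm(30), rnorm(30), rnorm(30)))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})
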