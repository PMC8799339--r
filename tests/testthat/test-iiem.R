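test_that("min-max standardization maps columns to [0,1] and zeroes constants", {
  x <- cbind(a = c(2, 4, 6), b = c(3, 3, 3))
  y <- iiem_standardize(x)
  expect_equal(unname(y[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(y[, "b"]), c(0, 0, 0))
  expect_error(iiem_standardize(x[1, , drop = FALSE]), "2 rows")
  withr::local_seed(21)
  x2 <- rand_indicator_matrix(20, 5)
  expect_equal(iiem_standardize(x2), oracle_iiem(x2)$y)
  # cost-type columns flip orientation
  yc <- iiem_standardize(x, invert = "a")
  expect_equal(unname(yc[, "a"]), c(1, 0.5, 0))
})

test_that("uniform columns carry maximal entropy, exactly 1", {
  y <- cbind(rep(0.37, 6), rep(0, 6))
  expect_equal(unname(iiem_entropy(y)), c(1, 1))
})

test_that("entropy of a concentrated two-node column matches hand evaluation", {
  # b = (eps, 1 + eps) / (1 + 2 eps), eps = 1e-4
  eps <- 1e-4
  b <- c(eps, 1 + eps) / (1 + 2 * eps)
  expected <- -sum(b * log(b)) / log(2)
  expect_equal(unname(iiem_entropy(cbind(c(0, 1)), epsilon = eps)), expected)
  expect_equal(expected, 0.001473, tolerance = 1e-3)
  expect_error(iiem_entropy(cbind(c(0.5, 1))[1, , drop = FALSE]), "2 rows")
})

test_that("more concentrated columns have lower entropy", {
  concentrated <- c(1, rep(0, 9))
  near_uniform <- runif(10, 0.9, 1.0)
  H <- iiem_entropy(cbind(concentrated, near_uniform))
  expect_lt(H[1], H[2])
})

test_that("entropy weights normalize, stay positive, and match the hand example", {
  # H = (1, 0.5, 0): S = 1.5, weights ((1-H) + 0.15) / 1.95
  w <- iiem_weights(c(1, 0.5, 0))
  expect_equal(unname(w), c(0.15, 0.65, 1.15) / 1.95)
  # equal entropies give equal weights
  expect_equal(unname(iiem_weights(rep(0.3, 4))), rep(0.25, 4))
  withr::local_seed(5)
  for (i in 1:20) {
    H <- runif(5)
    w <- iiem_weights(H)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_error(iiem_weights(c(1, 1, 1)), "uninformative")
})

test_that("importance is a weighted distance from the ideal point", {
  omega <- c(0.2, 0.3, 0.5)
  expect_equal(unname(iiem_importance(rbind(c(0, 0, 0)), omega)), 0)
  expect_equal(unname(iiem_importance(rbind(c(1, 1, 1)), omega)), 1)
  withr::local_seed(9)
  y <- matrix(runif(15), 5, 3)
  Z <- iiem_importance(y, omega)
  direct <- sqrt(rowSums(sweep(y^2, 2, omega, `*`)))
  expect_equal(unname(Z), unname(direct), tolerance = 1e-12)
  expect_equal(unname(iiem_importance(y, omega, sqrt_form = FALSE)),
               unname(direct^2), tolerance = 1e-12)
  expect_error(iiem_importance(y, omega[1:2]), "omega")
})

test_that("threshold selection is inclusive and deterministically ordered", {
  Z <- c(n1 = 0.5, n2 = 0.4, n3 = 0.39)
  expect_equal(select_by_z(Z, 0.4), c("n1", "n2"))
  expect_equal(select_by_z(Z, 0), c("n1", "n2", "n3"))
  expect_equal(select_by_z(Z, 1), character(0))
  # ties broken by label
  expect_equal(select_by_z(c(b = 0.6, a = 0.6), 0.5), c("a", "b"))
})

test_that("full chain matches the straight-line oracle on random matrices", {
  withr::local_seed(77)
  for (rep in 1:30) {
    x <- rand_indicator_matrix(sample(3:30, 1), 5)
    fit <- iiem(x)
    ref <- oracle_iiem(x)
    expect_equal(unname(fit$Z), ref$Z, tolerance = 1e-10)
    expect_equal(unname(fit$H), ref$H, tolerance = 1e-12)
    expect_equal(unname(fit$omega), ref$omega, tolerance = 1e-12)
    expect_true(all(fit$Z >= 0 & fit$Z <= 1))
  }
})

test_that("chain is invariant to positive rescaling of a raw column", {
  withr::local_seed(13)
  x <- rand_indicator_matrix(15, 5)
  x_scaled <- x
  x_scaled[, 2] <- x[, 2] * 37.5
  a <- iiem(x); b <- iiem(x_scaled)
  expect_equal(a$Z, b$Z, tolerance = 1e-12)
  expect_equal(a$omega, b$omega, tolerance = 1e-12)
})

test_that("with fixed weights, increasing a standardized value increases Z", {
  withr::local_seed(14)
  y <- matrix(runif(20, 0, 0.9), 4, 5)
  omega <- rep(0.2, 5)
  Z0 <- iiem_importance(y, omega)
  y[2, 3] <- y[2, 3] + 0.05
  Z1 <- iiem_importance(y, omega)
  expect_gt(Z1[2], Z0[2])
  expect_equal(Z1[-2], Z0[-2])
})
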