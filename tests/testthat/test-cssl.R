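test_that("composite loss matches hand arithmetic", {
  # perfect fit, no consistency
  x_l <- matrix(c(1, 2, 3), 3, 1)
  w <- 2; b <- 1
  y <- as.vector(x_l * 2 + 1)
  expect_equal(unname(composite_loss(w, b, x_l, y)),
               c(0, 0, 0))
  # w=(1,0), one unlabeled x=(0,0), delta=(0.3,-0.1), lambda=2:
  # consistency = (w.delta)^2 = 0.09, contribution 0.18
  l <- composite_loss(c(1, 0), 0, matrix(0, 1, 2), 0,
                      x_u = matrix(0, 1, 2),
                      delta = matrix(c(0.3, -0.1), 1, 2), lambda_u = 2)
  expect_equal(unname(l["consistency"]), 0.09)
  expect_equal(unname(l["total"]) - unname(l["supervised"]), 0.18)
  # zero perturbation kills the consistency term exactly
  l0 <- composite_loss(c(1, 5), 2, matrix(rnorm(6), 3, 2), rnorm(3),
                       x_u = matrix(rnorm(4), 2, 2),
                       delta = matrix(0, 2, 2), lambda_u = 1)
  expect_equal(unname(l0["consistency"]), 0)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(15)
  n_l <- 7; n_u <- 5; d <- 3
  x_l <- matrix(rnorm(n_l * d), n_l, d)
  y_l <- rnorm(n_l, 28, 5)
  delta <- matrix(rnorm(n_u * d, 0, 0.2), n_u, d)
  w <- rnorm(d); b <- 0.3; lam <- 1.7
  loss <- function(w, b) {
    r <- as.vector(x_l %*% w) + b - y_l
    mean(r^2) + lam * mean(as.vector(delta %*% w)^2)
  }
  gw <- 2 * crossprod(x_l, as.vector(x_l %*% w) + b - y_l)[, 1] / n_l +
    lam * 2 * crossprod(delta, as.vector(delta %*% w))[, 1] / n_u
  gb <- 2 * sum(as.vector(x_l %*% w) + b - y_l) / n_l
  h <- 1e-6
  for (j in seq_len(d)) {
    ej <- rep(0, d); ej[j] <- h
    num <- (loss(w + ej, b) - loss(w - ej, b)) / (2 * h)
    expect_equal(gw[j], num, tolerance = 1e-5)
  }
  expect_equal(gb, (loss(w, b + h) - loss(w, b - h)) / (2 * h),
               tolerance = 1e-5)
})

test_that("lambda_u = 0 training recovers the least-squares solution", {
  set.seed(20)
  x <- scale(matrix(rnorm(100 * 6), 100, 6))
  colnames(x) <- paste0("f", 1:6)
  y <- as.vector(x %*% c(4, -3, 2, 1, 0.5, 0)) + 28 + rnorm(100, 0, 0.8)
  fit <- cssl(x, y, lambda_u = 0, learning_rate = 1e-2, max_iter = 50000,
              tol = 0, clamp = FALSE)
  ols <- qr.solve(cbind(1, x), y)  # normal-equations oracle
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
})

test_that("empty unlabeled set reproduces the supervised trajectory", {
  set.seed(21)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rnorm(60, 28, 8)
  f1 <- cssl(x, y, x_u = NULL, lambda_u = 1, seed = 5, max_iter = 500)
  f2 <- cssl(x, y, x_u = matrix(numeric(0), 0, 4), lambda_u = 1, seed = 5,
             max_iter = 500)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$history, f2$history)
})

test_that("Monte-Carlo consistency mean matches sigma^2 * ||w||^2", {
  set.seed(22)
  d <- 6; n_u <- 40; sigma <- 0.3
  w <- rnorm(d)
  draws <- 400
  cons <- replicate(draws, {
    delta <- matrix(rnorm(n_u * d, 0, sigma), n_u, d)
    mean(as.vector(delta %*% w)^2)
  })
  expected <- sigma^2 * sum(w^2)
  se <- sd(cons) / sqrt(draws)
  expect_lt(abs(mean(cons) - expected), 3 * se)
})

test_that("predictions are affine, named-matched, and clamp to the BBS range", {
  set.seed(23)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.vector(x %*% c(10, 5, -4)) + 28
  fit <- cssl(x, y, lambda_u = 0, max_iter = 20000, clamp = FALSE)
  # linear interpolation property (clamp off)
  x1 <- x[1, , drop = FALSE]; x2 <- x[2, , drop = FALSE]
  al <- 0.3
  expect_equal(predict(fit, al * x1 + (1 - al) * x2),
               al * predict(fit, x1) + (1 - al) * predict(fit, x2),
               tolerance = 1e-10)
  # clamping bounds extreme inputs
  far <- matrix(100, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_lte(predict(fit, far, clamp = TRUE), 56)
  expect_gte(predict(fit, -far, clamp = TRUE), 0)
  # column order of newdata does not matter when names are present
  expect_equal(predict(fit, x[, c("c", "a", "b")]), predict(fit, x))
  # constant model predicts its bias
  fit0 <- cssl(matrix(0, 10, 2), rep(28, 10), max_iter = 2000)
  expect_equal(unname(predict(fit0, matrix(rnorm(6), 3, 2))), rep(28, 3),
               tolerance = 1e-6)
})

test_that("training history converges (smoothed non-increasing trend)", {
  set.seed(24)
  x <- scale(matrix(rnorm(80 * 5), 80, 5))
  y <- as.vector(x %*% rnorm(5)) * 5 + 28 + rnorm(80)
  x_u <- matrix(rnorm(30 * 5), 30, 5)
  fit <- cssl(x, y, x_u, lambda_u = 1, sigma_delta = 0.1, max_iter = 2000)
  total <- fit$history[, "total"]
  sm <- stats::filter(total, rep(1 / 50, 50), sides = 1)
  sm <- sm[!is.na(sm)]
  # allow small stochastic wiggle from the redrawn perturbations
  expect_true(all(diff(sm) <= 0.02 * sm[-length(sm)] + 1e-8))
  expect_lt(sm[length(sm)], sm[1])
})

test_that("model methods expose coefficients, residuals and simulations", {
  set.seed(25)
  x <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("u", "v")))
  y <- as.vector(x %*% c(3, 1)) + 30 + rnorm(40, 0, 0.5)
  fit <- cssl(x, y, lambda_u = 0, max_iter = 20000, clamp = FALSE)
  expect_named(coef(fit), c("(bias)", "u", "v"))
  expect_equal(residuals(fit), y - fitted(fit), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(40, 3))
  s <- summary(fit)
  expect_s3_class(s, "summary.cssl")
  expect_lt(s$train$rmse, 1)
})

test_that("evaluation metrics match hand arithmetic and degenerate rules", {
  ev <- evaluate(c(0, 10), c(2, 8))
  expect_equal(ev$rmse, 2)
  expect_equal(ev$mae, 2)
  expect_equal(ev$r2, 0.84)
  perf <- evaluate(1:5, 1:5)
  expect_equal(c(perf$rmse, perf$mae, perf$r2), c(0, 0, 1))
  base <- evaluate(c(2, 4, 6), rep(4, 3))
  expect_equal(base$r2, 0)
  expect_true(is.na(evaluate(c(3, 3), c(1, 2))$r2))
  # RMSE >= MAE always
  set.seed(26)
  for (i in 1:5) {
    yt <- rnorm(20); yp <- rnorm(20)
    m <- evaluate(yt, yp)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("divergent learning rates raise a training error", {
  set.seed(27)
  x <- matrix(rnorm(30 * 3), 30, 3) * 10
  y <- rnorm(30, 28, 5)
  expect_error(cssl(x, y, learning_rate = 5, max_iter = 200),
               class = "training_error")
})
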