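test_that("constant observations give a flat posterior with no excess variance", {
  X <- matrix(runif(12), ncol = 2)
  m <- gp_fit(X, rep(0.42, 6), seed = 1)
  p <- gp_predict(m, matrix(runif(10), ncol = 2))
  expect_equal(p$mean, rep(0.42, 5), tolerance = 1e-6)
  expect_true(all(p$sd < 1e-3))
})

test_that("noiseless smooth 1-D samples are interpolated at the training points", {
  x <- matrix(seq(0, 1, length.out = 9), ncol = 1)
  y <- sin(2 * pi * x[, 1]) * 0.3 + 0.5
  m <- gp_fit(x, y, seed = 2)
  p <- gp_predict(m, x)
  expect_equal(p$mean, y, tolerance = 1e-4)
  expect_true(all(p$sd / m$y_sd < 1e-2))
})

test_that("fitted hyperparameters beat 100 random draws on the marginal likelihood", {
  set.seed(5)
  X <- matrix(runif(30), ncol = 2)
  y <- 0.8 * exp(-rowSums((X - 0.4)^2) * 3) + rnorm(15, 0, 0.01)
  m <- gp_fit(X, y, seed = 3)
  ys <- (y - m$y_mean) / m$y_sd
  for (i in 1:100) {
    theta <- c(log(runif(2, 0.01, 100)), log(runif(1, 1e-6, 1e3)),
               log(runif(1, 1e-8, 1)))
    expect_gte(m$log_marginal_likelihood + 1e-6,
               -flowbo:::gp_nll(theta, X, ys))
  }
})

test_that("posterior matches an independent dense linear-algebra reference", {
  # direct textbook GP formulas, written independently of the package path
  set.seed(9)
  for (rep in 1:5) {
    n <- 8; d <- 2
    X <- matrix(runif(n * d), ncol = d)
    y <- rowSums(sin(3 * X)) / 3
    m <- gp_fit(X, y, seed = rep)
    Xs <- matrix(runif(6 * d), ncol = d)
    p <- gp_predict(m, Xs)
    ys <- (y - m$y_mean) / m$y_sd
    K <- matern52_kernel(X, X, m$length_scales, m$kernel_variance) +
      diag(m$noise_variance + m$jitter, n)
    Ks <- matern52_kernel(Xs, X, m$length_scales, m$kernel_variance)
    Kss <- matern52_kernel(Xs, Xs, m$length_scales, m$kernel_variance)
    Kinv <- solve(K)
    mu_ref <- as.numeric(Ks %*% Kinv %*% ys) * m$y_sd + m$y_mean
    var_ref <- pmax(diag(Kss - Ks %*% Kinv %*% t(Ks)), 0)
    expect_equal(p$mean, mu_ref, tolerance = 1e-8)
    expect_equal(p$sd, sqrt(var_ref) * m$y_sd, tolerance = 1e-6)
  }
})

test_that("far from all data the posterior reverts to the prior", {
  # fix short length scales by hand so the query point is many length
  # scales from every training point
  X <- matrix(runif(10, 0, 0.3), ncol = 2)
  y <- runif(5, 0.2, 0.8)
  m <- gp_fit(X, y, seed = 4)
  m$length_scales[] <- 0.02
  K <- matern52_kernel(X, X, m$length_scales, m$kernel_variance) +
    diag(m$noise_variance, 5)
  m$L <- chol(K)
  m$alpha <- backsolve(m$L, forwardsolve(t(m$L), (y - m$y_mean) / m$y_sd))
  p <- gp_predict(m, matrix(c(1, 1), ncol = 2))
  expect_equal(p$mean, m$y_mean, tolerance = 1e-6)
  expect_equal(p$sd, sqrt(m$kernel_variance) * m$y_sd, tolerance = 1e-6)
})

test_that("predictions are invariant under permutation of the training points", {
  set.seed(21)
  X <- matrix(runif(20), ncol = 2)
  y <- rowSums(X^2) / 2
  perm <- sample(10)
  m1 <- gp_fit(X, y, seed = 6)
  m2 <- gp_fit(X[perm, ], y[perm], seed = 6)
  Xs <- matrix(runif(8), ncol = 2)
  p1 <- gp_predict(m1, Xs); p2 <- gp_predict(m2, Xs)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-4)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-4)
})

test_that("ARD length scales expose an irrelevant variable", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(runif(60 * 3), ncol = 3)
    y <- 0.7 * exp(-((X[, 1] - 0.4)^2 + (X[, 2] - 0.6)^2) * 4) +
      rnorm(60, 0, 0.005)  # column 3 is pure noise input
    m <- gp_fit(X, y, n_restarts = 3, seed = seed)
    imp <- gp_importance(m)
    if (imp$variable[3] == "x3") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("campaign-style telescoped data ranks the coil temperature least important", {
  # space-filling design over the telescoped bounds, evaluated on the
  # calibrated rig with 1% measurement noise — the data profile of a
  # campaign's exploration phase
  sp <- design_space_preset("telescoped")
  X <- lhs_design(sp, seed = 314, n_points = 40)
  y <- apply(X, 1, function(cond)
    simulate_telescoped(cond, params = kinetic_preset(),
                        preset = rig_preset("telescoped"))$yield_overall)
  set.seed(314)
  y <- y + rnorm(40, 0, 0.01)
  m <- gp_fit(to_unit(sp, X), y, seed = 314)
  imp <- gp_importance(m, sp)
  expect_equal(imp$variable[4], "T2")
})

test_that("exactly symmetric variables tie in the importance ranking", {
  set.seed(31)
  U <- matrix(runif(80), ncol = 2)
  X <- rbind(U, U[, 2:1])  # symmetrized design
  y <- exp(-((X[, 1] - 0.5)^2 + (X[, 2] - 0.5)^2) * 5)
  m <- gp_fit(X, y, seed = 8)
  expect_lt(abs(diff(m$length_scales)) / min(m$length_scales), 0.05)
  expect_true(all(gp_importance(m)$tied))
})

test_that("duplicate-only training data is rejected with advice", {
  X <- matrix(0.5, nrow = 4, ncol = 2)
  expect_error(gp_fit(X, runif(4)), "jitter|duplicate")
})

test_that("surrogate state serializes to JSON and back", {
  X <- matrix(runif(10), ncol = 2)
  y <- runif(5)
  m <- gp_fit(X, y, seed = 10)
  js <- jsonlite::fromJSON(gp_serialize(m))
  expect_equal(unlist(js$length_scales), unname(m$length_scales),
               ignore_attr = TRUE)
  expect_equal(js$noise_variance, m$noise_variance)
})
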