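# Matern covariance, spatial Gaussian-process fitting and prediction.

test_that("Matern nu=1 covariance: limits, range convention, monotone", {
  expect_equal(maternCov(0, 2.5, 1e4), 2.5)
  # at d = range the correlation is x K1(x) at x = sqrt(8) ~ 0.14
  oracle <- sqrt(8) * besselK(sqrt(8), 1)
  expect_equal(maternCov(1e4, 1, 1e4), oracle, tolerance = 1e-12)
  expect_lt(abs(oracle - 0.14), 0.005)

  d <- seq(0, 5e4, by = 100)
  cv <- maternCov(d, 1.3, 8000)
  expect_true(all(diff(cv) <= 1e-12))
  expect_true(all(cv >= 0))
  expect_error(maternCov(-1, 1, 1e4), ">= 0")
})

test_that("profile marginal likelihood matches dense direct evaluation", {
  for (n in c(40, 200)) {
    sim <- simGPData(n, beta = c(0.3, 0.2, -0.1), sigmaV2 = 0.5,
                     rangeM = 12000, sigmaE2 = 0.2, seed = n)
    X <- cbind(1, sim$X)
    for (hp in list(c(0.5, 12000, 0.2), c(0.1, 30000, 0.6))) {
      ll <- gpLogLik(X, sim$coords, sim$y, hp[1], hp[2], hp[3])
      # dense oracle: explicit covariance, determinant and solve
      S <- maternCov(as.matrix(dist(sim$coords)), hp[1], hp[2])
      diag(S) <- hp[1] + hp[3]
      Si <- solve(S)
      bh <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% sim$y)
      r <- sim$y - X %*% bh
      ref <- -0.5 * (n * log(2 * pi) +
                     determinant(S)$modulus[1] + t(r) %*% Si %*% r)
      expect_equal(ll, as.numeric(ref), tolerance = 1e-8)
    }
  }
})

test_that("GLS coefficients at fixed hyperparameters match brute force", {
  sim <- simGPData(25, beta = c(0.4, 0.25, -0.15), sigmaV2 = 0.4,
                   rangeM = 15000, sigmaE2 = 0.1, seed = 77)
  m <- fitGP(sim$design, sim$y,
             fixedHyper = c(sigmaV2 = 0.4, rangeM = 15000, sigmaE2 = 0.1))
  S <- maternCov(sim$D, 0.4, 15000); diag(S) <- 0.4 + 0.1
  X <- cbind(1, sim$X)
  bh <- solve(t(X) %*% solve(S) %*% X, t(X) %*% solve(S) %*% sim$y)
  expect_equal(m@beta, as.numeric(bh), tolerance = 1e-6)
})

test_that("with no spatial signal the GP matches ordinary least squares", {
  sim <- simGPData(300, beta = c(0.5, 0.1, -0.08), sigmaV2 = 0,
                   rangeM = 10000, sigmaE2 = 0.01, seed = 5)
  hold <- 251:300
  dtr <- makeDesign(sim$X[1:250, ], sim$coords[1:250, ])
  m <- fitGP(dtr, sim$y[1:250])
  X <- cbind(1, sim$X[1:250, ])
  bh <- solve(t(X) %*% X, t(X) %*% sim$y[1:250])      # OLS oracle
  seBeta <- sqrt(diag(solve(t(X) %*% X)) * 0.01)
  expect_true(all(abs(m@beta - sim$beta) <= 3 * pmax(seBeta, 1e-3)))

  lin <- fitLinear(dtr, sim$y[1:250])
  prG <- predictModel(m, sim$X[hold, ], coords = sim$coords[hold, ])
  prL <- predictModel(lin, sim$X[hold, ])
  evG <- computeMetrics(sim$y[hold], prG)@expVar
  evL <- computeMetrics(sim$y[hold], prL)@expVar
  expect_lt(abs(evG - evL), 0.1)
})

test_that("strong spatial structure gives the GP an edge over OLS", {
  sim <- simGPData(400, beta = c(0.4, 0.1, -0.1), sigmaV2 = 0.08,
                   rangeM = 12500, sigmaE2 = 0.02, seed = 9)
  tr <- 1:280; te <- 281:400
  dtr <- makeDesign(sim$X[tr, ], sim$coords[tr, ])
  m <- fitGP(dtr, sim$y[tr])
  lin <- fitLinear(dtr, sim$y[tr])
  evG <- computeMetrics(sim$y[te],
                        predictModel(m, sim$X[te, ],
                                     coords = sim$coords[te, ]))@expVar
  evL <- computeMetrics(sim$y[te], predictModel(lin, sim$X[te, ]))@expVar
  expect_gte(evG, evL + 0.05)
})

test_that("GP prediction interpolates, decays to the mean, sd >= 0", {
  sim <- simGPData(40, beta = c(0.5, 0.2), sigmaV2 = 0.3, rangeM = 10000,
                   sigmaE2 = 0.05, seed = 15)
  # near-zero nugget: the GP interpolates the training data
  m <- fitGP(sim$design, sim$y,
             fixedHyper = c(sigmaV2 = 0.3, rangeM = 10000, sigmaE2 = 1e-10))
  pr <- predictModel(m, sim$X, coords = sim$coords, clamp = FALSE)
  expect_equal(pr, sim$y, tolerance = 1e-6)

  # far from all data: mean -> X beta, latent sd -> sqrt(sigmaV2)
  mfit <- fitGP(sim$design, sim$y,
                fixedHyper = c(sigmaV2 = 0.3, rangeM = 10000,
                               sigmaE2 = 0.05))
  farX <- matrix(c(0.5, -0.5), 2, 1)
  farC <- cbind(c(1e7, 2e7), c(1e7, 2e7))
  pf <- predictModel(mfit, farX, coords = farC, se = TRUE, clamp = FALSE)
  expect_equal(pf$mean, as.numeric(cbind(1, farX) %*% mfit@beta),
               tolerance = 0.01)
  expect_equal(pf$sd, rep(sqrt(0.3), 2), tolerance = 0.01 * sqrt(0.3))

  prAll <- predictModel(mfit, sim$X, coords = sim$coords, se = TRUE)
  expect_true(all(prAll$sd >= 0))
  expect_error(predictModel(mfit, cbind(sim$X, sim$X), coords = sim$coords),
               "covariate")
})

test_that("baselines: trivial mean and linear model identities", {
  set.seed(8)
  y <- runif(50)
  mm <- fitMeanBaseline(y)
  expect_equal(mean((predictModel(mm, NULL, n = 50) - y)^2),
               mean((y - mean(y))^2))

  X <- matrix(rnorm(150), 50, 3)
  yy <- as.numeric(0.3 + X %*% c(0.2, -0.1, 0.05))
  lin <- fitLinear(makeDesign(X), yy)
  expect_equal(predictModel(lin, X), yy, tolerance = 1e-10)
  bh <- solve(t(cbind(1, X)) %*% cbind(1, X),
              t(cbind(1, X)) %*% yy)                  # normal equations
  expect_equal(lin@beta, as.numeric(bh), tolerance = 1e-10)
})
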