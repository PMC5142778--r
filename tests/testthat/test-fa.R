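test_that("a zero-factor model has no shared component", {
  set.seed(1)
  X <- matrix(rpois(200 * 8, 5), 200, 8)
  fit <- fitFA(X, 0)
  expect_identical(latentDim(fit), 0L)
  expect_identical(sharedDimensionality(fit), 0L)
  expect_true(all(percentSharedVariance(fit)$perNeuron == 0))
  # Psi equals the maximum-likelihood (1/n) sample variances
  expect_equal(independentVariances(fit),
               apply(X, 2, function(v) mean((v - mean(v))^2)),
               ignore_attr = TRUE)
})

test_that("EM increases the training likelihood monotonically", {
  set.seed(2)
  for (rep in 1:5) {
    spec <- threeFactorSpec(p = 15, seed = rep)
    X <- spikeCounts(sampleFACounts(spec, 150, seed = rep))
    fit <- suppressWarnings(fitFA(X, 3, tol = 1e-8, maxIter = 500))
    expect_gte(min(diff(fit@logLikTrace)), -1e-9 * abs(fit@logLik))
  }
})

test_that("likelihood agrees with the dense-covariance oracle", {
  set.seed(3)
  for (rep in 1:5) {
    p <- 10
    L <- matrix(rnorm(p * 2), p, 2)
    Psi <- runif(p, 0.5, 2)
    mu <- runif(p, 1, 5)
    model <- asFAModel(generativeFASpec(mu, L, Psi))
    X <- matrix(rnorm(40 * p, mean = 3), 40, p)
    expect_equal(logLikelihoodFA(X, model), denseLogLik(X, mu, L, Psi),
                 tolerance = 1e-8)
  }
})

test_that("likelihood closed forms at the mean hold", {
  n <- 7
  model <- asFAModel(generativeFASpec(rep(0, n), matrix(0, n, 0), rep(1, n)))
  # a single standard-normal observation at the mean
  expect_equal(logLikelihoodFA(matrix(0, 1, n), model), -n / 2 * log(2 * pi))
  # appending a trial equal to mu adds exactly -0.5*log det(2*pi*Sigma)
  set.seed(4)
  spec <- threeFactorSpec(p = 9, seed = 9)
  fit <- asFAModel(spec)
  X <- matrix(rnorm(30 * 9, 4), 30, 9)
  Sigma <- tcrossprod(spec@L) + diag(spec@Psi)
  delta <- logLikelihoodFA(rbind(X, spec@mu), fit) - logLikelihoodFA(X, fit)
  expect_equal(delta, -0.5 * determinant(2 * pi * Sigma)$modulus[[1]],
               tolerance = 1e-10)
})

test_that("generative three-factor structure is recovered", {
  spec <- threeFactorSpec(p = 80, seed = 33)
  cm <- sampleFACounts(spec, 2000, seed = 5)
  sel <- selectDimensionality(cm, mMax = 8, folds = 4, seed = 3)
  expect_identical(sel$mStar, 3L)
  fit <- fitFA(cm, 3)
  truth <- tcrossprod(spec@L)
  err <- norm(tcrossprod(fit@L) - truth, "F") / norm(truth, "F")
  expect_lt(err, 0.15)
})

test_that("cross-validation returns 0 for independent data", {
  spec <- generativeFASpec(mu = rep(5, 40), L = matrix(0, 40, 0),
                           Psi = rep(2, 40))
  cm <- sampleFACounts(spec, 600, seed = 7)
  sel <- cvSelectM(cm, 0:4, folds = 4, seed = 3)
  expect_identical(sel$mStar, 0L)
  # singleton grid is honored
  expect_identical(cvSelectM(cm, 0L, folds = 4, seed = 3)$mStar, 0L)
})

test_that("fitting guards reject degenerate inputs", {
  X <- matrix(rpois(50 * 5, 4), 50, 5)
  expect_error(fitFA(X, 5), "neurons - 1")
  X2 <- cbind(X, 3)
  expect_error(fitFA(X2, 1), "zero-variance")
  expect_error(cvSelectM(X[1:3, ], 0:1, folds = 4), "folds")
  model <- suppressWarnings(fitFA(X, 1))
  expect_error(logLikelihoodFA(X2, model), "disagree")
  w <- capture_warnings(fitFA(X[1:4, ], 1, maxIter = 50))
  expect_true(any(grepl("trials", w)))
})

test_that("shared dimensionality implements the 95% rule", {
  expect_identical(sharedDimensionality(c(10, 0.2)), 1L)
  expect_identical(sharedDimensionality(rep(1, 50)), 48L)
  expect_identical(sharedDimensionality(numeric(0)), 0L)
  # generic cumulative-sum oracle on random spectra
  set.seed(8)
  for (rep in 1:20) {
    lam <- sort(rexp(sample(2:12, 1)), decreasing = TRUE)
    k <- sharedDimensionality(lam)
    expect_true(sum(lam[seq_len(k)]) >= 0.95 * sum(lam))
    if (k > 1) expect_true(sum(lam[seq_len(k - 1)]) < 0.95 * sum(lam))
  }
})

test_that("per-neuron and per-mode shared-variance metrics are consistent", {
  # hand-computable cases
  m2 <- asFAModel(generativeFASpec(c(0, 0), matrix(1, 2, 1), c(1, 1)))
  expect_equal(percentSharedVariance(m2)$perNeuron, c(50, 50))
  expect_equal(perModePercentSharedVariance(m2), 50)
  expect_equal(modeVarianceFractions(sharedSpectrum(
    asFAModel(generativeFASpec(rep(0, 3),
                               cbind(c(sqrt(3), 0, 0), c(0, 1, 0)),
                               rep(1, 3))))), c(75, 25))
  # identities on random fitted models: mode fractions sum to 100, the
  # per-neuron decomposition sums across modes to the per-neuron value,
  # and the eigenvalue sum matches the trace of LL^T
  set.seed(9)
  for (rep in 1:10) {
    p <- sample(5:12, 1)
    X <- matrix(rnorm(80 * p, 10, 2), 80, p) +
      rnorm(80) %o% runif(p, 0.3, 1)
    fit <- suppressWarnings(fitFA(X, sample(1:3, 1), tol = 1e-7,
                                  maxIter = 300))
    spec <- sharedSpectrum(fit)
    expect_equal(sum(modeVarianceFractions(spec)), 100, tolerance = 1e-10)
    denom <- rowSums(fit@L^2) + fit@Psi
    perModeNeuron <- sweep(spec@vectors^2, 2, spec@values, `*`)
    expect_equal(100 * rowSums(perModeNeuron) / denom,
                 percentSharedVariance(fit)$perNeuron, tolerance = 1e-10)
    expect_equal(sum(spec@values), sum(fit@L^2), tolerance = 1e-8)
    expect_equal(mean(perModePercentSharedVariance(fit, spec)) *
                   length(spec@values),
                 sum(perModePercentSharedVariance(fit, spec)))
    expect_equal(sum(perModePercentSharedVariance(fit, spec)),
                 percentSharedVariance(fit)$population, tolerance = 1e-10)
    # a one-mode model's single per-mode value is the population mean
    fit1 <- suppressWarnings(fitFA(X, 1, tol = 1e-7, maxIter = 300))
    expect_equal(perModePercentSharedVariance(fit1),
                 percentSharedVariance(fit1)$population, tolerance = 1e-10)
  }
})

test_that("estimation error shrinks with trial count", {
  spec <- threeFactorSpec(p = 30, seed = 44)
  truth <- tcrossprod(spec@L)
  errs <- vapply(c(500, 2000, 8000), function(n) {
    fit <- fitFA(sampleFACounts(spec, n, seed = 10), 3)
    norm(tcrossprod(fit@L) - truth, "F") / norm(truth, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("d_shared never exceeds the model rank", {
  set.seed(11)
  for (rep in 1:5) {
    spec <- threeFactorSpec(p = 12, seed = rep + 50)
    fit <- suppressWarnings(fitFA(spikeCounts(sampleFACounts(spec, 300,
                                                             seed = rep)),
                                  sample(0:4, 1), maxIter = 300))
    expect_lte(sharedDimensionality(fit), latentDim(fit))
  }
  # appending an extra orthogonal mode cannot reduce d_shared
  lam <- c(5, 2, 1)
  expect_gte(sharedDimensionality(c(lam, 0.8)), sharedDimensionality(lam))
})
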