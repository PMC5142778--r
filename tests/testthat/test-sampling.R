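test_that("nested subsets grow by augmentation", {
  sets <- nestedNeuronSubsets(1:80, c(10, 20, 40), seed = 1)
  expect_identical(lengths(sets), c(10L, 20L, 40L))
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
  expect_identical(sort(nestedNeuronSubsets(1:15, 15, seed = 2)[[1]]), 1:15)
  expect_error(nestedNeuronSubsets(1:10, c(5, 5), seed = 1), "increasing")
  expect_error(nestedNeuronSubsets(1:10, c(5, 20), seed = 1), "pool")
})

test_that("nested subset draws are uniform over the pool", {
  counts <- integer(80)
  for (s in 1:1000) {
    idx <- nestedNeuronSubsets(1:80, 10, seed = s)[[1]]
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts / 1000
  se <- sqrt(0.125 * 0.875 / 1000)
  expect_true(all(abs(freq - 0.125) < 4 * se))
})

test_that("disjoint sets partition without overlap", {
  sets <- disjointSets(1:400, 5, 80, seed = 3)
  expect_identical(length(unique(unlist(sets))), 400L)
  for (i in 1:4) for (j in (i + 1):5)
    expect_identical(intersect(sets[[i]], sets[[j]]), integer(0))
  expect_identical(length(disjointSets(1:50, 1, 20, seed = 1)[[1]]), 20L)
  expect_error(disjointSets(1:100, 5, 30, seed = 1), "too small")
})

test_that("cluster-balanced sampling controls representation", {
  labels <- rep(1:50, each = 80)
  for (N in c(1L, 10L, 50L)) {
    idx <- clusterBalancedSample(labels, N, total = 50, seed = N)
    expect_identical(length(idx), 50L)
    expect_identical(length(unique(labels[idx])), as.integer(N))
    expect_true(all(table(labels[idx]) == 50 / N))
  }
  expect_error(clusterBalancedSample(labels, 7L, total = 50), "divide")
})

test_that("independent data yields flat zero scaling curves", {
  spec <- generativeFASpec(mu = rep(5, 60), L = matrix(0, 60, 0),
                           Psi = rep(2, 60))
  cm <- sampleFACounts(spec, 320, seed = 9)
  tab <- scalingExperiment(cm, axis = "neurons", grid = c(10, 20),
                           fixed = 150, nNeuronSets = 2, nTrialSets = 2,
                           faOpts = list(mMax = 3), seed = 4)
  expect_true(all(tab$dShared == 0))
  expect_true(all(tab$psv == 0))
  agg <- aggregateScaling(tab)
  expect_identical(agg$reps, c(4L, 4L))
  # stored standard errors recompute from the per-repeat values
  for (v in agg$value) {
    d <- tab$dShared[tab$value == v]
    expect_equal(agg$dSharedSE[agg$value == v], sd(d) / sqrt(length(d)))
  }
})

test_that("clustered network scaling dissociates from non-clustered", {
  fxC <- toyStudyRun(clustered = TRUE)
  fxN <- toyStudyRun(clustered = FALSE)
  tabC <- scalingExperiment(fxC$counts, axis = "neurons",
                            grid = c(10, 20, 40), fixed = 300,
                            nNeuronSets = 3, nTrialSets = 1,
                            neuronPool = fxC$pool,
                            faOpts = list(mMax = 12), seed = 5)
  aggC <- aggregateScaling(tabC)
  expect_true(all(aggC$dShared > 0))
  expect_true(all(diff(aggC$dShared) >= 0))
  tabN <- scalingExperiment(fxN$counts, axis = "neurons", grid = 40,
                            fixed = 300, nNeuronSets = 3, nTrialSets = 1,
                            neuronPool = fxN$pool,
                            faOpts = list(mMax = 8), seed = 5)
  # the clustered network carries far more shared structure at equal size
  expect_gt(mean(tabC$dShared[tabC$value == 40]), mean(tabN$dShared))
  expect_gt(mean(tabC$psv[tabC$value == 40]), mean(tabN$psv))
})

test_that("trial sweeps saturate on clustered-network data", {
  fx <- toyStudyRun(clustered = TRUE)
  tab <- scalingExperiment(fx$counts, axis = "trials",
                           grid = c(75, 150, 300), fixed = 30,
                           nNeuronSets = 3, nTrialSets = 1,
                           neuronPool = fx$pool,
                           faOpts = list(mMax = 10), seed = 6)
  agg <- aggregateScaling(tab)
  expect_true(all(diff(agg$dShared) >= 0) || # non-decreasing, or saturated:
                abs(diff(tail(agg$dShared, 2))) <=
                  sum(tail(agg$dSharedSE, 2)) + 1e-9)
})

test_that("count autocorrelation matches known processes", {
  set.seed(10)
  # i.i.d. counts: all non-zero lags within noise
  X <- matrix(rpois(500 * 40, 5), 500, 40)
  ac <- countAutocorrelation(countMatrix(X), maxLag = 5)
  expect_equal(ac$mean[1], 1)
  expect_true(all(abs(ac$mean[-1]) < 3 * ac$se[-1] + 1e-12))
  # AR(1) with rho = 0.5 shows up at lag 1
  rho <- 0.5
  Y <- matrix(0, 600, 30)
  Y[1, ] <- rnorm(30)
  for (t in 2:600) Y[t, ] <- rho * Y[t - 1, ] + rnorm(30)
  ac2 <- countAutocorrelation(countMatrix(Y + 10), maxLag = 3)
  expect_lt(abs(ac2$mean[2] - rho), 3 * ac2$se[2])
  # constant neurons are flagged and excluded
  Z <- cbind(X[, 1:5], 7)
  ac3 <- countAutocorrelation(countMatrix(Z), maxLag = 2)
  expect_identical(ac3$excluded, 6L)
  expect_true(all(is.na(ac3$perNeuron[6, ])))
})

test_that("simulated 1-s counts have near-zero autocorrelation beyond lag 0", {
  fx <- toyStudyRun(clustered = FALSE)
  ac <- countAutocorrelation(fx$counts[, fx$pool], maxLag = 5)
  expect_equal(ac$mean[1], 1)
  expect_true(all(abs(ac$mean[-1]) < 0.1))
})

test_that("trial spacing does not change the metrics for exchangeable data", {
  spec <- generativeFASpec(mu = rep(5, 30), L = matrix(0, 30, 0),
                           Psi = rep(2, 30))
  cm <- sampleFACounts(spec, 450, seed = 11)
  tab <- trialSpacingCheck(cm, nTrialsUsed = 120, spacings = c(0, 1, 2),
                           faOpts = list(mMax = 2), seed = 12)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$dShared == 0))
  tab2 <- trialSpacingCheck(cm, nTrialsUsed = 120, spacings = c(0, 1, 2),
                            faOpts = list(mMax = 2), seed = 12)
  expect_identical(tab, tab2)
  expect_error(trialSpacingCheck(cm, nTrialsUsed = 200, spacings = 2),
               "not enough")
})
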