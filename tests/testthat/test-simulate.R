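test_that("synaptic filter has the closed-form shape", {
  expect_identical(synapticFilter(0, 1, 3), 0)
  expect_true(all(synapticFilter(seq(0, 50, by = 0.1), 1, 3) >= 0))
  expect_error(synapticFilter(1, 3, 3), "tau1")
  expect_error(synapticFilter(-1, 1, 3), "non-negative")
  # unit normalization for several (tau1, tau2) pairs
  for (taus in list(c(1, 3), c(1, 2), c(0.5, 7))) {
    q <- stats::integrate(synapticFilter, 0, Inf, tau1 = taus[1],
                          tau2 = taus[2], rel.tol = 1e-10)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  # peak location from dF/dt = 0
  tGrid <- seq(0, 10, by = 1e-4)
  tStar <- tGrid[which.max(synapticFilter(tGrid, 1, 3))]
  expect_equal(tStar, 1.5 * log(3), tolerance = 1e-3)
})

# uncoupled LIF neuron with constant bias mu fires with
# ISI = tau * log((mu - vReset)/(mu - vThreshold)) + refractory
test_that("uncoupled neuron reproduces the closed-form interspike interval", {
  cfg <- networkConfig(nExcitatory = 1L, nInhibitory = 0L,
                       biasRange = rbind(E = c(1.15, 1.15), I = c(1, 1)),
                       p = matrix(0, 2, 2,
                                  dimnames = list(c("E", "I"), c("E", "I"))))
  net <- buildNetwork(cfg, seed = 1)
  sp <- simulateNetwork(net, duration = 3, seed = 2)
  isi <- diff(sp@events$time) * 1000
  expected <- 15 * log(1.15 / 0.15) + 5
  expect_true(all(abs(isi - expected) <= cfg@dt + 1e-9))
  rate <- nrow(sp@events) / 3
  expect_equal(rate, 1000 / expected, tolerance = 0.02)
})

test_that("subthreshold neurons stay silent", {
  cfg <- networkConfig(nExcitatory = 3L, nInhibitory = 0L,
                       biasRange = rbind(E = c(0.9, 0.99), I = c(1, 1)),
                       p = matrix(0, 2, 2,
                                  dimnames = list(c("E", "I"), c("E", "I"))))
  net <- buildNetwork(cfg, seed = 1)
  sp <- simulateNetwork(net, duration = 2, seed = 2)
  expect_identical(nrow(sp@events), 0L)
})

test_that("no neuron violates the refractory period", {
  fx <- miniClusteredSim()
  ev <- fx$spikes@events
  isiMin <- min(vapply(split(ev$time, ev$neuron), function(tt)
    if (length(tt) > 1) min(diff(tt)) else Inf, numeric(1)))
  expect_gte(isiMin * 1000, fx$config@refractory)
})

test_that("identical configuration and seeds reproduce the spike record", {
  cfg <- toyNetworkConfig(0.05)
  net <- buildNetwork(cfg, seed = 3)
  a <- simulateNetwork(net, duration = 6, seed = 4)
  b <- simulateNetwork(net, duration = 6, seed = 4)
  expect_identical(a@events, b@events)
  c <- simulateNetwork(net, duration = 6, seed = 5)
  expect_false(identical(a@events, c@events))
})

test_that("halving the integration step leaves firing rates converged", {
  # uncoupled population: trajectories are deterministic, so per-neuron
  # rates must agree
  cfg <- networkConfig(nExcitatory = 40L, nInhibitory = 10L,
                       p = matrix(0, 2, 2,
                                  dimnames = list(c("E", "I"), c("E", "I"))))
  net <- buildNetwork(cfg, seed = 6)
  r <- sapply(c(0.05, 0.025), function(dt) {
    sp <- simulateNetwork(net, duration = 22, seed = 7, dt = dt)
    binSpikeCounts(sp, 1, neurons = seq_len(50), burnIn = 2)@meanRate
  })
  expect_lt(max(abs(r[, 2] - r[, 1]) / r[, 1]), 0.01)
  # recurrent network: individual trajectories are chaotic, but the
  # population mean rate converges
  fx <- miniClusteredSim()
  rp <- sapply(c(0.05, 0.025), function(dt) {
    sp <- simulateNetwork(fx$network, duration = 22, seed = 8, dt = dt)
    mean(binSpikeCounts(sp, 1, neurons = seq_len(250))@meanRate)
  })
  expect_lt(abs(rp[2] - rp[1]) / rp[1], 0.01)
})

test_that("dt must divide the refractory period", {
  cfg <- toyNetworkConfig(0.05)
  net <- buildNetwork(cfg, seed = 1)
  expect_error(simulateNetwork(net, duration = 1, seed = 1, dt = 0.3),
               "refractory")
})

test_that("binning counts events into half-open bins", {
  ev <- data.frame(neuron = c(1L, 1L), time = c(0.5, 1.5))
  sp <- new("SpikeRecord", events = ev, duration = 2, config = NULL)
  cm <- binSpikeCounts(sp, binWidth = 1, burnIn = 0, neurons = 1L)
  expect_identical(as.vector(spikeCounts(cm)), c(1, 1))
  # spike exactly on a bin edge belongs to the later bin
  sp2 <- new("SpikeRecord",
             events = data.frame(neuron = 1L, time = 1.0),
             duration = 2, config = NULL)
  cm2 <- binSpikeCounts(sp2, 1, burnIn = 0, neurons = 1L)
  expect_identical(as.vector(spikeCounts(cm2)), c(0, 1))
  expect_error(binSpikeCounts(sp, 1, burnIn = 0, neurons = integer(0)),
               "non-empty")
})

test_that("binning conserves events and scales with bin width", {
  fx <- miniClusteredSim()
  sp <- fx$spikes
  cfg <- fx$config
  neurons <- seq_len(cfg@nExcitatory)
  for (bw in c(0.2, 0.5, 1.0)) {
    cm <- binSpikeCounts(sp, bw, burnIn = 2, neurons = neurons)
    expect_identical(nrow(cm@counts), as.integer(floor((sp@duration - 2) / bw)))
    retained <- sum(sp@events$time >= 2 &
                      sp@events$time < 2 + nrow(cm@counts) * bw &
                      sp@events$neuron <= cfg@nExcitatory)
    expect_identical(sum(cm@counts), retained)
  }
})

test_that("same-cluster pairs covary more than cross-cluster pairs", {
  fx <- toyStudyRun(clustered = TRUE)
  X <- spikeCounts(fx$counts)
  lab <- clusterLabels(fx$counts)
  cv <- stats::cov(X)
  same <- outer(lab, lab, "==") & upper.tri(cv)
  diffc <- outer(lab, lab, "!=") & upper.tri(cv)
  expect_gt(mean(cv[same]), mean(cv[diffc]))
})
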