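# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small clustered network (200 E in 10 clusters of 20, 50 I) and a short run:
# used for connectivity/dynamics property tests
miniClusteredSim <- function() fixture("miniClustered", function() {
  cfg <- toyNetworkConfig(0.05)
  net <- buildNetwork(cfg, seed = 101)
  spikes <- simulateNetwork(net, duration = 34, seed = 202)
  counts <- binSpikeCounts(spikes, 1, neurons = seq_len(cfg@nExcitatory),
                           network = net)
  list(config = cfg, network = net, spikes = spikes, counts = counts)
})

# desk-scale study conditions: 400 E in 10 clusters of 40, ~300 one-second
# trials from one continuous run (clustered and non-clustered variants)
toyStudyRun <- function(clustered) {
  name <- if (clustered) "studyClustered" else "studyNonclustered"
  fixture(name, function() {
    cfg <- toyNetworkConfig(0.1, clustered = clustered)
    net <- buildNetwork(cfg, seed = 11)
    spikes <- simulateNetwork(net, duration = 302, seed = 12)
    counts <- binSpikeCounts(spikes, 1, neurons = seq_len(cfg@nExcitatory),
                             network = net)
    list(config = cfg, network = net, counts = counts,
         pool = activeNeurons(counts))
  })
}

# a well-conditioned 3-factor generative spec used across recovery tests
threeFactorSpec <- function(p = 80, seed = 33) {
  set.seed(seed)
  L <- matrix(rnorm(p * 3, sd = 0.7), p, 3)
  generativeFASpec(mu = runif(p, 2, 8), L = L, Psi = runif(p, 0.5, 2))
}

# dense-covariance Gaussian log-likelihood: the brute-force oracle against
# which the Woodbury implementation is checked
denseLogLik <- function(X, mu, L, Psi) {
  S <- tcrossprod(L) + diag(Psi, length(Psi))
  ch <- chol(S)
  logDet <- 2 * sum(log(diag(ch)))
  Xc <- sweep(X, 2, mu)
  q <- colSums(forwardsolve(t(ch), t(Xc))^2)  # one quadratic form per trial
  sum(-0.5 * (ncol(X) * log(2 * pi) + logDet + q))
}

# classical Gram-Schmidt orthonormalization (independent of qr()) for the
# brute-force principal-angle route
gramSchmidt <- function(M) {
  Q <- matrix(0, nrow(M), 0)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) Q <- cbind(Q, v / nv)
  }
  Q
}
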