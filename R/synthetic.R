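# Seed-deterministic generators producing data with the statistical
# structure the analysis assumes, so every pipeline stage is testable
# without recordings.

#' Construct a generative factor-analysis specification
#'
#' @param mu per-neuron mean counts per trial.
#' @param L loading matrix (neurons x m_true); a p x 0 matrix gives
#'   independent neurons.
#' @param Psi per-neuron independent variances (> 0).
#' @param poissonize replace each Gaussian draw by a Poisson count with the
#'   draw (truncated at zero) as its rate.
#' @return a [GenerativeFASpec-class].
#' @export
generativeFASpec <- function(mu, L, Psi, poissonize = FALSE) {
  new("GenerativeFASpec", mu = as.numeric(mu), L = as.matrix(L),
      Psi = as.numeric(Psi), poissonize = poissonize)
}

#' Sample trials from a generative factor-analysis model
#'
#' Draws latents \eqn{z \sim N(0, I_m)} per trial and emits
#' \eqn{x = \mu + Lz + \epsilon} with \eqn{\epsilon \sim N(0, \Psi)}; with
#' Poissonization on, each x is used as a rate (truncated at 0) for a
#' Poisson count. As trials grow, the sample mean converges to \eqn{\mu}
#' and the sample covariance to \eqn{LL^T + \Psi}.
#'
#' @param spec a [GenerativeFASpec-class].
#' @param nTrials number of trials to draw.
#' @param seed RNG seed (fixed seed gives bit-identical output).
#' @param binWidth nominal bin width (s) recorded in the result.
#' @return a [CountMatrix-class], trials x neurons.
#' @export
sampleFACounts <- function(spec, nTrials, seed = 1L, binWidth = 1) {
  validObject(spec)
  p <- length(spec@mu)
  m <- ncol(spec@L)
  withSeed(seed, {
    X <- matrix(stats::rnorm(nTrials * p, sd = rep(sqrt(spec@Psi),
                                                   each = nTrials)),
                nTrials, p)
    if (m > 0) {
      Z <- matrix(stats::rnorm(nTrials * m), nTrials, m)
      X <- X + Z %*% t(spec@L)
    }
    X <- sweep(X, 2, spec@mu, `+`)
    if (spec@poissonize)
      X <- matrix(stats::rpois(length(X), pmax(X, 0)), nTrials, p)
    countMatrix(X, binWidth = binWidth)
  })
}

#' In-vivo-like generative parameters
#'
#' Builds a [GenerativeFASpec-class] emulating the stated structure of
#' spontaneous V1 population activity at 1-second bins: a dominant
#' same-sign co-fluctuation mode carrying more than 60% of the shared
#' variance, a handful of weaker mixed-sign modes, and independent
#' variances scaled so that every neuron's percent shared variance equals
#' the requested overall value (making the population mean exact by
#' construction).
#'
#' The first mode's entries are drawn as \eqn{|N(1, 0.25)|} (all one sign:
#' a population-wide up/down co-fluctuation); the remaining modes are
#' random directions orthogonalized against it, with geometrically decaying
#' eigenvalues filling the remaining shared variance.
#'
#' @param nNeurons number of neurons (default 80).
#' @param firstModeShare fraction of shared variance on the first mode
#'   (default 0.65; must exceed 0 and be at most 1).
#' @param overallPSV overall percent shared variance (default 51.8;
#'   0 yields an m = 0 spec).
#' @param nModes total number of shared modes (default 5).
#' @param seed RNG seed.
#' @return a [GenerativeFASpec-class].
#' @export
makeInvivoLikeParams <- function(nNeurons = 80L, firstModeShare = 0.65,
                                 overallPSV = 51.8, nModes = 5L, seed = 1L) {
  p <- as.integer(nNeurons)
  if (overallPSV < 0 || overallPSV >= 100)
    stop("overallPSV must lie in [0, 100)")
  if (firstModeShare <= 0 || firstModeShare > 1)
    stop("firstModeShare must lie in (0, 1]")
  withSeed(seed, {
    mu <- stats::rlnorm(p, meanlog = log(3), sdlog = 0.6)  # counts per 1-s trial
    if (overallPSV == 0) {
      return(generativeFASpec(mu, matrix(0, p, 0), Psi = mu))
    }
    m <- if (firstModeShare == 1) 1L else as.integer(nModes)
    # eigenvalue profile: first mode takes firstModeShare of the total,
    # the rest decays geometrically
    totalShared <- mean(mu) * overallPSV / 100 * p
    lam <- numeric(m)
    lam[1] <- firstModeShare * totalShared
    if (m > 1) {
      decay <- 0.6 ^ seq_len(m - 1)
      lam[-1] <- (1 - firstModeShare) * totalShared * decay / sum(decay)
    }
    v1 <- abs(stats::rnorm(p, mean = 1, sd = 0.5))
    V <- cbind(v1 / sqrt(sum(v1^2)))
    if (m > 1) {
      R <- matrix(stats::rnorm(p * (m - 1)), p, m - 1)
      R <- R - V %*% crossprod(V, R)
      V <- cbind(V, qr.Q(qr(R))[, seq_len(m - 1), drop = FALSE])
    }
    L <- V %*% diag(sqrt(lam), m, m)
    sh <- rowSums(L^2)
    Psi <- sh * (100 - overallPSV) / overallPSV
    generativeFASpec(mu, L, Psi)
  })
}

#' Convert a generative specification to a fitted-model object
#'
#' Wraps the ground-truth parameters of a [GenerativeFASpec-class] in an
#' [FAModel-class] so the full metrics pipeline ([sharedSpectrum()],
#' [percentSharedVariance()], [modeVarianceFractions()],
#' [perModePercentSharedVariance()]) can run on the exact parameters.
#'
#' @param spec a [GenerativeFASpec-class].
#' @return an [FAModel-class] (fit metadata is vacuous).
#' @export
asFAModel <- function(spec) {
  p <- length(spec@mu)
  new("FAModel", mu = spec@mu, L = spec@L, Psi = spec@Psi,
      m = ncol(spec@L), neuronIds = seq_len(p), nObs = 0L,
      logLik = NA_real_, logLikTrace = numeric(0), iterations = 0L,
      converged = TRUE)
}

#' Reduced desk-scale network configuration
#'
#' Scales the canonical network down for desk-scale experiments while
#' preserving the connectivity structure: the within/between-cluster
#' probability ratio (0.4854 / 0.1942) is kept exactly and the
#' pair-count-weighted mean E-to-E connection probability stays 0.2.
#' Synaptic weights are rescaled by \code{jScale} (default
#' \code{1/sqrt(scale)}, the balanced-network convention J ~ 1/sqrt(N))
#' to keep firing in a plausible irregular regime at reduced size.
#'
#' At \code{scale = 1} the canonical presets are returned exactly. At
#' \code{scale = 0.1}, for example, the clustered variant has 400
#' excitatory neurons in 10 clusters of 40 plus 100 inhibitory neurons.
#'
#' @param scale population scale factor in (0, 1].
#' @param clustered clustered or non-clustered variant.
#' @param jScale synaptic weight multiplier (default \code{1/sqrt(scale)}).
#' @param dt integration step (ms).
#' @param burnIn discarded interval (s).
#' @return a [NetworkConfig-class].
#' @export
toyNetworkConfig <- function(scale, clustered = TRUE, jScale = NULL,
                             dt = 0.05, burnIn = 2) {
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  if (scale == 1) {
    return(if (clustered) clusteredNetworkConfig(dt = dt, burnIn = burnIn)
           else nonclusteredNetworkConfig(dt = dt, burnIn = burnIn))
  }
  cs <- min(80L, as.integer(round(400 * scale)))
  if (cs < 2L) stop("scale too small: clusters would have fewer than 2 neurons")
  nClusters <- max(2L, as.integer(round(4000 * scale / cs)))
  nE <- nClusters * cs
  nI <- max(1L, as.integer(round(1000 * scale)))
  if (is.null(jScale)) jScale <- 1 / sqrt(scale)

  ratio <- 0.4854 / 0.1942
  wIn <- (cs - 1) / (nE - 1)
  pOut <- 0.2 / (wIn * ratio + (1 - wIn))
  pIn <- ratio * pOut

  J <- rbind(E = c(E = 0.024, I = -0.045), I = c(E = 0.014, I = -0.057)) * jScale
  networkConfig(nExcitatory = nE, nInhibitory = nI, J = J,
                nClusters = if (clustered) nClusters else 0L,
                clusterSize = if (clustered) cs else 0L,
                pInEE = pIn, pOutEE = pOut,
                jInEE = 0.0456 * jScale, jOutEE = 0.024 * jScale,
                dt = dt, burnIn = burnIn)
}

setMethod("show", "GenerativeFASpec", function(object) {
  cat(sprintf("GenerativeFASpec: %d neurons, %d true factors%s\n",
              length(object@mu), ncol(object@L),
              if (object@poissonize) ", Poissonized" else ""))
})
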