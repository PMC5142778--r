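#' Difference-of-exponentials synaptic filter
#'
#' The postsynaptic current kernel
#' \deqn{F(t) = \frac{e^{-t/\tau_2} - e^{-t/\tau_1}}{\tau_2 - \tau_1}}
#' with rise constant \eqn{\tau_1} and decay constant \eqn{\tau_2}
#' (\eqn{\tau_1 < \tau_2}). F(0) = 0, F is non-negative, and it integrates
#' to 1, so synaptic weights J carry the full charge of one spike.
#'
#' @param t time since the presynaptic spike (ms), vectorized, \code{t >= 0}.
#' @param tau1 rise time constant (ms).
#' @param tau2 decay time constant (ms).
#' @return filter value(s) in 1/ms.
#' @examples
#' synapticFilter(1.5 * log(3), 1, 3)  # the peak for tau1=1, tau2=3
#' @export
synapticFilter <- function(t, tau1, tau2) {
  if (tau1 >= tau2) stop("tau1 must be strictly less than tau2")
  if (any(t < 0)) stop("t must be non-negative")
  (exp(-t / tau2) - exp(-t / tau1)) / (tau2 - tau1)
}

#' Simulate spiking dynamics of a network
#'
#' Integrates the leaky-integrate-and-fire dynamics
#' \eqn{\dot V = (\mu - V)/\tau + I_{syn}} for every neuron with
#' exponential-Euler steps of \code{dt} ms, an absolute refractory period,
#' and synaptic currents built from the difference-of-exponentials filter
#' ([synapticFilter()]) applied to presynaptic spike trains. Per-neuron
#' biases are drawn once per simulation from the configured uniform ranges,
#' and initial voltages uniformly on \code{[vReset, vThreshold)}; both come
#' from \code{seed}, so identical (network, seed) pairs reproduce the spike
#' record exactly.
#'
#' @param network a [Network-class] from [buildNetwork()].
#' @param duration simulated time (s).
#' @param seed dynamics RNG seed (biases and initial conditions).
#' @param dt integration step (ms); defaults to the config's \code{dt}. The
#'   refractory period must be a whole number of steps.
#' @return a [SpikeRecord-class].
#' @export
simulateNetwork <- function(network, duration, seed = 1L, dt = NULL) {
  config <- network@config
  if (is.null(dt)) dt <- config@dt
  if (duration <= 0) stop("duration must be positive")
  stepsPerRef <- config@refractory / dt
  if (abs(stepsPerRef - round(stepsPerRef)) > 1e-9)
    stop("dt must divide the refractory period evenly")

  n <- nNeurons(network)
  isE <- network@populationLabel == "E"
  tauM <- ifelse(isE, config@tauM["E"], config@tauM["I"])

  res <- withSeed(seed, {
    bias <- numeric(n)
    bias[isE] <- stats::runif(sum(isE), config@biasRange["E", "min"],
                              config@biasRange["E", "max"])
    bias[!isE] <- stats::runif(sum(!isE), config@biasRange["I", "min"],
                               config@biasRange["I", "max"])
    v0 <- stats::runif(n, config@vReset, config@vThreshold)
    w <- methods::as(network@weights, "CsparseMatrix")
    simulate_lif_cpp(w@p, w@i, w@x, as.integer(isE), tauM, bias, v0,
                     config@vThreshold, config@vReset, config@refractory,
                     config@tauRise, config@tauDecay["E"], config@tauDecay["I"],
                     dt, duration)
  })
  ev <- data.frame(neuron = res$neuron, time = res$time)
  ev <- ev[order(ev$time, ev$neuron), , drop = FALSE]
  rownames(ev) <- NULL
  new("SpikeRecord", events = ev, duration = duration, config = config)
}

#' Bin a spike record into a trials x neurons count matrix
#'
#' Counts the spikes of the requested neurons in consecutive half-open bins
#' \code{[t, t + binWidth)} after discarding the burn-in; a partial trailing
#' bin is dropped. Each bin is one "trial" of spontaneous activity.
#'
#' @param spikes a [SpikeRecord-class].
#' @param binWidth bin width in seconds (default 1).
#' @param burnIn seconds discarded from the start (defaults to the config's
#'   burn-in, or 0 without a config).
#' @param neurons integer neuron indices to keep (default: all neurons that
#'   the config declares, or all observed).
#' @param clusterLabel optional integer cluster label per requested neuron;
#'   taken from a supplied [Network-class] via \code{network} if given.
#' @param network optional [Network-class], used for cluster labels.
#' @return a [CountMatrix-class].
#' @export
binSpikeCounts <- function(spikes, binWidth = 1, burnIn = NULL, neurons = NULL,
                           clusterLabel = NULL, network = NULL) {
  if (binWidth <= 0) stop("binWidth must be positive")
  config <- spikes@config
  if (is.null(burnIn)) burnIn <- if (is(config, "NetworkConfig")) config@burnIn else 0
  if (burnIn >= spikes@duration) stop("burnIn must be smaller than the duration")
  if (is.null(neurons)) {
    neurons <- if (is(config, "NetworkConfig"))
      seq_len(config@nExcitatory + config@nInhibitory)
    else sort(unique(spikes@events$neuron))
  }
  neurons <- as.integer(neurons)
  if (!length(neurons)) stop("neuron subset must be non-empty")

  nBins <- floor((spikes@duration - burnIn) / binWidth)
  if (nBins < 1) stop("no complete bin fits after the burn-in")
  ev <- spikes@events
  keep <- ev$neuron %in% neurons & ev$time >= burnIn &
    ev$time < burnIn + nBins * binWidth
  ev <- ev[keep, , drop = FALSE]
  binIdx <- floor((ev$time - burnIn) / binWidth) + 1L
  neuronIdx <- match(ev$neuron, neurons)
  counts <- matrix(0L, nrow = nBins, ncol = length(neurons))
  if (nrow(ev)) {
    tab <- table(factor(binIdx, levels = seq_len(nBins)),
                 factor(neuronIdx, levels = seq_along(neurons)))
    counts <- matrix(as.integer(tab), nrow = nBins)
  }

  if (is.null(clusterLabel)) {
    if (!is.null(network)) {
      lab <- rep(NA_integer_, nNeurons(network))
      if (length(network@clusterLabel))
        lab[seq_along(network@clusterLabel)] <- network@clusterLabel
      clusterLabel <- lab[neurons]
    } else clusterLabel <- rep(NA_integer_, length(neurons))
  }
  new("CountMatrix", counts = counts, binWidth = binWidth, burnIn = burnIn,
      neuronIds = neurons, clusterLabel = as.integer(clusterLabel),
      meanRate = colSums(counts) / (nBins * binWidth),
      trialStart = burnIn + (seq_len(nBins) - 1) * binWidth)
}

#' Construct a count matrix directly
#'
#' Wraps a plain trials x neurons matrix in a [CountMatrix-class], filling
#' in default metadata.
#'
#' @param counts non-negative integer matrix, trials x neurons.
#' @param binWidth bin width in seconds.
#' @param neuronIds,clusterLabel optional per-neuron metadata.
#' @param burnIn discarded interval (s), bookkeeping only.
#' @return a [CountMatrix-class].
#' @export
countMatrix <- function(counts, binWidth = 1, neuronIds = NULL,
                        clusterLabel = NULL, burnIn = 0) {
  counts <- as.matrix(counts)
  if (is.null(neuronIds)) neuronIds <- seq_len(ncol(counts))
  if (is.null(clusterLabel)) clusterLabel <- rep(NA_integer_, ncol(counts))
  new("CountMatrix", counts = counts, binWidth = binWidth, burnIn = burnIn,
      neuronIds = as.integer(neuronIds), clusterLabel = as.integer(clusterLabel),
      meanRate = colMeans(counts) / binWidth,
      trialStart = burnIn + (seq_len(nrow(counts)) - 1) * binWidth)
}

#' @rdname spikeCounts
#' @export
setMethod("spikeCounts", "CountMatrix", function(x) {
  m <- x@counts
  storage.mode(m) <- "double"
  colnames(m) <- x@neuronIds
  m
})

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "CountMatrix", function(x) ncol(x@counts))

#' @rdname nTrials
#' @export
setMethod("nTrials", "CountMatrix", function(x) nrow(x@counts))

#' @rdname binWidth
#' @export
setMethod("binWidth", "CountMatrix", function(x) x@binWidth)

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "CountMatrix", function(x) x@clusterLabel)

#' Subset a count matrix
#'
#' \code{x[trials, neurons]} keeps the selected trials and neurons with
#' their metadata.
#'
#' @param x a [CountMatrix-class].
#' @param i trial indices.
#' @param j neuron (column) indices.
#' @param ... ignored.
#' @param drop ignored; the result is always a [CountMatrix-class].
#' @export
setMethod("[", "CountMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  new("CountMatrix", counts = x@counts[i, j, drop = FALSE],
      binWidth = x@binWidth, burnIn = x@burnIn,
      neuronIds = x@neuronIds[j], clusterLabel = x@clusterLabel[j],
      meanRate = x@meanRate[j], trialStart = x@trialStart[i])
})

setMethod("show", "SpikeRecord", function(object) {
  cat(sprintf("SpikeRecord: %d events from %d neurons over %g s\n",
              nrow(object@events), length(unique(object@events$neuron)),
              object@duration))
})

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix: %d trials x %d neurons (bin %g s)\n",
              nrow(object@counts), ncol(object@counts), object@binWidth))
})
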