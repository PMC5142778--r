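#' @import methods
#' @importFrom Matrix sparseMatrix
NULL

POPULATIONS <- c("E", "I")

#' Network configuration
#'
#' Holds every parameter of the balanced excitatory/inhibitory
#' leaky-integrate-and-fire network: population sizes, membrane time
#' constants, bias ranges, threshold/reset voltages, refractory period,
#' synaptic filter time constants, the 2x2 synaptic-weight and
#' connection-probability matrices (post x pre), the cluster geometry for
#' the clustered variant, and the integration step and burn-in.
#'
#' Voltages are normalized so that 0 corresponds to rest (about -65 mV) and
#' 1 to threshold (about -50 mV). All times are milliseconds except
#' \code{burnIn}, which is seconds (the unit used at all binning interfaces).
#'
#' @slot nExcitatory,nInhibitory population sizes.
#' @slot tauM membrane time constants (ms), named \code{c(E=, I=)}.
#' @slot biasRange 2x2 matrix of uniform bias bounds, rows \code{E}/\code{I},
#'   columns \code{min}/\code{max} (normalized voltage).
#' @slot vThreshold,vReset spike threshold and reset (normalized voltage).
#' @slot refractory absolute refractory period (ms).
#' @slot tauRise synaptic rise time constant (ms), shared by all synapses.
#' @slot tauDecay synaptic decay time constants (ms) per presynaptic
#'   population, named \code{c(E=, I=)}.
#' @slot J synaptic weights, 2x2 post x pre matrix.
#' @slot p connection probabilities, 2x2 post x pre matrix.
#' @slot nClusters number of excitatory clusters (0 = non-clustered).
#' @slot clusterSize neurons per cluster.
#' @slot pInEE,pOutEE within/between-cluster E-to-E connection probabilities.
#' @slot jInEE,jOutEE within/between-cluster E-to-E synaptic weights.
#' @slot dt integration step (ms).
#' @slot burnIn initial simulated interval discarded before binning (s).
#'
#' @seealso [clusteredNetworkConfig()], [nonclusteredNetworkConfig()],
#'   [toyNetworkConfig()], [buildNetwork()]
#' @export
setClass("NetworkConfig", slots = c(
  nExcitatory = "integer",
  nInhibitory = "integer",
  tauM = "numeric",
  biasRange = "matrix",
  vThreshold = "numeric",
  vReset = "numeric",
  refractory = "numeric",
  tauRise = "numeric",
  tauDecay = "numeric",
  J = "matrix",
  p = "matrix",
  nClusters = "integer",
  clusterSize = "integer",
  pInEE = "numeric",
  pOutEE = "numeric",
  jInEE = "numeric",
  jOutEE = "numeric",
  dt = "numeric",
  burnIn = "numeric"
))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  probs <- c(object@p, object@pInEE, object@pOutEE)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all connection probabilities must lie in [0, 1]")
  if (object@vReset >= object@vThreshold)
    msg <- c(msg, "vReset must be below vThreshold")
  if (any(object@tauRise >= object@tauDecay))
    msg <- c(msg, "tauRise must be below tauDecay for every synapse class")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (!identical(sort(names(object@tauM)), c("E", "I")))
    msg <- c(msg, "tauM must be named c(E=, I=)")
  if (object@nClusters > 0L) {
    if (object@nClusters * object@clusterSize != object@nExcitatory)
      msg <- c(msg, "nClusters * clusterSize must equal nExcitatory")
    # the pair-count-weighted mean of within/between probabilities must
    # recover the homogeneous E->E probability (what the clustering preserves)
    nE <- object@nExcitatory
    cs <- object@clusterSize
    wIn <- (cs - 1) / (nE - 1)
    pBar <- wIn * object@pInEE + (1 - wIn) * object@pOutEE
    if (abs(pBar - object@p["E", "E"]) > 5e-4)
      msg <- c(msg, sprintf(
        "pair-weighted mean of pInEE/pOutEE (%.5f) does not match p_EE (%.4f)",
        pBar, object@p["E", "E"]))
  }
  if (length(msg)) msg else TRUE
})

#' Instantiated network
#'
#' One realized connectivity draw from a [NetworkConfig-class]: the signed
#' sparse weight matrix over all ordered (postsynaptic, presynaptic) neuron
#' pairs, per-neuron population labels, cluster labels for excitatory
#' neurons, and the RNG seed used for the draw. Excitatory weights are
#' positive, inhibitory weights negative, and the diagonal is zero (no
#' self-connections).
#'
#' @slot weights sparse \code{dgCMatrix}, rows postsynaptic, columns
#'   presynaptic.
#' @slot populationLabel factor with levels \code{E}, \code{I}, one per neuron.
#' @slot clusterLabel integer cluster index per excitatory neuron
#'   (length 0 for non-clustered configs).
#' @slot seed connectivity seed.
#' @slot config the generating [NetworkConfig-class].
#' @export
setClass("Network", slots = c(
  weights = "Matrix",
  populationLabel = "factor",
  clusterLabel = "integer",
  seed = "integer",
  config = "NetworkConfig"
))

setValidity("Network", function(object) {
  msg <- character()
  n <- nrow(object@weights)
  if (ncol(object@weights) != n) msg <- c(msg, "weight matrix must be square")
  if (length(object@populationLabel) != n)
    msg <- c(msg, "populationLabel length must match the number of neurons")
  if (any(Matrix::diag(object@weights) != 0))
    msg <- c(msg, "self-connections are not allowed (diagonal must be zero)")
  if (length(msg)) msg else TRUE
})

#' Spike event record
#'
#' Time-sorted spike events from one simulation run: a two-column
#' data frame (\code{neuron}, 1-based index; \code{time}, seconds) plus the
#' simulated duration and the generating configuration. Consecutive spikes
#' of the same neuron are separated by at least the refractory period.
#'
#' @slot events data.frame with integer \code{neuron} and numeric
#'   \code{time} (s), sorted by time.
#' @slot duration simulated duration (s).
#' @slot config the [NetworkConfig-class] used, or \code{NULL}.
#' @export
setClass("SpikeRecord", slots = c(
  events = "data.frame",
  duration = "numeric",
  config = "ANY"
))

setValidity("SpikeRecord", function(object) {
  msg <- character()
  ev <- object@events
  if (!all(c("neuron", "time") %in% names(ev)))
    msg <- c(msg, "events must have columns 'neuron' and 'time'")
  else {
    if (is.unsorted(ev$time)) msg <- c(msg, "events must be time-sorted")
    if (nrow(ev) && (min(ev$time) < 0 || max(ev$time) >= object@duration))
      msg <- c(msg, "all spike times must lie in [0, duration)")
  }
  if (length(msg)) msg else TRUE
})

#' Trials x neurons spike-count matrix
#'
#' Spike counts in consecutive half-open time bins (rows = trials,
#' columns = neurons) together with the bin width, the burn-in that was
#' discarded, per-neuron metadata (cluster label, mean firing rate) and the
#' bin start times. One trial is one bin of spontaneous activity, treated
#' as an exchangeable observation by the factor-analysis stage.
#'
#' Binned spike data is integral and non-negative by construction (and file
#' parsing enforces this); synthetic Gaussian "counts" from the generative
#' sampler may be continuous.
#'
#' @slot counts numeric matrix, trials x neurons.
#' @slot binWidth bin width (s).
#' @slot burnIn discarded initial interval (s).
#' @slot neuronIds integer neuron indices (1-based) for the columns.
#' @slot clusterLabel integer cluster label per neuron (NA if none).
#' @slot meanRate mean firing rate per neuron (spikes/s).
#' @slot trialStart bin start time per trial (s).
#' @export
setClass("CountMatrix", slots = c(
  counts = "matrix",
  binWidth = "numeric",
  burnIn = "numeric",
  neuronIds = "integer",
  clusterLabel = "integer",
  meanRate = "numeric",
  trialStart = "numeric"
))

setValidity("CountMatrix", function(object) {
  msg <- character()
  x <- object@counts
  if (any(!is.finite(x)))
    msg <- c(msg, "counts must be finite")
  if (length(object@neuronIds) != ncol(x))
    msg <- c(msg, "neuronIds length must match the number of columns")
  if (length(object@clusterLabel) != ncol(x))
    msg <- c(msg, "clusterLabel length must match the number of columns")
  if (length(object@trialStart) != nrow(x))
    msg <- c(msg, "trialStart length must match the number of rows")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Fitted factor-analysis model
#'
#' Parameters of the Gaussian latent-factor model
#' \eqn{x \sim N(\mu, LL^T + \Psi)} fitted to a spike-count matrix:
#' per-neuron means \eqn{\mu}, the neurons x m loading matrix \eqn{L},
#' the diagonal independent variances \eqn{\Psi}, the latent dimensionality
#' \eqn{m}, and fit metadata. \eqn{LL^T} is the shared covariance; its
#' eigenstructure yields every downstream metric.
#'
#' @slot mu per-neuron mean spike count.
#' @slot L loading matrix (neurons x m; zero columns when m = 0).
#' @slot Psi per-neuron independent variance (diagonal of \eqn{\Psi}).
#' @slot m latent dimensionality.
#' @slot neuronIds neuron indices the model was fitted to.
#' @slot nObs number of trials used.
#' @slot logLik final training log-likelihood (nats, summed over trials).
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot iterations EM iterations run.
#' @slot converged whether the relative tolerance was reached.
#' @export
setClass("FAModel", slots = c(
  mu = "numeric",
  L = "matrix",
  Psi = "numeric",
  m = "integer",
  neuronIds = "integer",
  nObs = "integer",
  logLik = "numeric",
  logLikTrace = "numeric",
  iterations = "integer",
  converged = "logical"
))

setValidity("FAModel", function(object) {
  msg <- character()
  p <- length(object@mu)
  if (nrow(object@L) != p) msg <- c(msg, "L must have one row per neuron")
  if (ncol(object@L) != object@m) msg <- c(msg, "ncol(L) must equal m")
  if (length(object@Psi) != p) msg <- c(msg, "Psi must have one entry per neuron")
  if (any(object@Psi <= 0)) msg <- c(msg, "Psi entries must be strictly positive")
  if (object@m > max(p - 1L, 0L)) msg <- c(msg, "m must be at most neurons - 1")
  if (length(msg)) msg else TRUE
})

#' Eigenstructure of the shared covariance
#'
#' Eigenvalues (descending, non-negative) and orthonormal eigenvectors
#' ("modes") of the shared covariance \eqn{LL^T} of a fitted
#' [FAModel-class]. Each mode is a pattern of coordinated activity across
#' neurons; dominant modes carry the largest eigenvalues. Eigenvector signs
#' follow the convention that the largest-magnitude entry is positive.
#'
#' @slot values eigenvalues of \eqn{LL^T}, descending.
#' @slot vectors neurons x m matrix of unit-norm eigenvectors.
#' @slot neuronIds neuron indices of the rows.
#' @export
setClass("SharedSpectrum", slots = c(
  values = "numeric",
  vectors = "matrix",
  neuronIds = "integer"
))

setValidity("SharedSpectrum", function(object) {
  msg <- character()
  if (length(object@values) != ncol(object@vectors))
    msg <- c(msg, "one eigenvalue per eigenvector required")
  if (any(object@values < -1e-10)) msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(object@values))) msg <- c(msg, "eigenvalues must be descending")
  if (length(msg)) msg else TRUE
})

#' Mode basis restricted to a common neuron set
#'
#' Orthonormal basis for the span of the top-k modes of a model's shared
#' covariance after restriction to a common set of neurons (the rows of
#' \eqn{L} for those neurons). Used to compare mode subspaces estimated
#' from different neuron counts via principal angles.
#'
#' @slot neuronIds the common (ambient) neuron set, in a fixed order.
#' @slot basis matrix, common neurons x k, orthonormal columns.
#' @slot eigenvalues eigenvalues of the restricted shared covariance for the
#'   retained modes.
#' @slot sourceSize neuron count of the source model.
#' @export
setClass("ModeBasis", slots = c(
  neuronIds = "integer",
  basis = "matrix",
  eigenvalues = "numeric",
  sourceSize = "integer"
))

setValidity("ModeBasis", function(object) {
  msg <- character()
  if (nrow(object@basis) != length(object@neuronIds))
    msg <- c(msg, "basis must have one row per common neuron")
  if (ncol(object@basis) > nrow(object@basis))
    msg <- c(msg, "cannot have more modes than ambient dimensions")
  if (ncol(object@basis) > 0L) {
    g <- crossprod(object@basis)
    if (max(abs(g - diag(ncol(object@basis)))) > 1e-8)
      msg <- c(msg, "basis columns must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' Generative factor-analysis specification
#'
#' Ground-truth parameters used to sample synthetic spike-count matrices by
#' inverting the factor-analysis model: latents \eqn{z \sim N(0, I_m)},
#' observations \eqn{x = \mu + Lz + \epsilon}, \eqn{\epsilon \sim N(0, \Psi)}.
#' With \code{poissonize = TRUE} the Gaussian draw is used as a rate and
#' replaced by a Poisson count (rate truncated at zero), a coarse emulation
#' of spiking discreteness.
#'
#' @slot mu per-neuron mean counts per trial.
#' @slot L loading matrix (neurons x m_true).
#' @slot Psi per-neuron independent variances.
#' @slot poissonize logical; Poissonize the Gaussian draws.
#' @export
setClass("GenerativeFASpec", slots = c(
  mu = "numeric",
  L = "matrix",
  Psi = "numeric",
  poissonize = "logical"
))

setValidity("GenerativeFASpec", function(object) {
  msg <- character()
  p <- length(object@mu)
  if (nrow(object@L) != p) msg <- c(msg, "L must have one row per neuron")
  if (length(object@Psi) != p) msg <- c(msg, "Psi must have one entry per neuron")
  if (any(object@Psi <= 0))
    msg <- c(msg, "implied covariance must be positive definite (Psi > 0)")
  if (length(msg)) msg else TRUE
})
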