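#' Number of neurons represented by an object
#' @param x a popdim object.
#' @return integer neuron count.
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' Number of trials in a count matrix
#' @param x a [CountMatrix-class].
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Spike counts as a plain trials x neurons matrix
#' @param x a [CountMatrix-class].
#' @return numeric matrix, trials in rows, neurons in columns.
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' Cluster labels of the neurons in an object
#' @param x a [Network-class] or [CountMatrix-class].
#' @return integer vector (NA where no cluster applies).
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Bin width of a count matrix
#' @param x a [CountMatrix-class].
#' @return bin width in seconds.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Loading matrix of a fitted factor-analysis model
#' @param x an [FAModel-class].
#' @return neurons x m matrix L.
#' @export
setGeneric("loadingMatrix", function(x) standardGeneric("loadingMatrix"))

#' Independent (diagonal) variances of a factor-analysis model
#' @param x an [FAModel-class].
#' @return per-neuron variance vector (diagonal of Psi).
#' @export
setGeneric("independentVariances", function(x) standardGeneric("independentVariances"))

#' Latent dimensionality m of a factor-analysis model
#' @param x an [FAModel-class].
#' @return integer m.
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' Shared covariance LL^T implied by a model
#' @param x an [FAModel-class] or [GenerativeFASpec-class].
#' @return neurons x neurons matrix LL^T.
#' @export
setGeneric("sharedCovariance", function(x) standardGeneric("sharedCovariance"))

#' Eigenstructure of the shared covariance
#'
#' Eigendecomposes \eqn{LL^T} into eigenvalues (descending) and orthonormal
#' modes. Computed from the singular value decomposition of L, so the
#' number of returned modes equals m.
#'
#' @param x an [FAModel-class] or [GenerativeFASpec-class].
#' @return a [SharedSpectrum-class].
#' @export
setGeneric("sharedSpectrum", function(x) standardGeneric("sharedSpectrum"))

#' Shared dimensionality (d_shared)
#'
#' The number of leading eigenmodes of the shared covariance \eqn{LL^T}
#' needed to capture a fraction \code{threshold} (default 95%) of its
#' trace. Returns 0 for a model with no shared component (m = 0).
#'
#' @param x an [FAModel-class], [SharedSpectrum-class] or a numeric vector of
#'   eigenvalues.
#' @param threshold fraction of shared variance to capture (default 0.95).
#' @return integer d_shared.
#' @export
setGeneric("sharedDimensionality", function(x, threshold = 0.95)
  standardGeneric("sharedDimensionality"))

#' Percent shared variance per neuron
#'
#' For neuron k, the percentage of its spike-count variance assigned to the
#' shared component: \eqn{100 \, L_k L_k^T / (L_k L_k^T + \Psi_k)}, where
#' \eqn{L_k} is the k-th row of the loading matrix. The population value is
#' the unweighted mean over neurons.
#'
#' @param x an [FAModel-class] or [GenerativeFASpec-class].
#' @return list with \code{perNeuron} (numeric vector, %) and
#'   \code{population} (scalar mean, %).
#' @export
setGeneric("percentSharedVariance", function(x) standardGeneric("percentSharedVariance"))

#' Percent of shared variance explained by each mode
#'
#' \eqn{100 \, \lambda_i / \sum_j \lambda_j} for each eigenvalue
#' \eqn{\lambda_i} of \eqn{LL^T}, in descending eigenvalue order. Does not
#' involve the independent variances.
#'
#' @param x a [SharedSpectrum-class], [FAModel-class] or numeric eigenvalues.
#' @return numeric vector summing to 100 (empty when m = 0).
#' @export
setGeneric("modeVarianceFractions", function(x) standardGeneric("modeVarianceFractions"))
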