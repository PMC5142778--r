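#' Construct a network configuration
#'
#' Low-level constructor for [NetworkConfig-class]; the defaults are the
#' canonical balanced-network parameters (4000 excitatory and 1000
#' inhibitory leaky-integrate-and-fire neurons, normalized voltages, fast
#' difference-of-exponentials synapses). Use
#' [clusteredNetworkConfig()] / [nonclusteredNetworkConfig()] for the two
#' canonical presets and [toyNetworkConfig()] for reduced desk-scale
#' variants.
#'
#' @param nExcitatory,nInhibitory population sizes.
#' @param tauM membrane time constants in ms, named \code{c(E=, I=)}.
#' @param biasRange 2x2 matrix of uniform bias bounds (rows E/I, cols min/max).
#' @param vThreshold,vReset threshold and reset voltages (normalized).
#' @param refractory absolute refractory period (ms).
#' @param tauRise synaptic rise time constant (ms).
#' @param tauDecay synaptic decay time constants (ms), named \code{c(E=, I=)}.
#' @param J 2x2 post x pre synaptic-weight matrix.
#' @param p 2x2 post x pre connection-probability matrix.
#' @param nClusters number of excitatory clusters (0 for non-clustered).
#' @param clusterSize neurons per cluster.
#' @param pInEE,pOutEE within/between-cluster E-to-E connection probabilities.
#' @param jInEE,jOutEE within/between-cluster E-to-E weights.
#' @param dt integration step (ms).
#' @param burnIn discarded initial interval (s).
#' @return a validated [NetworkConfig-class].
#' @export
networkConfig <- function(nExcitatory = 4000L, nInhibitory = 1000L,
                          tauM = c(E = 15, I = 10),
                          biasRange = rbind(E = c(1.1, 1.2), I = c(1.0, 1.05)),
                          vThreshold = 1, vReset = 0, refractory = 5,
                          tauRise = 1, tauDecay = c(E = 3, I = 2),
                          J = rbind(E = c(E = 0.024, I = -0.045),
                                    I = c(E = 0.014, I = -0.057)),
                          p = rbind(E = c(E = 0.2, I = 0.5),
                                    I = c(E = 0.5, I = 0.5)),
                          nClusters = 0L, clusterSize = 0L,
                          pInEE = 0.4854, pOutEE = 0.1942,
                          jInEE = 0.0456, jOutEE = 0.024,
                          dt = 0.05, burnIn = 2) {
  colnames(biasRange) <- c("min", "max")
  dimnames(J) <- dimnames(p) <- list(c("E", "I"), c("E", "I"))
  new("NetworkConfig",
      nExcitatory = as.integer(nExcitatory), nInhibitory = as.integer(nInhibitory),
      tauM = tauM, biasRange = biasRange,
      vThreshold = vThreshold, vReset = vReset, refractory = refractory,
      tauRise = tauRise, tauDecay = tauDecay, J = J, p = p,
      nClusters = as.integer(nClusters), clusterSize = as.integer(clusterSize),
      pInEE = pInEE, pOutEE = pOutEE, jInEE = jInEE, jOutEE = jOutEE,
      dt = dt, burnIn = burnIn)
}

#' Canonical clustered network preset
#'
#' The full-scale clustered configuration: 50 clusters of 80 excitatory
#' neurons with elevated within-cluster connection probability (0.4854 vs
#' 0.1942 between clusters; pair-weighted mean 0.2) and strengthened
#' within-cluster synapses (0.0456 vs 0.024).
#'
#' @param dt integration step (ms).
#' @param burnIn discarded initial interval (s).
#' @return a [NetworkConfig-class].
#' @export
clusteredNetworkConfig <- function(dt = 0.05, burnIn = 2) {
  networkConfig(nClusters = 50L, clusterSize = 80L, dt = dt, burnIn = burnIn)
}

#' Canonical non-clustered network preset
#'
#' Homogeneous E-to-E connectivity at probability 0.2 and weight 0.024;
#' otherwise identical to the clustered preset.
#'
#' @inheritParams clusteredNetworkConfig
#' @return a [NetworkConfig-class].
#' @export
nonclusteredNetworkConfig <- function(dt = 0.05, burnIn = 2) {
  networkConfig(nClusters = 0L, clusterSize = 0L, dt = dt, burnIn = burnIn)
}

#' Build a network realization
#'
#' Draws the connectivity: every ordered (postsynaptic, presynaptic) pair is
#' connected independently with the class-appropriate probability, and
#' connected pairs receive the class-appropriate weight. In clustered
#' configurations, E-to-E pairs within the same cluster use
#' \code{pInEE}/\code{jInEE} and pairs in different clusters
#' \code{pOutEE}/\code{jOutEE}; cluster labels are assigned contiguously
#' (neurons 1..clusterSize form cluster 1, and so on). Self-connections are
#' excluded.
#'
#' @param config a [NetworkConfig-class].
#' @param seed connectivity RNG seed.
#' @return a [Network-class].
#' @export
buildNetwork <- function(config, seed = 1L) {
  validObject(config)
  nE <- config@nExcitatory
  nI <- config@nInhibitory
  n <- nE + nI
  pop <- factor(rep(c("E", "I"), c(nE, nI)), levels = c("E", "I"))
  clustered <- config@nClusters > 0L
  clusterLabel <- if (clustered)
    rep(seq_len(config@nClusters), each = config@clusterSize) else integer(0)

  withSeed(seed, {
    triplets <- vector("list", 5L)
    blk <- 0L
    addBlock <- function(postIdx, preIdx, prob, weight) {
      # one Bernoulli draw per ordered pair in this (post, pre) block
      nPost <- length(postIdx); nPre <- length(preIdx)
      hit <- which(stats::runif(nPost * nPre) < prob)
      if (!length(hit)) return(NULL)
      list(i = postIdx[((hit - 1L) %% nPost) + 1L],
           j = preIdx[((hit - 1L) %/% nPost) + 1L],
           x = rep(weight, length(hit)))
    }
    eIdx <- seq_len(nE)
    iIdx <- nE + seq_len(nI)
    blocks <- list()
    if (clustered && nE > 0L) {
      # within-cluster blocks, then one between-cluster complement:
      # draw the full E->E block at pOutEE and redraw within-cluster pairs
      # would bias; instead draw per cluster pair-type explicitly
      for (c1 in seq_len(config@nClusters)) {
        members <- which(clusterLabel == c1)
        blocks[[length(blocks) + 1L]] <-
          addBlock(members, members, config@pInEE, config@jInEE)
      }
      # between-cluster pairs: draw all E->E then drop within-cluster hits
      hit <- which(stats::runif(nE * nE) < config@pOutEE)
      if (length(hit)) {
        i <- ((hit - 1L) %% nE) + 1L
        j <- ((hit - 1L) %/% nE) + 1L
        keep <- clusterLabel[i] != clusterLabel[j]
        blocks[[length(blocks) + 1L]] <-
          list(i = i[keep], j = j[keep], x = rep(config@jOutEE, sum(keep)))
      }
    } else if (nE > 0L) {
      blocks[[length(blocks) + 1L]] <-
        addBlock(eIdx, eIdx, config@p["E", "E"], config@J["E", "E"])
    }
    if (nI > 0L && nE > 0L) {
      blocks[[length(blocks) + 1L]] <-
        addBlock(eIdx, iIdx, config@p["E", "I"], config@J["E", "I"])
      blocks[[length(blocks) + 1L]] <-
        addBlock(iIdx, eIdx, config@p["I", "E"], config@J["I", "E"])
    }
    if (nI > 0L)
      blocks[[length(blocks) + 1L]] <-
        addBlock(iIdx, iIdx, config@p["I", "I"], config@J["I", "I"])

    blocks <- Filter(Negate(is.null), blocks)
    i <- unlist(lapply(blocks, `[[`, "i"), use.names = FALSE)
    j <- unlist(lapply(blocks, `[[`, "j"), use.names = FALSE)
    x <- unlist(lapply(blocks, `[[`, "x"), use.names = FALSE)
    if (is.null(i)) { i <- integer(0); j <- integer(0); x <- numeric(0) }
    keep <- i != j
    w <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                              dims = c(n, n))
    new("Network", weights = w, populationLabel = pop,
        clusterLabel = clusterLabel, seed = as.integer(seed), config = config)
  })
}

#' @describeIn buildNetwork number of neurons in the network.
#' @param x a [Network-class].
#' @export
setMethod("nNeurons", "Network", function(x) nrow(x@weights))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "Network", function(x) x@clusterLabel)

setMethod("show", "NetworkConfig", function(object) {
  kind <- if (object@nClusters > 0L)
    sprintf("clustered (%d clusters of %d)", object@nClusters, object@clusterSize)
  else "non-clustered"
  cat(sprintf("NetworkConfig: %d E + %d I neurons, %s\n",
              object@nExcitatory, object@nInhibitory, kind))
  cat(sprintf("  dt = %g ms, burn-in = %g s, refractory = %g ms\n",
              object@dt, object@burnIn, object@refractory))
})

setMethod("show", "Network", function(object) {
  cat(sprintf("Network: %d neurons, %d synapses (seed %d)\n",
              nNeurons(object), length(object@weights@x), object@seed))
})
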