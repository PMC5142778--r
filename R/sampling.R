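# Subsampling protocols and scaling curves: how shared dimensionality and
# percent shared variance change with the number of neurons, trials, or
# clusters represented in the sample.

#' Nested neuron subsets of increasing size
#'
#' Draws a chain of subsets where each larger set augments the previous one
#' with additional neurons chosen uniformly without replacement, so every
#' smaller sample is contained in every larger one.
#'
#' @param pool integer vector of candidate neuron indices.
#' @param sizes strictly increasing subset sizes (max <= pool size).
#' @param seed RNG seed.
#' @return list of integer index vectors, one per size; each extends the
#'   previous (the first \code{sizes[i]} elements are set i).
#' @export
nestedNeuronSubsets <- function(pool, sizes, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (max(sizes) > length(pool)) stop("largest size exceeds the pool")
  withSeed(seed, {
    chain <- samplePool(pool, max(sizes))
    lapply(sizes, function(s) chain[seq_len(s)])
  })
}

#' Disjoint random neuron sets
#'
#' Draws \code{nSets} pairwise-disjoint subsets of equal size, uniformly
#' without replacement.
#'
#' @param pool integer vector of candidate indices.
#' @param nSets number of sets (default 5).
#' @param size elements per set.
#' @param seed RNG seed.
#' @return list of integer index vectors.
#' @export
disjointSets <- function(pool, nSets = 5L, size, seed = 1L) {
  nSets <- as.integer(nSets)
  size <- as.integer(size)
  if (nSets * size > length(pool))
    stop("pool too small for ", nSets, " disjoint sets of ", size)
  withSeed(seed, {
    drawn <- samplePool(pool, nSets * size)
    split(drawn, rep(seq_len(nSets), each = size))
  })
}

#' Sample neurons with controlled cluster representation
#'
#' Chooses \code{nClustersRepresented} clusters uniformly at random and
#' then \code{total / nClustersRepresented} neurons uniformly within each,
#' yielding exactly \code{total} neurons whose cluster diversity is
#' controlled. \code{nClustersRepresented} must divide \code{total}.
#'
#' @param clusterLabels integer cluster label per neuron in the pool.
#' @param nClustersRepresented number of distinct clusters to represent.
#' @param total total neurons to sample (default 50).
#' @param seed RNG seed.
#' @return integer vector of neuron indices (positions in
#'   \code{clusterLabels}).
#' @export
clusterBalancedSample <- function(clusterLabels, nClustersRepresented,
                                  total = 50L, seed = 1L) {
  N <- as.integer(nClustersRepresented)
  total <- as.integer(total)
  if (total %% N != 0L)
    stop("nClustersRepresented must divide the total sample size")
  perCluster <- total %/% N
  clusters <- sort(unique(clusterLabels[!is.na(clusterLabels)]))
  if (N > length(clusters)) stop("not enough clusters in the pool")
  withSeed(seed, {
    chosen <- samplePool(clusters, N)
    sizesOk <- vapply(chosen, function(cl)
      sum(clusterLabels == cl, na.rm = TRUE) >= perCluster, logical(1))
    if (!all(sizesOk)) stop("a chosen cluster has fewer members than needed")
    unlist(lapply(chosen, function(cl)
      samplePool(which(clusterLabels == cl), perCluster)), use.names = FALSE)
  })
}

#' Neurons eligible for analysis
#'
#' Indices of neurons with non-degenerate activity: mean rate at least
#' \code{minRate} spikes/s and non-zero count variance. Mirrors the usual
#' screening of recorded units before population analysis; silent or
#' constant neurons carry no covariance information and break model
#' fitting.
#'
#' @param counts a [CountMatrix-class].
#' @param minRate minimum mean firing rate (spikes/s, default 1).
#' @return integer column indices.
#' @export
activeNeurons <- function(counts, minRate = 1) {
  X <- spikeCounts(counts)
  which(counts@meanRate >= minRate & apply(X, 2, stats::var) > 0)
}

# fit FA (with or without CV selection) and return the two headline
# metrics; zero-variance neurons in the subsample are dropped (they carry
# no covariance information)
.faMetricsOnce <- function(X, faOpts, seed) {
  keep <- apply(X, 2, stats::var) > 0
  if (!all(keep)) X <- X[, keep, drop = FALSE]
  m <- faOpts[["m"]]
  if (is.null(m)) {
    sel <- selectDimensionality(X, mMax = faOpts[["mMax"]] %||% 10L,
                                folds = faOpts[["folds"]] %||% 4L, seed = seed,
                                tol = faOpts[["tol"]] %||% 1e-6,
                                maxIter = faOpts[["maxIter"]] %||% 500L)
    m <- sel$mStar
  }
  fit <- suppressWarnings(fitFA(X, m, tol = faOpts[["tol"]] %||% 1e-6,
                                maxIter = faOpts[["maxIter"]] %||% 500L))
  c(mStar = m, dShared = sharedDimensionality(fit),
    psv = percentSharedVariance(fit)$population)
}

#' Scaling of shared-variability metrics with neuron or trial count
#'
#' For each grid value, subsamples the count matrix, selects the
#' factor-analysis dimensionality by cross-validated likelihood, and
#' records shared dimensionality and percent shared variance, repeated over
#' a crossing of disjoint neuron sets and disjoint contiguous trial blocks
#' (the model-network protocol; set \code{nNeuronSets = nTrialSets = 1} for
#' single-sample, array-style runs).
#'
#' Neuron sweeps use nested subsets within each neuron set (each count
#' augments the previous sample) at a fixed trial count; trial sweeps use
#' a fixed neuron count with nested trial ranges within each block.
#'
#' @param counts a [CountMatrix-class].
#' @param axis \code{"neurons"} or \code{"trials"}.
#' @param grid increasing neuron or trial counts.
#' @param fixed the fixed complementary dimension (trials for a neuron
#'   sweep, neurons for a trial sweep).
#' @param nNeuronSets,nTrialSets number of disjoint neuron sets and trial
#'   blocks (default 5 x 5).
#' @param neuronPool optional indices restricting which neurons may be
#'   sampled (e.g. excitatory only); default all.
#' @param faOpts fitting options as in [modeStabilityExperiment()].
#' @param seed RNG seed.
#' @return data.frame with one row per (grid value, neuron set, trial
#'   block): \code{axis}, \code{value}, \code{neuronSet}, \code{trialSet},
#'   \code{mStar}, \code{dShared}, \code{psv}.
#' @seealso [aggregateScaling()]
#' @export
scalingExperiment <- function(counts, axis = c("neurons", "trials"), grid,
                              fixed, nNeuronSets = 5L, nTrialSets = 5L,
                              neuronPool = NULL, faOpts = list(), seed = 1L) {
  axis <- match.arg(axis)
  grid <- sort(as.integer(grid))
  X <- spikeCounts(counts)
  if (is.null(neuronPool)) neuronPool <- seq_len(ncol(X))
  nT <- nrow(X)

  maxNeurons <- if (axis == "neurons") max(grid) else as.integer(fixed)
  trialNeed <- if (axis == "trials") max(grid) else as.integer(fixed)
  if (nTrialSets * trialNeed > nT)
    stop("not enough trials for ", nTrialSets, " blocks of ", trialNeed)

  neuronSets <- disjointSets(neuronPool, nNeuronSets, maxNeurons, seed = seed)
  # contiguous non-overlapping trial blocks from one continuous run
  blockStarts <- floor(seq(0, nT - trialNeed, length.out = max(nTrialSets, 1)))
  if (nTrialSets > 1 && any(diff(blockStarts) < trialNeed))
    blockStarts <- (seq_len(nTrialSets) - 1L) * trialNeed
  trialSets <- lapply(blockStarts[seq_len(nTrialSets)],
                      function(s) s + seq_len(trialNeed))

  rows <- list()
  for (ns in seq_len(nNeuronSets)) {
    # nested chain within this neuron set so larger samples augment smaller
    chain <- if (axis == "neurons")
      nestedNeuronSubsets(neuronSets[[ns]], grid, seed = seed + ns)
    else list(neuronSets[[ns]])
    for (ts in seq_len(nTrialSets)) {
      for (gi in seq_along(grid)) {
        neuronIdx <- if (axis == "neurons") chain[[gi]] else chain[[1]]
        trialIdx <- if (axis == "trials") trialSets[[ts]][seq_len(grid[gi])]
          else trialSets[[ts]]
        met <- .faMetricsOnce(X[trialIdx, neuronIdx, drop = FALSE], faOpts,
                              seed = seed + 1000L * ns + ts)
        rows[[length(rows) + 1L]] <- data.frame(
          axis = axis, value = grid[gi], neuronSet = ns, trialSet = ts,
          mStar = met[["mStar"]], dShared = met[["dShared"]],
          psv = met[["psv"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "faOpts") <- faOpts
  out
}

#' Aggregate a scaling table into mean and standard error per grid value
#'
#' @param table output of [scalingExperiment()] (or any data.frame with
#'   \code{value}, \code{dShared}, \code{psv}).
#' @return data.frame with per-value repeat count, mean and standard error
#'   (sd / sqrt(repeats)) of \code{dShared} and \code{psv}.
#' @export
aggregateScaling <- function(table) {
  out <- do.call(rbind, lapply(split(table, table$value), function(d) {
    data.frame(value = d$value[1], reps = nrow(d),
               dShared = mean(d$dShared), dSharedSE = standardError(d$dShared),
               psv = mean(d$psv), psvSE = standardError(d$psv))
  }))
  rownames(out) <- NULL
  out[order(out$value), , drop = FALSE]
}

#' Per-neuron spike-count autocorrelation across trials
#'
#' Standard biased autocorrelation of each neuron's trial-ordered count
#' sequence (lag 0 equals 1), with the population mean and standard error
#' across neurons per lag. Validates the exchangeable-trials assumption of
#' the factor-analysis stage: for sufficiently wide bins the
#' autocorrelation is near zero at all non-zero lags.
#'
#' @param counts a [CountMatrix-class] (trials ordered by start time).
#' @param maxLag largest lag (in trials) to evaluate.
#' @return list with \code{perNeuron} (neurons x (maxLag+1) matrix),
#'   \code{mean}, \code{se} (per lag, across included neurons) and
#'   \code{excluded} (indices of constant-count neurons).
#' @export
countAutocorrelation <- function(counts, maxLag = 10L) {
  X <- spikeCounts(counts)
  maxLag <- as.integer(maxLag)
  if (maxLag >= nrow(X)) stop("maxLag must be smaller than the trial count")
  vars <- unname(apply(X, 2, stats::var))
  excluded <- which(vars == 0)
  ac <- matrix(NA_real_, ncol(X), maxLag + 1L)
  for (j in seq_len(ncol(X))) {
    if (vars[j] == 0) next
    ac[j, ] <- stats::acf(X[, j], lag.max = maxLag, plot = FALSE,
                          demean = TRUE)$acf[, 1, 1]
  }
  inc <- ac[setdiff(seq_len(ncol(X)), excluded), , drop = FALSE]
  list(perNeuron = ac,
       mean = colMeans(inc),
       se = apply(inc, 2, standardError),
       excluded = excluded)
}

#' Factor-analysis metrics under different trial spacings
#'
#' Repeats the shared-variance metrics on equal-sized trial samples drawn
#' four ways: adjacent trials (skip 0), every other trial (skip 1), every
#' third trial (skip 2), and uniformly at random. If trials are
#' exchangeable, the four samplings agree statistically.
#'
#' @param counts a [CountMatrix-class].
#' @param nTrialsUsed trials per sampling (default 400).
#' @param spacings skipped trials between samples (default 0, 1, 2).
#' @param faOpts fitting options as in [scalingExperiment()].
#' @param seed RNG seed (random sampling and CV folds).
#' @return data.frame with \code{sampling}, \code{mStar}, \code{dShared},
#'   \code{psv}.
#' @export
trialSpacingCheck <- function(counts, nTrialsUsed = 400L, spacings = c(0L, 1L, 2L),
                              faOpts = list(), seed = 1L) {
  X <- spikeCounts(counts)
  nT <- nrow(X)
  nTrialsUsed <- as.integer(nTrialsUsed)
  need <- nTrialsUsed * (max(spacings) + 1L)
  if (need > nT) stop("not enough trials for the largest spacing")
  samplings <- c(stats::setNames(
    lapply(spacings, function(s) seq(1L, by = s + 1L, length.out = nTrialsUsed)),
    paste0("skip", spacings)),
    list(random = withSeed(seed, sort(samplePool(seq_len(nT), nTrialsUsed)))))
  rows <- lapply(names(samplings), function(nm) {
    met <- .faMetricsOnce(X[samplings[[nm]], , drop = FALSE], faOpts, seed = seed)
    data.frame(sampling = nm, mStar = met[["mStar"]],
               dShared = met[["dShared"]], psv = met[["psv"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
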