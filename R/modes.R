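# Comparison of shared-variability modes across neuron counts. Modes
# estimated from different neuron counts live in different spaces; they are
# compared by restricting every loading matrix to a common neuron set,
# eigendecomposing the restricted shared covariance, and measuring
# principal angles between the spans of the top-k modes.

#' Top modes of the shared covariance restricted to common neurons
#'
#' Takes the rows of L for the common neurons, forms
#' \eqn{L_{sub} L_{sub}^T}, and returns the top-k eigenvectors as an
#' orthonormal [ModeBasis-class] over those neurons. If the restricted
#' covariance has rank below k, the available modes are returned with a
#' warning.
#'
#' @param model an [FAModel-class].
#' @param commonNeurons indices into the model's neurons (positions in the
#'   model's neuron order) defining the common set.
#' @param k number of dominant modes to keep (default 5).
#' @return a [ModeBasis-class].
#' @export
restrictedModes <- function(model, commonNeurons, k = 5L) {
  commonNeurons <- as.integer(commonNeurons)
  p <- length(model@mu)
  if (any(commonNeurons < 1L | commonNeurons > p))
    stop("commonNeurons must index the model's neurons")
  if (k > length(commonNeurons))
    stop("k cannot exceed the size of the common neuron set")
  Lsub <- model@L[commonNeurons, , drop = FALSE]
  if (ncol(Lsub) == 0L) {
    warning("model has no shared component (m = 0); returning an empty basis")
    return(new("ModeBasis", neuronIds = model@neuronIds[commonNeurons],
               basis = matrix(0, length(commonNeurons), 0),
               eigenvalues = numeric(0), sourceSize = as.integer(p)))
  }
  sv <- svd(Lsub)
  tolRank <- max(dim(Lsub)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > max(tolRank, 1e-12))
  if (r < k) {
    warning(sprintf("restricted shared covariance has rank %d < k = %d; %s",
                    r, k, "returning the available modes"))
    k <- r
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  new("ModeBasis", neuronIds = model@neuronIds[commonNeurons], basis = U,
      eigenvalues = sv$d[seq_len(k)]^2, sourceSize = as.integer(p))
}

#' Principal angles between two mode subspaces
#'
#' Orthonormalizes both bases (QR) and returns
#' \eqn{\theta_i = \arccos \sigma_i} for the singular values
#' \eqn{\sigma_i} of \eqn{Q_A^T Q_B}, clipped to [0, 1], in ascending
#' order (degrees). Angles are invariant to column order, sign, and any
#' rotation within either span.
#'
#' @param A,B [ModeBasis-class] objects over the same ambient neuron set
#'   (same ids, same order), or plain matrices with matching row count.
#' @return data.frame with \code{index} and \code{angle} (degrees,
#'   non-decreasing, within [0, 90]).
#' @export
principalAngles <- function(A, B) {
  matA <- if (is(A, "ModeBasis")) A@basis else as.matrix(A)
  matB <- if (is(B, "ModeBasis")) B@basis else as.matrix(B)
  if (is(A, "ModeBasis") && is(B, "ModeBasis") &&
      !identical(A@neuronIds, B@neuronIds))
    stop("mode bases are defined over different ambient neuron sets")
  if (nrow(matA) != nrow(matB))
    stop("bases must share the ambient dimension")
  qa <- qr.Q(qr(matA))[, seq_len(qr(matA)$rank), drop = FALSE]
  qb <- qr.Q(qr(matB))[, seq_len(qr(matB)$rank), drop = FALSE]
  sv <- svd(crossprod(qa, qb))$d
  ang <- sort(acos(pmin(pmax(sv, 0), 1))) * 180 / pi
  data.frame(index = seq_along(ang), angle = ang)
}

#' Monte-Carlo baseline for angles between random subspaces
#'
#' Distribution of principal angles between two independent k-dimensional
#' subspaces of R^ambient drawn from the rotation-invariant ensemble
#' (standard Gaussian matrices, orthonormalized). Used as the chance
#' reference against which measured mode angles are judged.
#'
#' @param ambient ambient dimension (default 20).
#' @param k subspace dimension (default 5).
#' @param reps Monte-Carlo repetitions.
#' @param seed RNG seed.
#' @return data.frame with \code{index}, \code{mean} and \code{sd} of each
#'   ordered principal angle (degrees), plus attribute \code{"samples"}
#'   holding the reps x k angle draws.
#' @export
randomAngleBaseline <- function(ambient = 20L, k = 5L, reps = 1000L, seed = 1L) {
  if (k > ambient) stop("k cannot exceed the ambient dimension")
  draws <- withSeed(seed, {
    t(matrix(vapply(seq_len(reps), function(r) {
      A <- matrix(stats::rnorm(ambient * k), ambient, k)
      B <- matrix(stats::rnorm(ambient * k), ambient, k)
      principalAngles(A, B)$angle
    }, numeric(k)), nrow = k))
  })
  out <- data.frame(index = seq_len(k),
                    mean = colMeans(draws),
                    sd = apply(draws, 2, stats::sd))
  attr(out, "samples") <- draws
  out
}

#' Mode stability across neuron counts
#'
#' Reproduces the subspace-stability protocol: nested neuron subsets of
#' increasing size are drawn from the count matrix, a factor-analysis model
#' is fitted per subset, every model is restricted to a common core of
#' \code{commonSize} neurons (contained in the smallest subset), and the
#' principal angles between each subset's top-k modes and the reference
#' fit's top-k modes are reported, together with the per-mode percent
#' shared variance of the smallest and reference fits and the random-angle
#' baseline.
#'
#' @param counts a [CountMatrix-class].
#' @param subsetSizes increasing neuron counts to compare (each <=
#'   \code{referenceSize}).
#' @param referenceSize neuron count of the reference fit.
#' @param commonSize size of the common neuron core (default 20).
#' @param k number of dominant modes (default 5).
#' @param faOpts list of fitting options: \code{m} for a fixed
#'   dimensionality, or \code{mMax}, \code{folds} for cross-validated
#'   selection; optional \code{tol}, \code{maxIter}.
#' @param seed RNG seed (subset draws and CV folds).
#' @param baselineReps Monte-Carlo repetitions for the chance baseline.
#' @return list with \code{angles} (data.frame: subsetSize, index, angle),
#'   \code{baseline} (from [randomAngleBaseline()]), \code{perMode}
#'   (per-mode percent shared variance for the smallest and reference
#'   fits), and \code{subsets} (the neuron index sets used).
#' @export
modeStabilityExperiment <- function(counts, subsetSizes, referenceSize,
                                    commonSize = 20L, k = 5L,
                                    faOpts = list(), seed = 1L,
                                    baselineReps = 1000L) {
  subsetSizes <- sort(as.integer(subsetSizes))
  if (max(subsetSizes) > referenceSize)
    stop("referenceSize must be at least every subset size")
  if (commonSize > min(subsetSizes))
    stop("commonSize must fit inside the smallest subset")
  pool <- seq_len(nNeurons(counts))
  sizes <- unique(c(subsetSizes, as.integer(referenceSize)))
  sets <- nestedNeuronSubsets(pool, sizes, seed = seed)
  names(sets) <- sizes
  common <- sets[[1]][seq_len(commonSize)]

  fitOne <- function(idx) {
    sub <- counts[, idx]
    m <- faOpts[["m"]]
    if (is.null(m)) {
      sel <- selectDimensionality(sub,
                                  mMax = faOpts[["mMax"]] %||% 10L,
                                  folds = faOpts[["folds"]] %||% 4L,
                                  seed = seed,
                                  tol = faOpts[["tol"]] %||% 1e-6,
                                  maxIter = faOpts[["maxIter"]] %||% 500L)
      m <- sel$mStar
    }
    suppressWarnings(fitFA(sub, m, tol = faOpts[["tol"]] %||% 1e-6,
                           maxIter = faOpts[["maxIter"]] %||% 500L))
  }

  fits <- lapply(sets, fitOne)
  refFit <- fits[[length(fits)]]
  refBasis <- restrictedModes(refFit, match(common, sets[[length(sets)]]), k = k)

  angleRows <- lapply(as.character(subsetSizes), function(sz) {
    fit <- fits[[sz]]
    basis <- restrictedModes(fit, match(common, sets[[sz]]),
                             k = min(k, ncol(refBasis@basis)))
    pa <- principalAngles(basis, refBasis)
    cbind(subsetSize = as.integer(sz), pa)
  })
  angles <- do.call(rbind, angleRows)

  list(angles = angles,
       baseline = randomAngleBaseline(commonSize, k, reps = baselineReps,
                                      seed = seed),
       perMode = list(
         smallest = perModePercentSharedVariance(fits[[1]]),
         reference = perModePercentSharedVariance(refFit)),
       subsets = sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
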