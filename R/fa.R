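# Shared-variance decomposition of spike-count covariance by factor
# analysis. The model is x ~ N(mu, LL' + Psi) with diagonal Psi; EM runs
# entirely on the sample covariance (the Gaussian sufficient statistic), so
# each iteration costs O(p^2 m) regardless of trial count. Likelihoods use
# the Woodbury identity and the matrix determinant lemma so that only an
# m x m system is ever factorized.

# Sigma^{-1} and log|Sigma| for Sigma = LL' + diag(Psi) via Woodbury
.faSigmaInv <- function(L, Psi) {
  p <- length(Psi)
  m <- ncol(L)
  if (m == 0L) {
    return(list(SigmaInv = diag(1 / Psi, p), logDet = sum(log(Psi))))
  }
  PsiInvL <- L / Psi
  G <- diag(m) + crossprod(L, PsiInvL)        # I + L' Psi^-1 L
  cG <- chol(G)
  logDet <- 2 * sum(log(diag(cG))) + sum(log(Psi))
  # Psi^-1 - Psi^-1 L G^-1 L' Psi^-1
  GinvLt <- backsolve(cG, forwardsolve(t(cG), t(PsiInvL)))
  SigmaInv <- diag(1 / Psi, p) - PsiInvL %*% GinvLt
  list(SigmaInv = SigmaInv, logDet = logDet)
}

# Gaussian log-likelihood (nats, summed over n trials) from a second-moment
# matrix A about the model mean
.faLogLikFromMoment <- function(L, Psi, A, n) {
  p <- length(Psi)
  s <- .faSigmaInv(L, Psi)
  -n / 2 * (p * log(2 * pi) + s$logDet + sum(s$SigmaInv * A))
}

#' Fit the factor-analysis model by expectation-maximization
#'
#' Fits \eqn{x \sim N(\mu, LL^T + \Psi)} to a trials x neurons count
#' matrix. \eqn{\mu} is the sample mean; EM alternates the posterior
#' moments of the m latents with closed-form updates of L and the diagonal
#' \eqn{\Psi}, and the training log-likelihood is non-decreasing across
#' iterations. For \code{m = 0} the model has no shared component and
#' \eqn{\Psi} equals the maximum-likelihood sample variances.
#'
#' Initialization is deterministic: L starts at the top-m principal
#' directions of the sample covariance, scaled by the square root of each
#' eigenvalue's excess over the mean initial \eqn{\Psi}; \eqn{\Psi} starts
#' at the sample variances. \eqn{\Psi} is floored at \code{1e-6} times each
#' neuron's sample variance to rule out Heywood cases.
#'
#' @param counts a [CountMatrix-class] or trials x neurons matrix.
#' @param m latent dimensionality (>= 0).
#' @param tol stop when the relative log-likelihood change falls below this.
#' @param maxIter maximum EM iterations.
#' @return an [FAModel-class].
#' @seealso [cvSelectM()] for choosing m, [sharedSpectrum()],
#'   [percentSharedVariance()] for derived metrics.
#' @export
fitFA <- function(counts, m, tol = 1e-8, maxIter = 3000L) {
  ids <- if (is(counts, "CountMatrix")) counts@neuronIds else NULL
  X <- asCountInput(counts)
  n <- nrow(X)
  p <- ncol(X)
  m <- as.integer(m)
  if (m < 0L) stop("m must be non-negative")
  if (m > p - 1L) stop("m must be at most neurons - 1")
  if (n <= p) warning("fewer trials than neurons + 1; the fit may be unstable")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / n
  v <- diag(S)
  if (any(v <= 0))
    stop("zero-variance neuron(s) at column(s) ",
         paste(which(v <= 0), collapse = ", "),
         "; drop them or add jitter before fitting")
  if (is.null(ids)) ids <- seq_len(p)

  if (m == 0L) {
    L <- matrix(0, p, 0)
    ll <- .faLogLikFromMoment(L, v, S, n)
    return(new("FAModel", mu = mu, L = L, Psi = v, m = 0L,
               neuronIds = as.integer(ids), nObs = as.integer(n),
               logLik = ll, logLikTrace = ll, iterations = 0L,
               converged = TRUE))
  }

  es <- eigen(S, symmetric = TRUE)
  Psi <- v
  scl <- sqrt(pmax(es$values[seq_len(m)] - mean(Psi), 1e-3 * mean(Psi)))
  L <- es$vectors[, seq_len(m), drop = FALSE] %*% diag(scl, m, m)
  floorPsi <- 1e-6 * v

  trace <- numeric(maxIter)
  llPrev <- -Inf
  iter <- 0L
  converged <- FALSE
  Im <- diag(m)
  repeat {
    iter <- iter + 1L
    s <- .faSigmaInv(L, Psi)
    ll <- -n / 2 * (p * log(2 * pi) + s$logDet + sum(s$SigmaInv * S))
    trace[iter] <- ll
    if (is.finite(llPrev) &&
        abs(ll - llPrev) <= tol * abs(llPrev)) { converged <- TRUE; break }
    if (iter >= maxIter) break
    llPrev <- ll
    beta <- crossprod(L, s$SigmaInv)           # m x p
    SB <- S %*% t(beta)                        # p x m = S beta'
    M <- Im - beta %*% L + beta %*% SB         # E[zz'] averaged over trials
    L <- SB %*% solve(M)
    Psi <- pmax(v - rowSums(L * SB), floorPsi)
  }
  if (!converged)
    warning(sprintf("EM did not reach tolerance in %d iterations", maxIter))
  new("FAModel", mu = mu, L = L, Psi = Psi, m = m,
      neuronIds = as.integer(ids), nObs = as.integer(n),
      logLik = trace[iter], logLikTrace = trace[seq_len(iter)],
      iterations = iter, converged = converged)
}

#' Exact log-likelihood of counts under a fitted model
#'
#' Multivariate-normal log density under covariance \eqn{LL^T + \Psi},
#' summed over trials (nats), evaluated with the Woodbury inversion and the
#' matrix determinant lemma so only an m x m factorization is needed.
#'
#' @param counts a [CountMatrix-class] or trials x neurons matrix.
#' @param model an [FAModel-class] with matching neuron dimension.
#' @return scalar log-likelihood.
#' @export
logLikelihoodFA <- function(counts, model) {
  X <- asCountInput(counts)
  if (ncol(X) != length(model@mu))
    stop("counts and model disagree on the number of neurons")
  Xc <- sweep(X, 2, model@mu)
  A <- crossprod(Xc) / nrow(X)
  .faLogLikFromMoment(model@L, model@Psi, A, nrow(X))
}

#' Select the latent dimensionality by cross-validated likelihood
#'
#' Partitions trials into \code{folds} random folds (seeded); for every m
#' in \code{mGrid} the model is fitted on the training folds and scored by
#' exact held-out log-likelihood on the left-out fold. The selected
#' \code{mStar} maximizes the mean held-out log-likelihood, with ties going
#' to the smallest m (parsimony).
#'
#' @param counts a [CountMatrix-class] or trials x neurons matrix.
#' @param mGrid integer candidate dimensionalities (should include 0).
#' @param folds number of cross-validation folds (>= 2, default 4).
#' @param seed RNG seed for the fold assignment.
#' @param tol,maxIter EM settings passed to [fitFA()].
#' @return list with \code{mStar}, \code{table} (data.frame of m and mean
#'   held-out log-likelihood), \code{folds} and \code{seed}.
#' @export
cvSelectM <- function(counts, mGrid, folds = 4L, seed = 1L,
                      tol = 1e-6, maxIter = 500L) {
  X <- asCountInput(counts)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be at least 2")
  if (n < folds) stop("fewer trials than folds")
  mGrid <- sort(unique(as.integer(mGrid)))
  foldId <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  ll <- matrix(NA_real_, nrow = length(mGrid), ncol = folds)
  for (f in seq_len(folds)) {
    train <- X[foldId != f, , drop = FALSE]
    test <- X[foldId == f, , drop = FALSE]
    for (gi in seq_along(mGrid)) {
      fit <- suppressWarnings(fitFA(train, mGrid[gi], tol = tol,
                                    maxIter = maxIter))
      ll[gi, f] <- logLikelihoodFA(test, fit)
    }
  }
  meanLL <- rowMeans(ll)
  list(mStar = mGrid[which.max(meanLL)],
       table = data.frame(m = mGrid, meanHeldOutLogLik = meanLL),
       folds = folds, seed = seed)
}

#' Coarse-to-fine cross-validated dimensionality search
#'
#' Evaluates a coarse m grid (unit steps up to 10, then steps of 2 up to
#' \code{mMax}) with [cvSelectM()], then refines with unit steps around the
#' coarse argmax. Returns the refined selection together with the combined
#' evaluation table.
#'
#' @inheritParams cvSelectM
#' @param mMax largest dimensionality to consider (capped at neurons - 1).
#' @return as [cvSelectM()].
#' @export
selectDimensionality <- function(counts, mMax = 10L, folds = 4L, seed = 1L,
                                 tol = 1e-6, maxIter = 500L) {
  X <- asCountInput(counts)
  mMax <- min(as.integer(mMax), ncol(X) - 1L)
  coarse <- unique(c(0:min(10L, mMax),
                     if (mMax > 10L) seq(12L, mMax, by = 2L)))
  res <- cvSelectM(X, coarse, folds = folds, seed = seed,
                   tol = tol, maxIter = maxIter)
  extra <- setdiff(intersect((res$mStar - 1L):(res$mStar + 1L), 0:mMax), coarse)
  if (length(extra)) {
    res2 <- cvSelectM(X, extra, folds = folds, seed = seed,
                      tol = tol, maxIter = maxIter)
    tab <- rbind(res$table, res2$table)
    tab <- tab[order(tab$m), , drop = FALSE]
    rownames(tab) <- NULL
    best <- tab$m[which.max(tab$meanHeldOutLogLik)]
    res <- list(mStar = best, table = tab, folds = folds, seed = seed)
  }
  res
}

# ---- derived metrics -------------------------------------------------------

.spectrumFromL <- function(L, ids) {
  m <- ncol(L)
  if (m == 0L) {
    return(new("SharedSpectrum", values = numeric(0),
               vectors = matrix(0, nrow(L), 0), neuronIds = as.integer(ids)))
  }
  sv <- svd(L, nu = m, nv = 0)
  U <- sv$u
  # sign convention: largest-magnitude entry of each mode positive
  for (j in seq_len(ncol(U))) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  new("SharedSpectrum", values = sv$d^2, vectors = U,
      neuronIds = as.integer(ids))
}

#' @rdname sharedSpectrum
#' @export
setMethod("sharedSpectrum", "FAModel", function(x)
  .spectrumFromL(x@L, x@neuronIds))

#' @rdname sharedSpectrum
#' @export
setMethod("sharedSpectrum", "GenerativeFASpec", function(x)
  .spectrumFromL(x@L, seq_along(x@mu)))

#' @rdname sharedCovariance
#' @export
setMethod("sharedCovariance", "FAModel", function(x) tcrossprod(x@L))

#' @rdname sharedCovariance
#' @export
setMethod("sharedCovariance", "GenerativeFASpec", function(x) tcrossprod(x@L))

.dSharedFromValues <- function(values, threshold) {
  total <- sum(values)
  if (!length(values) || total <= 0) return(0L)
  as.integer(which(cumsum(values) >= threshold * total)[1])
}

#' @rdname sharedDimensionality
#' @export
setMethod("sharedDimensionality", "numeric", function(x, threshold = 0.95)
  .dSharedFromValues(sort(x, decreasing = TRUE), threshold))

#' @rdname sharedDimensionality
#' @export
setMethod("sharedDimensionality", "SharedSpectrum", function(x, threshold = 0.95)
  .dSharedFromValues(x@values, threshold))

#' @rdname sharedDimensionality
#' @export
setMethod("sharedDimensionality", "FAModel", function(x, threshold = 0.95)
  .dSharedFromValues(sharedSpectrum(x)@values, threshold))

.psv <- function(L, Psi) {
  sh <- rowSums(L^2)
  per <- 100 * sh / (sh + Psi)
  per[sh + Psi == 0] <- 0
  list(perNeuron = per, population = mean(per))
}

#' @rdname percentSharedVariance
#' @export
setMethod("percentSharedVariance", "FAModel", function(x) .psv(x@L, x@Psi))

#' @rdname percentSharedVariance
#' @export
setMethod("percentSharedVariance", "GenerativeFASpec", function(x)
  .psv(x@L, x@Psi))

#' @rdname modeVarianceFractions
#' @export
setMethod("modeVarianceFractions", "SharedSpectrum", function(x) {
  if (!length(x@values)) return(numeric(0))
  100 * x@values / sum(x@values)
})

#' @rdname modeVarianceFractions
#' @export
setMethod("modeVarianceFractions", "FAModel", function(x)
  modeVarianceFractions(sharedSpectrum(x)))

#' Percent shared variance along each mode
#'
#' Partitions each neuron's percent shared variance across the eigenmodes
#' of \eqn{LL^T}: for mode i and neuron k the contribution is
#' \eqn{100 \, \lambda_i u_{ik}^2 / (L_k L_k^T + \Psi_k)}, averaged over
#' neurons. Summing the result over modes recovers the population percent
#' shared variance exactly.
#'
#' @param model an [FAModel-class] (or [GenerativeFASpec-class]).
#' @param spectrum optional precomputed [SharedSpectrum-class].
#' @return numeric vector, one value (%) per mode, descending eigenvalue
#'   order.
#' @export
perModePercentSharedVariance <- function(model, spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- sharedSpectrum(model)
  if (!length(spectrum@values)) return(numeric(0))
  denom <- rowSums(model@L^2) + model@Psi
  contrib <- sweep(spectrum@vectors^2, 2, spectrum@values, `*`)  # p x m
  colMeans(100 * contrib / denom)
}

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "FAModel", function(x) length(x@mu))

#' @rdname loadingMatrix
#' @export
setMethod("loadingMatrix", "FAModel", function(x) x@L)

#' @rdname independentVariances
#' @export
setMethod("independentVariances", "FAModel", function(x) x@Psi)

#' @rdname latentDim
#' @export
setMethod("latentDim", "FAModel", function(x) x@m)

setMethod("show", "FAModel", function(object) {
  cat(sprintf(
    "FAModel: %d neurons, m = %d (%d trials; logLik %.2f; %s in %d iter)\n",
    length(object@mu), object@m, object@nObs, object@logLik,
    if (object@converged) "converged" else "not converged", object@iterations))
})

setMethod("show", "SharedSpectrum", function(object) {
  cat(sprintf("SharedSpectrum: %d modes over %d neurons\n",
              length(object@values), nrow(object@vectors)))
  if (length(object@values)) {
    fr <- modeVarianceFractions(object)
    cat(sprintf("  top mode %.1f%% of shared variance; d_shared = %d\n",
                fr[1], sharedDimensionality(object)))
  }
})
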