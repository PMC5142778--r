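# File formats: counts as TSV (trials x neurons, header of 0-based neuron
# ids, sidecar JSON metadata), spikes as two-column TSV, configurations and
# fitted models as JSON. Neuron ids are 0-based on disk and 1-based inside
# R objects; all times are seconds at file interfaces.

.openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Write / read a count matrix as TSV plus JSON sidecar
#'
#' The TSV has one header row of 0-based neuron ids and one row per trial;
#' the sidecar (\code{<path>.json}) stores bin width, burn-in, cluster
#' labels, mean rates and trial start times. \code{readCounts} validates
#' the table (rectangular, numeric, non-negative, no duplicate ids) and
#' reports the offending line on failure.
#'
#' @param x a [CountMatrix-class].
#' @param path TSV file path (\code{.gz} accepted when reading).
#' @return \code{writeCounts}: the path, invisibly. \code{readCounts}: a
#'   [CountMatrix-class].
#' @export
writeCounts <- function(x, path) {
  stopifnot(is(x, "CountMatrix"))
  m <- x@counts
  colnames(m) <- x@neuronIds - 1L
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(binWidth = x@binWidth, burnIn = x@burnIn,
               neuronIds = x@neuronIds - 1L,
               clusterLabel = x@clusterLabel, trialStart = x@trialStart)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeCounts
#' @param sidecar path of the JSON metadata file (default
#'   \code{<path>.json}; silently optional).
#' @export
readCounts <- function(path, sidecar = paste0(path, ".json")) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 2) stop("counts file needs a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ids <- suppressWarnings(as.integer(header))
  if (any(is.na(ids))) stop("header must contain integer neuron ids")
  if (anyDuplicated(ids)) stop("duplicate neuron ids in header")
  p <- length(ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  counts <- matrix(0, length(rows), p)
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != p)
      stop(sprintf("line %d: expected %d cells, found %d", r + 1L, p,
                   length(rows[[r]])))
    v <- suppressWarnings(as.numeric(rows[[r]]))
    if (any(is.na(v)) || any(v != round(v)))
      stop(sprintf("line %d: non-integer cell", r + 1L))
    if (any(v < 0)) stop(sprintf("line %d: negative count", r + 1L))
    counts[r, ] <- v
  }
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else list()
  cm <- countMatrix(counts, binWidth = meta$binWidth %||% 1,
                    neuronIds = ids + 1L,
                    clusterLabel = meta$clusterLabel %||% NULL,
                    burnIn = meta$burnIn %||% 0)
  if (!is.null(meta$trialStart)) cm@trialStart <- as.numeric(meta$trialStart)
  cm
}

#' Write / read a spike record as two-column TSV
#'
#' Format: an optional \code{# duration_s=<x>} comment, a header line, then
#' \code{neuron_id<TAB>time_s} rows sorted by time (0-based neuron ids on
#' disk). Gzip-compressed files are read transparently. Unsorted input is
#' rejected unless \code{lenient = TRUE}, which sorts with a warning.
#'
#' @param x a [SpikeRecord-class].
#' @param path file path (\code{.gz} accepted when reading).
#' @return \code{writeSpikes}: the path, invisibly. \code{readSpikes}: a
#'   [SpikeRecord-class] (without configuration).
#' @export
writeSpikes <- function(x, path) {
  stopifnot(is(x, "SpikeRecord"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.17g", x@duration), con)
  writeLines("neuron_id\ttime_s", con)
  if (nrow(x@events))
    writeLines(sprintf("%d\t%.17g", x@events$neuron - 1L, x@events$time), con)
  invisible(path)
}

#' @rdname writeSpikes
#' @param lenient sort out-of-order rows with a warning instead of failing.
#' @param duration duration override (s); default from the file comment or
#'   the ceiling of the last spike time.
#' @export
readSpikes <- function(path, lenient = FALSE, duration = NULL) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (is.null(duration) && length(lines) && startsWith(lines[1], "# duration_s="))
    duration <- as.numeric(sub("# duration_s=", "", lines[1], fixed = TRUE))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("spike file is empty")
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("line %d: expected 2 tab-separated cells", bad[1] + 1L))
  neuron <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  time <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (any(is.na(neuron)) || any(neuron < 0))
    stop(sprintf("line %d: invalid neuron id",
                 which(is.na(neuron) | neuron < 0)[1] + 1L))
  if (any(is.na(time)) || any(time < 0))
    stop(sprintf("line %d: invalid spike time",
                 which(is.na(time) | time < 0)[1] + 1L))
  if (is.unsorted(time)) {
    if (!lenient) stop("spike times are not sorted (use lenient = TRUE to sort)")
    warning("spike times were not sorted; sorting")
    ord <- order(time, neuron)
    neuron <- neuron[ord]
    time <- time[ord]
  }
  if (is.null(duration)) duration <- if (length(time)) ceiling(max(time) + 1e-9) else 0
  new("SpikeRecord",
      events = data.frame(neuron = neuron + 1L, time = time),
      duration = duration, config = NULL)
}

#' Write / read a network configuration as JSON
#'
#' @param config a [NetworkConfig-class].
#' @param path JSON file path.
#' @return \code{writeNetworkConfig}: the path, invisibly.
#'   \code{readNetworkConfig}: a [NetworkConfig-class].
#' @export
writeNetworkConfig <- function(config, path) {
  stopifnot(is(config, "NetworkConfig"))
  obj <- list(
    nExcitatory = config@nExcitatory, nInhibitory = config@nInhibitory,
    tauM = as.list(config@tauM),
    biasRange = list(E = unname(config@biasRange["E", ]),
                     I = unname(config@biasRange["I", ])),
    vThreshold = config@vThreshold, vReset = config@vReset,
    refractory = config@refractory,
    tauRise = config@tauRise, tauDecay = as.list(config@tauDecay),
    J = list(EE = config@J["E", "E"], EI = config@J["E", "I"],
             IE = config@J["I", "E"], II = config@J["I", "I"]),
    p = list(EE = config@p["E", "E"], EI = config@p["E", "I"],
             IE = config@p["I", "E"], II = config@p["I", "I"]),
    nClusters = config@nClusters, clusterSize = config@clusterSize,
    pInEE = config@pInEE, pOutEE = config@pOutEE,
    jInEE = config@jInEE, jOutEE = config@jOutEE,
    dt = config@dt, burnIn = config@burnIn)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  networkConfig(
    nExcitatory = o$nExcitatory, nInhibitory = o$nInhibitory,
    tauM = c(E = o$tauM$E, I = o$tauM$I),
    biasRange = rbind(E = o$biasRange$E, I = o$biasRange$I),
    vThreshold = o$vThreshold, vReset = o$vReset, refractory = o$refractory,
    tauRise = o$tauRise, tauDecay = c(E = o$tauDecay$E, I = o$tauDecay$I),
    J = rbind(E = c(E = o$J$EE, I = o$J$EI), I = c(E = o$J$IE, I = o$J$II)),
    p = rbind(E = c(E = o$p$EE, I = o$p$EI), I = c(E = o$p$IE, I = o$p$II)),
    nClusters = o$nClusters, clusterSize = o$clusterSize,
    pInEE = o$pInEE, pOutEE = o$pOutEE, jInEE = o$jInEE, jOutEE = o$jOutEE,
    dt = o$dt, burnIn = o$burnIn)
}

#' Canonical network configuration presets
#'
#' Loads the clustered or non-clustered full-scale configuration shipped
#' with the package (\code{inst/extdata}).
#'
#' @param kind \code{"clustered"} or \code{"nonclustered"}.
#' @return a [NetworkConfig-class].
#' @export
paperNetworkConfig <- function(kind = c("clustered", "nonclustered")) {
  kind <- match.arg(kind)
  readNetworkConfig(system.file("extdata", paste0(kind, "_paper.json"),
                                package = "popdim", mustWork = TRUE))
}

#' Write / read a fitted factor-analysis model as JSON
#'
#' Serializes mu, L (row-major), Psi, m, the neuron ids and fit metadata.
#'
#' @param model an [FAModel-class].
#' @param path JSON file path.
#' @return \code{writeFAModel}: the path, invisibly. \code{readFAModel}:
#'   an [FAModel-class].
#' @export
writeFAModel <- function(model, path) {
  stopifnot(is(model, "FAModel"))
  obj <- list(mu = model@mu,
              L = if (model@m > 0) apply(model@L, 1, function(r) r,
                                         simplify = FALSE) else list(),
              Psi = model@Psi, m = model@m,
              neuronIds = model@neuronIds - 1L, nObs = model@nObs,
              logLik = model@logLik, iterations = model@iterations,
              converged = model@converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFAModel
#' @export
readFAModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(o$mu)
  L <- if (o$m > 0) {
    if (is.matrix(o$L)) o$L
    else if (is.list(o$L)) do.call(rbind, o$L)
    else matrix(o$L, nrow = p)
  } else matrix(0, p, 0)
  new("FAModel", mu = as.numeric(o$mu), L = L, Psi = as.numeric(o$Psi),
      m = as.integer(o$m), neuronIds = as.integer(o$neuronIds) + 1L,
      nObs = as.integer(o$nObs), logLik = as.numeric(o$logLik),
      logLikTrace = numeric(0), iterations = as.integer(o$iterations),
      converged = as.logical(o$converged))
}
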