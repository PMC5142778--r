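#' @useDynLib popdim, .registration = TRUE
#' @importClassesFrom Matrix Matrix dgCMatrix
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd var acf setNames
#' @importFrom utils read.delim write.table
NULL
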