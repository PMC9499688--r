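#' @useDynLib oligolens, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dist sd IQR runif setNames
#' @importFrom utils head read.table write.table
#' @import methods
NULL
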