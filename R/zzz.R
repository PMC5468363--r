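#' @useDynLib sdpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm setNames
#' @importFrom utils combn
NULL
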