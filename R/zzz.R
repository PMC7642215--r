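#' @useDynLib staincycle, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif predict quantile
#' @importFrom utils head tail write.csv
#' @importFrom grDevices rgb
#' @importFrom graphics plot lines legend rasterImage par
#' @keywords internal
"_PACKAGE"
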