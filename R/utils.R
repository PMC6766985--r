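#' @importFrom utils head tail read.delim write.csv read.csv
#' @importFrom stats rnorm runif sd dist cor sd quantile
NULL

## package-level cache for rule tables etc.
.gridtox_cache <- new.env(parent = emptyenv())

## lightweight structured logging to stderr; quiet by option
gtLog <- function(fmt, ..., level = "INFO") {
  if (isTRUE(getOption("GridTox.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[GridTox %s] %s", level, sprintf(fmt, ...)))
}

gtWarn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## path to a packaged data file
gtExtdata <- function(file) {
  p <- system.file("extdata", file, package = "GridTox", mustWork = TRUE)
  p
}

## smoothing helper for loss-curve checks (simple moving average)
movingAverage <- function(x, window = 5L) {
  stats::filter(x, rep(1 / window, window), sides = 2L)
}
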