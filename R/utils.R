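#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft lm p.adjust predict pt quantile convolve dist
#'   rnorm rpois runif sd var setNames residuals complete.cases
#' @importFrom utils head read.delim write.table
NULL

# Stop with a consistent invalid-argument condition.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("fvconn_invalid_argument", "error")))
}

stop_state <- function(...) {
  stop(errorCondition(paste0(...), class = c("fvconn_invalid_state", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Derive a reproducible child seed from a parent seed and a stream index.
# Keeps results < 2^31 so they remain valid R integers.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(stream)) %% 2147483647)
}

# Upper-triangle vectorization used for edge-level comparisons everywhere.
upper_vec <- function(m) m[upper.tri(m)]

#' Population (1/n) standard deviation
#' @param x numeric vector
#' @return non-negative scalar
#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
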