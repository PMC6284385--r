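#' @importFrom stats median dnorm runif rbeta rbinom complete.cases aggregate
#' @importFrom utils read.table write.table head
NULL

# round half away from zero for positive positions (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

# error helper: consistent "field: problem" messages for config validation
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# derive a per-item stream seed from a global seed; stable, order-independent,
# and kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}
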