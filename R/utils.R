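#' @importFrom Matrix Matrix sparseMatrix Diagonal readMM writeMM
#'   colSums rowSums colMeans rowMeans
#' @importFrom rlang %||% .data abort warn
#' @importFrom stats cor cor.test rnbinom rpois rnorm rlnorm rmultinom runif
#'   sd wilcox.test pt p.adjust setNames
#' @importFrom methods as is
NULL

# Stage-local seed: derive a 32-bit sub-seed from a master seed and a stage
# name so each pipeline stage has its own reproducible RNG stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

is_count_matrix <- function(x) inherits(x, "count_matrix")

assert_that <- function(ok, msg) if (!isTRUE(ok)) abort(msg)
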