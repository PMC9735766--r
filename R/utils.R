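# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Preprocessing stages in their mandatory order. Each stage may only be
# applied to an EEM whose current stage ranks strictly lower; skipping
# stages is allowed (blank subtraction and inner-filter correction are
# optional), going backwards or repeating is not.
.stages <- c(
  raw = 0L, blank_subtracted = 1L, ife_corrected = 2L,
  raman_normalized = 3L, scatter_excised = 4L, interpolated = 5L,
  scaled = 6L
)

stage_rank <- function(stage) {
  r <- .stages[[stage]]
  if (is.null(r)) stop("unknown pipeline stage: ", stage, call. = FALSE)
  r
}

check_stage <- function(x, op_stage, require = NULL) {
  cur <- x$meta$pipeline_stage %||% "raw"
  if (!is.null(require) && cur != require) {
    stop(sprintf("'%s' requires an EEM at stage '%s' (got '%s')",
                 op_stage, require, cur), call. = FALSE)
  }
  if (stage_rank(cur) >= stage_rank(op_stage)) {
    stop(sprintf(
      "pipeline order violation: stage '%s' cannot follow stage '%s'",
      op_stage, cur), call. = FALSE)
  }
  invisible(cur)
}

set_stage <- function(x, stage) {
  x$meta$pipeline_stage <- stage
  x
}

# Round half away from zero at `digits` decimals (display convention for
# printed tables; R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trapezoidal integral of y over x (ascending x).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_ascending <- function(x) {
  is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    (length(x) == 1 || all(diff(x) > 0))
}
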