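# Internal helpers shared across modules.

# Condition constructor: all package errors carry a machine-readable code
# ("schema", "data", "numeric") so callers and the CLI can map them to exit
# statuses without parsing messages.
stop_stainref <- function(code, msg, ...) {
  stop(structure(
    class = c(paste0("stainref_error_", code), "stainref_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Angular distance between two vectors, in degrees
#'
#' @param u,v numeric vectors of equal length.
#' @return Angle in degrees in \[0, 180\].
#' @keywords internal
#' @export
angle_deg <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Smallest power of two at least m
#'
#' @param m positive integer.
#' @return The smallest integer power of 2 that is `>= m`.
#' @examples
#' next_pow2(100) # 128
#' next_pow2(128) # 128
#' @export
next_pow2 <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop_stainref("schema", "next_pow2 requires a single integer >= 1")
  m <- as.integer(ceiling(m))
  p <- 1L
  while (p < m) p <- p * 2L
  p
}

# Normalize matrix columns to unit Euclidean norm.
unit_cols <- function(w) {
  nrm <- sqrt(colSums(w^2))
  if (any(nrm == 0))
    stop_stainref("numeric", "stain matrix has a zero column")
  sweep(w, 2, nrm, "/")
}
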