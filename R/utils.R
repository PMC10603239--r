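# Internal helpers shared across modules.

#' Hand positions used in the HBR task
#'
#' The stimulated hand is held at one of three positions relative to the
#' face: FAR (~40 cm), MIDDLE (~20 cm) and NEAR (~4 cm). Positions are
#' encoded ordinally and unit-spaced as 0, 1, 2 so that model slopes are
#' per-step rates of change.
#' @export
HBR_POSITIONS <- c("FAR", "MIDDLE", "NEAR")

# FAR -> 0, MIDDLE -> 1, NEAR -> 2
position_index <- function(position) {
  if (is.numeric(position)) {
    if (!all(position %in% 0:2)) {
      stop("numeric positions must be 0 (FAR), 1 (MIDDLE) or 2 (NEAR)")
    }
    return(as.numeric(position))
  }
  position <- as.character(position)
  idx <- match(position, HBR_POSITIONS) - 1
  if (anyNA(idx)) {
    stop("unknown position(s): ", paste(unique(position[is.na(idx)]), collapse = ", "))
  }
  as.numeric(idx)
}

position_factor <- function(position) {
  factor(HBR_POSITIONS[position_index(position) + 1], levels = HBR_POSITIONS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a whole number >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive number", name))
  }
  invisible(as.numeric(x))
}

# seeds derived from a user seed must stay below .Machine$integer.max
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 101 + offset) %% 2147483587
}
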