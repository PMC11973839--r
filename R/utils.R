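#' Heaviside step function
#'
#' `H(x) = 1` for `x >= 0` and `0` otherwise. This is the final decision
#' operator of the sum-of-sigmoids classifier: a zero sum is classified as
#' an event.
#'
#' @param x numeric vector of finite values.
#' @return numeric vector of 0/1.
#' @examples
#' heaviside(c(-1, 0, 2))
#' @export
heaviside <- function(x) {
  if (any(!is.finite(x))) stop("heaviside() requires finite input")
  as.numeric(x >= 0)
}

# half-up rounding used only at display time (the clinical tables round
# .005 upward; R's round() rounds to even)
.round2 <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# weighted median; used to initialise the sigmoid location parameter at the
# gain-weighted median stump threshold
.weightedMedian <- function(x, w) {
  if (!length(x)) return(NA_real_)
  if (all(w <= 0)) w <- rep(1, length(x))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

.assertBinary <- function(v, what) {
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop(what, " must contain only 0/1 values")
  invisible(v)
}
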