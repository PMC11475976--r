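#' The eight S- and V-shaped transfer functions
#'
#' Transfer functions map a continuous optimizer coordinate to a
#' bit-probability in \[0, 1\]. The S-family are logistic sigmoids of
#' decreasing slope; the V-family are even functions vanishing at 0:
#' \deqn{S1 = 1/(1+e^{-2x}),\; S2 = 1/(1+e^{-x}),\; S3 = 1/(1+e^{-x/2}),\;
#'       S4 = 1/(1+e^{-x/3})}
#' \deqn{V1 = |\mathrm{erf}((\sqrt\pi/2)x)|,\; V2 = |\tanh x|,\;
#'       V3 = |x/\sqrt{1+x^2}|,\; V4 = |(2/\pi)\arctan((\pi/2)x)|}
#'
#' @return Character vector of the eight valid ids, `"S1" ... "V4"`.
#' @export
transfer_function_ids <- function() {
  c(paste0("S", 1:4), paste0("V", 1:4))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

.tf_registry <- list(
  S1 = function(x) 1 / (1 + exp(-2 * x)),
  S2 = function(x) 1 / (1 + exp(-x)),
  S3 = function(x) 1 / (1 + exp(-x / 2)),
  S4 = function(x) 1 / (1 + exp(-x / 3)),
  V1 = function(x) abs(erf(sqrt(pi) / 2 * x)),
  V2 = function(x) abs(tanh(x)),
  V3 = function(x) abs(x / sqrt(1 + x^2)),
  V4 = function(x) abs(2 / pi * atan(pi / 2 * x))
)

#' Evaluate a transfer function
#'
#' @param id one of [transfer_function_ids()].
#' @param x finite numeric vector of continuous coordinates.
#' @return Probabilities in \[0, 1\], same length as `x`.
#' @export
#' @examples
#' tf_value("S2", log(3))  # 0.75
#' tf_value("V3", 1)       # 1/sqrt(2)
tf_value <- function(id, x) {
  if (!id %in% names(.tf_registry)) {
    stop("unknown transfer function '", id, "'; valid ids: ",
         paste(transfer_function_ids(), collapse = ", "))
  }
  if (any(!is.finite(x))) stop("x: must be finite")
  .tf_registry[[id]](x)
}

#' Which family (S or V) a transfer function belongs to
#' @param id transfer function id.
#' @return `"S"` or `"V"`.
#' @export
tf_family <- function(id) substr(id, 1, 1)

#' Binarize a continuous position into a feature mask
#'
#' Converts each coordinate independently into a bit by comparing a fresh
#' Uniform(0,1) draw (from R's current RNG stream) against the transfer
#' function value. Two conventions are supported:
#' * `"set"` (default): `bit_j = 1` iff `u_j < T(x_j)` — stateless, used for
#'   both families.
#' * `"flip"`: the V-shaped flip rule — with probability `T(x_j)` the current
#'   bit `current[j]` is complemented, otherwise kept.
#'
#' @param position finite numeric vector (the continuous candidate).
#' @param id transfer function id.
#' @param v_rule `"set"` or `"flip"`.
#' @param current integer 0/1 vector, required for the flip rule.
#' @return Integer 0/1 vector the length of `position` (possibly all-zero;
#'   see [repair_mask()]).
#' @export
binarize <- function(position, id, v_rule = c("set", "flip"),
                     current = NULL) {
  v_rule <- match.arg(v_rule)
  if (length(position) == 0) stop("position: empty vector")
  p <- tf_value(id, position)
  u <- runif(length(position))
  if (v_rule == "set") {
    as.integer(u < p)
  } else {
    if (is.null(current) || length(current) != length(position)) {
      stop("flip rule requires a 'current' bit vector of matching length")
    }
    as.integer(xor(current == 1L, u < p))
  }
}
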