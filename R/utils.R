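#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats var sd cor median quantile setNames rnorm rbinom rmultinom
#'   rlnorm runif rpois coef vcov pnorm pchisq pt qchisq pf optimize lm glm
#'   poisson offset model.matrix resid fitted prcomp phyper p.adjust
#'   smooth.spline predict ecdf ks.test rbeta
NULL

`%||%` <- rlang::`%||%`

# draw a child seed from a user seed without exhausting 32-bit range
derive_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147483587L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}
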