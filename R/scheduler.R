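#' Trial-scheduler parameters for the mouse go/no-go task
#'
#' Two strategies are supported for choosing whether the next trial is a go or
#' a no-go trial. `"consecutive_cr"` requires at least three consecutive
#' correct rejections before a go trial may be presented. `"double_sigmoid"`
#' draws the go probability from a double sigmoidal function of the licking
#' bias measured over the last `window` trials.
#'
#' @param strategy `"double_sigmoid"` or `"consecutive_cr"`.
#' @param tau1,tau2 Inflection points of the two sigmoid terms (defaults -0.5, 0.5).
#' @param s1,s2 Slope exponents at the inflection points (defaults 16, 44).
#' @param window Number of recent trials over which the bias is computed (default 20).
#' @return A list of class `scheduler_params`.
#' @export
scheduler_params <- function(strategy = c("double_sigmoid", "consecutive_cr"),
                             tau1 = -0.5, tau2 = 0.5, s1 = 16, s2 = 44,
                             window = 20L) {
  strategy <- match.arg(strategy)
  if (window < 1) abort("`window` must be >= 1.", class = "vibropitch_domain_error")
  if (s1 <= 0 || s2 <= 0) abort("`s1` and `s2` must be positive.", class = "vibropitch_domain_error")
  structure(
    list(strategy = strategy, tau1 = tau1, tau2 = tau2, s1 = s1, s2 = s2,
         window = as.integer(window)),
    class = "scheduler_params"
  )
}

#' Go-trial probability under the double sigmoidal bias-correction model
#'
#' Evaluates
#' `P_go(bias) = 1 - 0.5 / (1 + ((bias + 1) / (tau1 - 1))^S1)
#'            - 0.5 / (1 + ((bias + 1) / (tau2 - 1))^S2)`.
#' The printed bases are negative (`tau - 1 < 0`); with the default even
#' integer exponents the value equals the magnitude of the base raised to the
#' exponent, and the implementation evaluates `|base|^S` throughout so that
#' non-default (non-even) exponents remain real-valued.
#'
#' The bias is the fraction of correct responses on no-go trials minus the
#' fraction correct on go trials over the recent window: a lick-happy animal
#' (bias near -1) gets `P_go = 0`, a lick-averse animal (bias near +1) gets
#' `P_go` near 1.
#'
#' @param bias Bias value(s) in `[-1, 1]`.
#' @param params A [scheduler_params()] object.
#' @return Go probabilities in `[0, 1]`, non-decreasing in `bias`.
#' @examples
#' go_probability(c(-1, 0, 1), scheduler_params())
#' @export
go_probability <- function(bias, params = scheduler_params()) {
  stopifnot(inherits(params, "scheduler_params"))
  if (any(!is.finite(bias)) || any(bias < -1) || any(bias > 1)) {
    abort("`bias` must lie in [-1, 1].", class = "vibropitch_domain_error")
  }
  b1 <- abs((bias + 1) / (params$tau1 - 1))
  b2 <- abs((bias + 1) / (params$tau2 - 1))
  p <- 1 - 0.5 / (1 + b1^params$s1) - 0.5 / (1 + b2^params$s2)
  pmin(pmax(p, 0), 1)
}

#' Response bias over a window of recent trials
#'
#' Bias = fraction correct on no-go trials minus fraction correct on go trials,
#' over the supplied window. A class absent from the window contributes a
#' fraction of 0. The result is clipped to `[-1, 1]`.
#'
#' @param is_go Logical vector: was each recent trial a go trial?
#' @param correct Logical vector: was the response correct?
#' @return A single bias value in `[-1, 1]`.
#' @examples
#' window_bias(rep(c(TRUE, FALSE), each = 10),
#'             c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 5), rep(FALSE, 5)))
#' @export
window_bias <- function(is_go, correct) {
  stopifnot(length(is_go) == length(correct))
  f_go <- if (any(is_go)) mean(correct[is_go]) else 0
  f_ng <- if (any(!is_go)) mean(correct[!is_go]) else 0
  min(max(f_ng - f_go, -1), 1)
}

#' Decide whether the next trial is a go trial
#'
#' Applies the configured scheduling strategy to the session history. Under
#' `"consecutive_cr"`, a go trial is only possible once the last three or more
#' responses are an unbroken run of correct rejections; when the gate is open
#' the go/no-go draw is 50/50. Under `"double_sigmoid"` the go probability is
#' [go_probability()] of the current window bias. Consumes random numbers from
#' the current RNG stream.
#'
#' @param is_go,correct Logical vectors of the full session history so far
#'   (may be empty).
#' @param params A [scheduler_params()] object.
#' @return `TRUE` for a go trial.
#' @export
next_trial_is_go <- function(is_go, correct, params = scheduler_params()) {
  stopifnot(inherits(params, "scheduler_params"))
  n <- length(is_go)
  if (params$strategy == "consecutive_cr") {
    cr <- !is_go & correct
    run <- 0L
    while (run < n && cr[n - run]) run <- run + 1L
    if (run >= 3L) return(runif(1) < 0.5)
    return(FALSE)
  }
  idx <- seq.int(max(1L, n - params$window + 1L), length.out = min(n, params$window))
  bias <- if (n == 0L) 0 else window_bias(is_go[idx], correct[idx])
  runif(1) < go_probability(bias, params)
}
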