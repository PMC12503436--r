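#' Group-relative advantages
#'
#' Standardizes raw rewards within a group of G candidate outputs:
#' `A_i = (r_i - mean) / sd`, with the population standard deviation
#' (divide by G), so for G = 2 the advantages are exactly +1/-1. A
#' degenerate group (sd at or below `std_floor`) yields all-zero
#' advantages rather than an error: uniform-reward groups contribute no
#' gradient signal.
#'
#' @param rewards Numeric vector of length >= 2.
#' @param std_floor Small non-negative constant guarding degenerate
#'   groups, default `1e-8`.
#' @return Numeric vector of advantages (mean 0; population sd 1 for
#'   non-degenerate groups).
#' @export
#' @examples
#' group_advantages(c(1, 0))
#' group_advantages(c(0.5, 0.5, 0.5))
group_advantages <- function(rewards, std_floor = 1e-8) {
  if (length(rewards) < 2) {
    stop("A reward group needs at least 2 members", call. = FALSE)
  }
  stopifnot(is.numeric(rewards), std_floor >= 0)
  mu <- mean(rewards)
  sd_pop <- sqrt(mean((rewards - mu)^2))
  if (sd_pop <= std_floor) return(rep(0, length(rewards)))
  (rewards - mu) / sd_pop
}

#' Per-output KL divergence estimator
#'
#' The unbiased low-variance estimator `x - log(x) - 1`, where `x` is
#' the reference-over-current policy probability ratio for a sampled
#' output. Non-negative everywhere, zero iff the ratio is 1 (identical
#' policies).
#'
#' @param ref_ratio Positive numeric vector of reference ratios.
#' @return Numeric vector of KL estimates.
#' @export
#' @examples
#' kl_estimate(c(1, 2, 0.5))
kl_estimate <- function(ref_ratio) {
  stopifnot(is.numeric(ref_ratio))
  if (any(ref_ratio <= 0)) {
    stop("ref_ratio must be strictly positive", call. = FALSE)
  }
  ref_ratio - log(ref_ratio) - 1
}

#' GRPO configuration
#'
#' The clip half-width and KL coefficient are deliberately mandatory:
#' the published objective leaves them unstated, so callers must be
#' explicit. Conventional PPO-family values are `clip_epsilon = 0.2`
#' and `kl_beta = 0.01`.
#'
#' @param clip_epsilon Clip half-width (> 0) of the probability-ratio
#'   surrogate.
#' @param kl_beta KL penalty coefficient (>= 0).
#' @param std_floor Degenerate-group guard for [group_advantages()].
#' @return A `grpo_config` list.
#' @export
grpo_config <- function(clip_epsilon, kl_beta, std_floor = 1e-8) {
  stopifnot(clip_epsilon > 0, kl_beta >= 0, std_floor >= 0)
  structure(
    list(clip_epsilon = clip_epsilon, kl_beta = kl_beta, std_floor = std_floor),
    class = "grpo_config"
  )
}

#' GRPO clipped-surrogate objective for one sampled group
#'
#' Computes group-relative advantages from the rewards, the per-output
#' pessimistic surrogate
#' `min(ratio * A, clip(ratio, 1 - eps, 1 + eps) * A)`, averages over
#' the group, and subtracts `kl_beta` times the mean per-output KL
#' estimate against the reference policy. Ratios are sequence-level, per
#' the objective's per-output notation; token aggregation is the
#' caller's concern.
#'
#' @param rewards Numeric vector of G raw rewards (G >= 2).
#' @param ratios Numeric vector of G current-over-old policy ratios
#'   (strictly positive).
#' @param ref_ratios Numeric vector of G reference-over-current ratios
#'   (strictly positive).
#' @param cfg A [grpo_config()].
#' @return The scalar objective value.
#' @export
#' @examples
#' grpo_objective(
#'   rewards = c(1, 0), ratios = c(1.5, 1.5), ref_ratios = c(1, 1),
#'   cfg = grpo_config(clip_epsilon = 0.2, kl_beta = 0)
#' )
grpo_objective <- function(rewards, ratios, ref_ratios, cfg) {
  stopifnot(inherits(cfg, "grpo_config"))
  g <- length(rewards)
  if (g < 2 || length(ratios) != g || length(ref_ratios) != g) {
    stop("rewards, ratios and ref_ratios must share length G >= 2",
      call. = FALSE
    )
  }
  if (any(ratios <= 0)) stop("ratios must be strictly positive", call. = FALSE)
  adv <- group_advantages(rewards, cfg$std_floor)
  clipped <- pmin(pmax(ratios, 1 - cfg$clip_epsilon), 1 + cfg$clip_epsilon)
  surrogate <- pmin(ratios * adv, clipped * adv)
  mean(surrogate) - cfg$kl_beta * mean(kl_estimate(ref_ratios))
}
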