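#' Logistic resource production rate
#'
#' `g(R) = r * R * (1 - R / K)`: density-dependent growth of the renewable
#' resource, maximal at `R = K/2` and zero at `R = 0` and `R = K`.
#'
#' @param R Resource level (resource units), `R >= 0`. Vectorized.
#' @param params A [cpr_params()] object.
#' @return Production rate (resource units per time).
#' @export
#' @examples
#' logistic_growth(50, cpr_params())  # r * K / 4 = 0.75
logistic_growth <- function(R, params) {
  check_R(R)
  params$r * R * (1 - R / params$K)
}

#' Half-saturation constant as a function of the harvest trait
#'
#' `k(theta) = k_min + k_var * theta^q_k`. A small `k` means aggressive
#' harvesting already at low resource levels (high resource affinity `1/k`);
#' raising the trait lowers the affinity and with it the current harvest.
#'
#' @param theta Harvest trait, within its bounds. Vectorized.
#' @inheritParams logistic_growth
#' @return Half-saturation constant (resource units), `>= k_min`.
#' @export
half_saturation <- function(theta, params) {
  theta <- check_theta(theta, params)
  params$k_min + params$k_var * theta^params$q_k
}

#' Group harvest rate (Monod kinetics)
#'
#' `G(R, theta) = n * h_max * R / (k(theta) + R)`: the group's aggregate
#' extraction rate saturates at `n * h_max` for abundant resource and falls
#' off with half-saturation constant `k(theta)`.
#'
#' @inheritParams half_saturation
#' @param R Resource level (resource units), `R >= 0`.
#' @return Harvest rate (resource units per time), in `[0, n * h_max)`.
#' @export
harvest_rate <- function(R, theta, params) {
  check_R(R)
  params$n * params$h_max * R / (half_saturation(theta, params) + R)
}

#' Punishment cost rate
#'
#' A Gaussian kernel in the trait, `P(theta) = p * exp(-(theta - theta_p)^2 /
#' (2 * sigma_p^2))`, active only when punishment is available in the round
#' (`params$punishment_on`). Punishment peaks at intermediate trait values:
#' highly cooperative groups need none, and egoistic groups will not pay for
#' it.
#'
#' @inheritParams half_saturation
#' @return Cost rate (fitness units per time); 0 when punishment is off.
#' @export
punishment_rate <- function(theta, params) {
  theta <- check_theta(theta, params)
  if (!params$punishment_on) return(rep(0, length(theta)))
  params$p * exp(-(theta - params$theta_p)^2 / (2 * params$sigma_p^2))
}

# Logistic decay of the discount weight over the round: a sets the speed,
# b the timing (as a fraction of T).
discount_decay <- function(t, params) {
  1 / (1 + exp(params$a * (t / params$T - params$b)))
}

#' Discount factor for future resource productivity
#'
#' `phi(theta, t) = phi_max * theta^q_phi * D(t)` with the logistic decay
#' `D(t) = 1 / (1 + exp(a * (t/T - b)))`. The weight users place on future
#' productivity grows with the trait (restraint and future orientation go
#' together) and decays as the end of the finite round approaches, because
#' there is less future left to account for.
#'
#' @inheritParams half_saturation
#' @param t Elapsed time within the round, in `[0, T]`. Vectorized
#'   (recycled against `theta`).
#' @return Discount weight in `[0, phi_max]`.
#' @export
discount_factor <- function(theta, t, params) {
  theta <- check_theta(theta, params)
  if (any(!is.finite(t)) || any(t < 0) || any(t > params$T))
    stop("t must lie in [0, T]", call. = FALSE)
  params$phi_max * theta^params$q_phi * discount_decay(t, params)
}

#' Discounted future resource productivity
#'
#' `F(R, theta, t) = phi(theta, t) * g(R)`: users estimate the future
#' productivity of the resource at the current resource level and weight it
#' by the discount factor.
#'
#' @inheritParams discount_factor
#' @param R Resource level (resource units).
#' @return Discounted future productivity (fitness units per time).
#' @export
future_productivity <- function(R, theta, t, params) {
  discount_factor(theta, t, params) * logistic_growth(R, params)
}

#' Fitness of the group's current strategy
#'
#' `W = G(R, theta) + F(R, theta, t) - P(theta)`: the sum of the current
#' harvest and the discounted future productivity, minus punishment costs.
#'
#' @inheritParams future_productivity
#' @return Fitness (fitness units per time).
#' @export
fitness <- function(R, theta, t, params) {
  harvest_rate(R, theta, params) +
    future_productivity(R, theta, t, params) -
    punishment_rate(theta, params)
}

#' Analytic fitness gradient with respect to the harvest trait
#'
#' Partial derivative of [fitness()] in `theta` at fixed `R` and `t`:
#' \deqn{\partial W/\partial\theta =
#'   -\frac{n h_{max} R\, k'(\theta)}{(k(\theta)+R)^2}
#'   + \phi_{max} q_\phi \theta^{q_\phi-1} D(t)\, g(R)
#'   + P(\theta)\frac{\theta-\theta_p}{\sigma_p^2}.}
#' The first term is the marginal loss of current harvest from more
#' restraint, the second the marginal gain of discounted future
#' productivity; their balance drives the adaptive trait dynamics.
#'
#' @inheritParams future_productivity
#' @return Gradient (fitness units per trait unit per time).
#' @export
fitness_gradient <- function(R, theta, t, params) {
  check_R(R)
  theta <- check_theta(theta, params)
  k <- half_saturation(theta, params)
  dk <- params$k_var * params$q_k *
    ifelse(theta == 0 & params$q_k == 1, 1, theta^(params$q_k - 1))
  dG <- -params$n * params$h_max * R * dk / (k + R)^2
  dtheta_pow <- if (params$q_phi == 1) rep(1, length(theta)) else {
    params$q_phi * theta^(params$q_phi - 1)
  }
  dF <- params$phi_max * dtheta_pow * discount_decay(t, params) *
    logistic_growth(R, params)
  dP <- if (params$punishment_on) {
    -punishment_rate(theta, params) * (theta - params$theta_p) / params$sigma_p^2
  } else 0
  dG + dF - dP
}

#' Right-hand side of the coupled resource/harvest/trait system
#'
#' The three ODEs: `dR/dt = g(R) - G(R, theta)` (production minus harvest),
#' `dH/dt = G(R, theta) - P(theta)` (harvest net of punishment costs), and
#' `dtheta/dt = delta * dW/dtheta` (adaptive trait dynamics proportional to
#' the fitness gradient). At a trait bound with an outward-pointing gradient
#' the trait derivative is projected to zero; at `R = 0` the resource is
#' absorbed (no growth, no harvest).
#'
#' @param state Named numeric vector or list with elements `R`, `H`, `theta`.
#' @param t Elapsed time within the round.
#' @inheritParams logistic_growth
#' @return Named numeric vector `c(dR, dH, dtheta)`.
#' @export
rhs <- function(state, t, params) {
  R <- state[["R"]]; H <- state[["H"]]; theta <- state[["theta"]]
  if (!is.finite(H)) stop("state H must be finite", call. = FALSE)
  check_R(R)
  theta <- check_theta(theta, params)
  if (R == 0) {
    g <- 0; G <- 0
  } else {
    g <- logistic_growth(R, params)
    G <- harvest_rate(R, theta, params)
  }
  P <- punishment_rate(theta, params)
  grad <- fitness_gradient(R, theta, t, params)
  dtheta <- params$delta * grad
  if ((theta <= params$theta_min && dtheta < 0) ||
      (theta >= params$theta_max && dtheta > 0)) dtheta <- 0
  c(dR = g - G, dH = G - P, dtheta = dtheta)
}
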