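# Deterministic model of Y-lineage frequency growth under culturally
# transmitted male dominance with elevated polygyny.
#
# A fixed fraction d of males is "dominant" and sires children at b times
# the rate of other males. Dominance is culturally heritable: a fraction
# tau of the next generation's dominant class is recruited from sons of
# dominant fathers (lineage-carrying sons first), the rest at random. p is
# the focal patriline's frequency among males, q the fraction of dominant
# males who carry it.

#' Dominance-model parameters
#'
#' @param d Dominant fraction of males, in (0, 1).
#' @param b Mating-success multiplier of dominant males, >= 1.
#' @param tau Father-to-son status-transmission fidelity, in \[0, 1\].
#' @param p0 Initial lineage frequency; defaults to `d * q0` (a lineage
#'   founded by the dominant class).
#' @param q0 Initial fraction of dominant males carrying the lineage.
#' @return A `dominance_model` object.
#' @export
dominance_model <- function(d, b, tau = 1, p0 = NULL, q0 = 1) {
  if (d <= 0 || d >= 1) stop_param("d must be in (0, 1)")
  if (b < 1) stop_param("b must be >= 1")
  if (tau < 0 || tau > 1) stop_param("tau must be in [0, 1]")
  if (q0 < 0 || q0 > 1) stop_param("q0 must be in [0, 1]")
  p0 <- p0 %||% (d * q0)
  if (p0 <= 0 || p0 > 1) stop_param("p0 must be in (0, 1]")
  structure(list(d = d, b = b, tau = tau, p0 = p0, q0 = q0),
            class = "dominance_model")
}

#' One generation of the dominance recursion
#'
#' Sons of dominant fathers make up `f = b d / (b d + 1 - d)` of the next
#' generation, so the lineage frequency updates to
#' `p' = (b d q + (p - d q)) / (b d + 1 - d)`. The dominant class (size
#' `d`) is then refilled: `tau * d` slots go to sons of dominant fathers
#' (lineage-carrying sons first), the remainder is drawn from the whole son
#' pool; this yields `q'`. All quantities are clamped to \[0, 1\] and the
#' `clamped` attribute records whether clamping occurred.
#'
#' @param state Numeric `c(p, q)`.
#' @param model A [dominance_model()].
#' @return `c(p, q)` for the next generation, attribute `clamped`.
#' @export
social_step <- function(state, model) {
  p <- state[1]; q <- state[2]
  d <- model$d; b <- model$b; tau <- model$tau
  denom <- b * d + 1 - d
  p_new <- (b * d * q + (p - d * q)) / denom
  f <- b * d / denom                       # sons with dominant fathers
  slots_dom <- min(tau * d, f)             # refilled from dominant-father sons
  lin_dom_sons <- f * q                    # ... of which lineage carriers
  q_new <- (min(slots_dom, lin_dom_sons) + (d - slots_dom) * p_new) / d
  clamped <- p_new < 0 || p_new > 1 || q_new < 0 || q_new > 1
  structure(c(p = clamp01(p_new), q = clamp01(q_new)), clamped = clamped)
}

#' Deterministic lineage-frequency trajectory
#'
#' Iterates [social_step()] for `T` generations from `(p0, q0)`. With
#' `tau = 1`, `q0 = 1` the closed form
#' `p_t = 1 - (1 - p0) / (b d + 1 - d)^t` holds and is available through
#' [closed_form_trajectory()].
#'
#' @param model A [dominance_model()].
#' @param T Number of generations (>= 0).
#' @return `data.frame(t, p, q)` with `T + 1` rows.
#' @export
trajectory <- function(model, T) {
  if (T < 0) stop_param("T must be >= 0")
  p <- numeric(T + 1); q <- numeric(T + 1)
  p[1] <- model$p0; q[1] <- model$q0
  state <- c(model$p0, model$q0)
  for (t in seq_len(T)) {
    state <- social_step(state, model)
    p[t + 1] <- state[1]; q[t + 1] <- state[2]
  }
  data.frame(t = 0:T, p = p, q = q)
}

#' Closed-form trajectory for tau = 1, q0 = 1
#' @inheritParams trajectory
#' @return Vector of lineage frequencies at generations `0..T`.
#' @export
closed_form_trajectory <- function(model, T) {
  if (model$tau != 1 || model$q0 != 1)
    stop_param("closed form requires tau = 1 and q0 = 1")
  denom <- model$b * model$d + 1 - model$d
  1 - (1 - model$p0) / denom^(0:T)
}

#' Smallest mating-success advantage reaching a target frequency
#'
#' Bisection on `b` in \[1, 1000\] for the smallest multiplier whose
#' `T`-generation trajectory ends at or above `target_p`.
#'
#' @param target_p Target lineage frequency (> p0).
#' @param T Horizon in generations (>= 1).
#' @param model A [dominance_model()] whose `b` slot is ignored.
#' @param tol Bisection tolerance on `b`.
#' @return The required `b` with attribute `attained`; if the target is not
#'   reachable even at `b = 1000`, returns `NA` with `attained = FALSE`.
#' @export
required_advantage <- function(target_p, T, model, tol = 1e-6) {
  if (T < 1) stop_param("T must be >= 1")
  if (target_p <= model$p0) stop_param("target_p must exceed p0")
  end_p <- function(b) {
    m <- dominance_model(model$d, b, model$tau, model$p0, model$q0)
    utils::tail(trajectory(m, T)$p, 1)
  }
  if (end_p(1000) < target_p)
    return(structure(NA_real_, attained = FALSE))
  lo <- 1; hi <- 1000
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (end_p(mid) >= target_p) hi <- mid else lo <- mid
  }
  structure(hi, attained = TRUE)
}

#' Grid of required advantages over model parameters
#'
#' Evaluates [required_advantage()] over the cross product of dominant
#' fractions, transmission fidelities and horizons.
#'
#' @param d_values,tau_values,T_values Parameter grids.
#' @param target_p Target lineage frequency.
#' @param q0 Initial dominant-carrier fraction.
#' @param p0 Initial lineage frequency (`NULL` = `d * q0` per cell).
#' @return `data.frame(d, tau, T, target_p, b_star, attained)`.
#' @export
advantage_grid <- function(d_values, tau_values, T_values, target_p,
                           q0 = 1, p0 = NULL) {
  grid <- expand.grid(d = d_values, tau = tau_values, T = T_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- dominance_model(grid$d[i], 1, grid$tau[i], p0, q0)
    b <- tryCatch(required_advantage(target_p, grid$T[i], m),
                  error = function(e) structure(NA_real_, attained = FALSE))
    data.frame(d = grid$d[i], tau = grid$tau[i], T = grid$T[i],
               target_p = target_p, b_star = as.numeric(b),
               attained = isTRUE(attr(b, "attained")))
  })
  do.call(rbind, res)
}
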