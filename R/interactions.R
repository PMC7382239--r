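#' Nematic angle between two orientations
#'
#' The interaction angle used by the collision rules: the angle between two
#' directions treated as orientations (antiparallel is equivalent to
#' parallel), `acos(|d1 . d2|)` in degrees, in [0, 90].
#'
#' @param d1,d2 unit 3-vectors.
#' @param tol tolerance on the unit-norm precondition.
#' @return angle in degrees in [0, 90].
#' @examples
#' interaction_angle(c(1, 0, 0), c(0, 1, 0))   # 90
#' interaction_angle(c(1, 0, 0), c(-1, 0, 0))  # 0 (nematic symmetry)
#' @export
interaction_angle <- function(d1, d2, tol = 1e-6) {
  d1 <- as.numeric(d1); d2 <- as.numeric(d2)
  if (abs(sqrt(sum(d1^2)) - 1) > tol || abs(sqrt(sum(d2^2)) - 1) > tol)
    stop("d1 and d2 must be unit vectors")
  acos(min(1, abs(sum(d1 * d2)))) * 180 / pi
}

#' Crossover severing survival law
#'
#' A registered crossover is tested independently with probability `p_cross`
#' at every later time step, so the probability that it has been severed
#' within `t` steps is the geometric law `1 - (1 - p_cross)^t`.  Exposed as
#' the closed-form reference that Monte-Carlo severing times are checked
#' against.
#'
#' @param p_cross per-step severing probability.
#' @param t number of elapsed steps (vectorized).
#' @return probability of severing within `t` steps.
#' @examples
#' severing_probability(0.005, 3000)  # ~0.9999997
#' @export
severing_probability <- function(p_cross, t) 1 - (1 - p_cross)^t

#' Monte-Carlo severing time of a persistent crossover
#'
#' Builds a minimal two-microtubule configuration with one registered
#' crossover inside a quiet engine (all rates zero) and applies severing
#' passes until the crossover is consumed or `max_steps` is reached.  Used
#' to check the per-step Bernoulli severing machinery against
#' [severing_probability()].
#'
#' @param p_cross per-step severing probability (> 0).
#' @param n_trials number of independent trials.
#' @param max_steps cap on the number of severing passes per trial.
#' @param seed integer base seed; trial i uses `seed + i - 1`.
#' @return integer vector of severing steps (NA where the cap was reached).
#' @export
severing_time_mc <- function(p_cross, n_trials, max_steps = 10000L, seed = 1L) {
  stopifnot(p_cross > 0)
  dom <- domain_box(4, 4, 4)
  quiet <- simulation_params(p_spont_cat = 0, p_rescue = 0, p_cat = 0,
                             p_cross = p_cross, k_nuc = 0)
  ell <- quiet$ell
  host <- cbind(seq(-1, 1, by = ell), 0, 0)
  crossing <- cbind(0.05, seq(-1, 1, by = ell), 0)
  vapply(seq_len(n_trials), function(i) {
    sim <- new_simulation(dom, quiet, seed = seed + i - 1L)
    sim_add_mt(sim, host, plus_state = "shrinking")   # static: nothing acts
    sim_add_mt(sim, crossing, plus_state = "shrinking")
    ids <- vapply(sim_state(sim)$mts, `[[`, integer(1), "id")
    mid_elem <- (nrow(crossing) - 1L) %/% 2L
    sim_register_crossover(sim, crossing_id = ids[2], crossing_element = mid_elem,
                           host_id = ids[1], host_element = mid_elem)
    engine_sever_until(sim$ptr, as.integer(max_steps))
  }, integer(1))
}
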