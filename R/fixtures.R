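#' Canonical segment-set fixtures
#'
#' Programmatic generators of 2D segment sets with known order parameters,
#' used throughout the tests and examples:
#'
#' * `parallel_array(theta0, n)`: n unit segments all at `theta0` degrees;
#'   S2 = 1, theta_S2 = theta0.
#' * `orthogonal_grid(n)`: equal numbers of unit segments at 0 and 90
#'   degrees; S2 = 0 exactly by cancellation.
#' * `isotropic(n)`: n unit segments with i.i.d. uniform orientations;
#'   E[S2] ~ sqrt(pi / (4 n)) for large n.
#' * `diagonal_square(n)`: equal numbers at +45 and -45 degrees; S2 = 0.
#'
#' @param name one of `"parallel_array"`, `"orthogonal_grid"`,
#'   `"isotropic"`, `"diagonal_square"`.
#' @param n number of segments (per arm for the grid/diagonal sets).
#' @param theta0 orientation in degrees (parallel array only).
#' @param seed integer seed (isotropic only).
#' @return an [mt_segments()] data frame.
#' @examples
#' s2_order(fixture_segments("parallel_array", 50, theta0 = 30))
#' s2_order(fixture_segments("orthogonal_grid", 10))
#' @export
fixture_segments <- function(name = c("parallel_array", "orthogonal_grid",
                                      "isotropic", "diagonal_square"),
                             n = 100L, theta0 = 0, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    parallel_array = {
      # parallel chords of a disc, all at theta0: segment ends lie on the
      # rim, so in rendered images the end-point gradients are isotropically
      # oriented instead of forming spurious straight edges
      rad <- theta0 * pi / 180
      u <- c(cos(rad), sin(rad))
      perp <- c(-sin(rad), cos(rad))
      R <- max(4, 0.25 * n)
      off <- seq(-0.85 * R, 0.85 * R, length.out = n)
      half <- sqrt(R^2 - off^2)
      mt_segments(x1 = off * perp[1] - half * u[1],
                  y1 = off * perp[2] - half * u[2],
                  x2 = off * perp[1] + half * u[1],
                  y2 = off * perp[2] + half * u[2])
    },
    orthogonal_grid = mt_segments(angle = rep(c(0, 90), each = n),
                                  weight = rep(1, 2 * n)),
    isotropic = {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
      mt_segments(angle = runif(n, -90, 90), weight = rep(1, n))
    },
    diagonal_square = mt_segments(angle = rep(c(45, -45), each = n),
                                  weight = rep(1, 2 * n)))
}

#' Simulation-state fixtures
#'
#' Builds a quiescent simulation (all rates zero) pre-loaded with an exact
#' microtubule arrangement, for cross-checking the segment and image
#' quantification paths against each other.
#'
#' @param name `"parallel_array"`: `n` straight MTs in the z = z0 plane at
#'   `theta0` degrees from +x; `"crossing_pair"`: two MTs crossing at the
#'   origin with a registered crossover at their middle elements.
#' @param domain confining domain (default 20 x 20 x 15 box).
#' @param n number of MTs.
#' @param theta0 in-plane orientation, degrees.
#' @param z0 plane height (um); defaults to just under the top face.
#' @param length MT length in um.
#' @param seed engine seed.
#' @return a list: `sim` (an `mt_simulation`) and `state` (its `sim_state`).
#' @export
fixture_state <- function(name = c("parallel_array", "crossing_pair"),
                          domain = domain_box(20, 20, 15), n = 20L,
                          theta0 = 0, z0 = NULL, length = 10, seed = 1L) {
  name <- match.arg(name)
  quiet <- simulation_params(p_spont_cat = 0, p_rescue = 0, p_cat = 0,
                             p_cross = 0, k_nuc = 0)
  sim <- new_simulation(domain, quiet, seed = seed)
  ell <- quiet$ell
  if (name == "parallel_array") {
    half_z <- switch(domain$kind, box = domain$dimensions[3] / 2,
                     sphere = domain$dimensions[1],
                     domain$dimensions[2] / 2)
    if (is.null(z0)) z0 <- half_z - 0.2
    rad <- theta0 * pi / 180
    u <- c(cos(rad), sin(rad), 0)
    nelem <- max(2L, round(length / ell))
    t <- seq(0, nelem) * ell - nelem * ell / 2
    width <- min(domain$dimensions[seq_len(min(2, base::length(domain$dimensions)))])
    offsets <- seq(-0.45, 0.45, length.out = n) * width
    perp <- c(-sin(rad), cos(rad), 0)
    maxo <- max(abs(offsets)) + 1e-9
    for (o in offsets) {
      # chord-like staggered lengths: avoids coherent end edges in renders
      half_i <- max(2L, round(nelem / 2 * sqrt(1 - 0.75 * (o / maxo)^2)))
      ti <- seq(-half_i, half_i) * ell
      v <- cbind(o * perp[1] + ti * u[1], o * perp[2] + ti * u[2], z0)
      if (all(domain_contains(domain, v))) sim_add_mt(sim, v)
    }
  } else {
    nelem <- max(4L, round(length / ell))
    t <- seq(0, nelem) * ell - nelem * ell / 2
    host <- cbind(t, 0, 0)
    crossing <- cbind(0.05, t, 0)
    sim_add_mt(sim, host, plus_state = "shrinking")
    sim_add_mt(sim, crossing, plus_state = "shrinking")
    ids <- vapply(sim_state(sim)$mts, `[[`, integer(1), "id")
    mid <- nelem %/% 2L
    sim_register_crossover(sim, ids[2], mid, ids[1], mid)
  }
  list(sim = sim, state = sim_state(sim))
}
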