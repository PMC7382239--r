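#' Simulation parameters
#'
#' Collects every rate, probability and threshold of the fixed-time-step
#' engine.  Probabilities are per time step; to convert to physical rates use
#' rate = -log(1 - P) / dt for a chosen step duration dt.  Defaults give the
#' wild-type (with-severing) condition; set `p_cross = 0` for the
#' severing-free (katanin mutant) condition.
#'
#' @param ell element length in um; every microtubule element has exactly
#'   this length.
#' @param t_steps number of time steps of a run.
#' @param p_spont_cat per-step spontaneous catastrophe probability at a
#'   growing plus end.
#' @param p_rescue per-step rescue probability at a shrinking plus end.
#' @param p_cat induced-catastrophe probability on a steep-angle collision.
#' @param p_cross per-step severing probability of a registered crossover;
#'   0.005 for the with-severing default, 0 for no severing.
#' @param alpha bundling threshold angle in degrees (collisions below it
#'   zipper onto the target orientation), in (0, 90).
#' @param k_nuc expected nucleations per step (Poisson).
#' @param nucleation_mode `"volume"` (diffuse interior nucleation, the
#'   acentrosomal default) or `"surface"` (membrane-bound).
#' @param d_contact contact radius in um; a proposed tip within this distance
#'   of a foreign element triggers collision resolution. Must be <= `ell`.
#' @param p_edge_cat catastrophe probability when a tip meets the boundary
#'   too steeply (or head-on, where no tangential continuation exists).
#' @param theta_edge incidence-angle threshold in degrees separating
#'   tangential deflection (below) from edge catastrophe (at or above).
#' @param minus_shrink_every treadmilling period: every this many steps the
#'   minus end loses one element (0 = static minus ends, the default).
#' @param r_replicates replicate count for [run_replicates()]; replicate i
#'   uses seed, seed + 1, ..., seed + R - 1.
#' @param seed base integer seed.
#' @return an object of class `simulation_params` (a validated named list).
#' @examples
#' simulation_params()                    # with-severing defaults
#' simulation_params(p_cross = 0)        # severing-free condition
#' @export
simulation_params <- function(ell = 0.2,
                              t_steps = 2000L,
                              p_spont_cat = 0.002,
                              p_rescue = 0.01,
                              p_cat = 0.5,
                              p_cross = 0.005,
                              alpha = 40,
                              k_nuc = 0.5,
                              nucleation_mode = c("volume", "surface"),
                              d_contact = 0.1,
                              p_edge_cat = 1.0,
                              theta_edge = 80,
                              minus_shrink_every = 0L,
                              r_replicates = 50L,
                              seed = 1L) {
  nucleation_mode <- match.arg(nucleation_mode)
  p <- list(ell = ell, t_steps = as.integer(t_steps),
            p_spont_cat = p_spont_cat, p_rescue = p_rescue, p_cat = p_cat,
            p_cross = p_cross, alpha = alpha, k_nuc = k_nuc,
            nucleation_mode = nucleation_mode, d_contact = d_contact,
            p_edge_cat = p_edge_cat, theta_edge = theta_edge,
            minus_shrink_every = as.integer(minus_shrink_every),
            r_replicates = as.integer(r_replicates), seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "simulation_params")
}

validate_params <- function(p) {
  probs <- c("p_spont_cat", "p_rescue", "p_cat", "p_cross", "p_edge_cat")
  for (nm in probs)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("%s must be a probability in [0, 1]", nm))
  if (!is.finite(p$ell) || p$ell <= 0) stop("ell must be > 0")
  if (p$d_contact > p$ell) stop("d_contact must be <= ell")
  if (p$alpha <= 0 || p$alpha >= 90) stop("alpha must be in (0, 90) degrees")
  if (p$k_nuc < 0) stop("k_nuc must be >= 0")
  if (p$t_steps < 0) stop("t_steps must be >= 0")
  if (p$r_replicates < 1) stop("r_replicates must be >= 1")
  invisible(p)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("<simulation_params>\n")
  cat(sprintf("  element length    %.3g um, contact radius %.3g um\n",
              x$ell, x$d_contact))
  cat(sprintf("  plus-end dynamics P_spont_cat = %.4g, P_rescue = %.4g\n",
              x$p_spont_cat, x$p_rescue))
  cat(sprintf("  collisions        alpha = %.3g deg, P_cat = %.3g\n",
              x$alpha, x$p_cat))
  cat(sprintf("  severing          P_cross = %.4g\n", x$p_cross))
  cat(sprintf("  nucleation        k_nuc = %.3g per step (%s)\n",
              x$k_nuc, x$nucleation_mode))
  cat(sprintf("  boundary          theta_edge = %.3g deg, P_edge_cat = %.3g\n",
              x$theta_edge, x$p_edge_cat))
  cat(sprintf("  run               t_steps = %d, R = %d, seed = %d\n",
              x$t_steps, x$r_replicates, x$seed))
  invisible(x)
}
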