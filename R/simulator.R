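#' Create a simulation
#'
#' Builds a fresh engine for the given domain, parameters and seed.  The
#' returned handle owns mutable engine state; [sim_step()] advances it and
#' [sim_state()] takes an immutable snapshot.  Identical (domain, params,
#' seed) triples reproduce bit-identical trajectories.
#'
#' @param domain a [confinement_domain()].
#' @param params a [simulation_params()] object.
#' @param seed integer seed for this trajectory (defaults to `params$seed`).
#' @return an object of class `mt_simulation`.
#' @examples
#' sim <- new_simulation(domain_box(40, 15, 15), simulation_params(), seed = 1)
#' sim_step(sim, 50)
#' sim_counts(sim)
#' @export
new_simulation <- function(domain, params = simulation_params(),
                           seed = params$seed) {
  stop_if_not_domain(domain)
  if (!inherits(params, "simulation_params"))
    stop("params must be a 'simulation_params' object")
  ptr <- engine_create(domain, params, as.integer(seed))
  structure(list(ptr = ptr, domain = domain, params = params,
                 seed = as.integer(seed)),
            class = "mt_simulation")
}

#' @export
print.mt_simulation <- function(x, ...) {
  cnt <- engine_counts(x$ptr)
  cat(sprintf("<mt_simulation> %s domain, step %d: %d MTs, %d elements, %d live crossovers\n",
              x$domain$kind, cnt$step, cnt$n_mts, cnt$n_elements,
              cnt$n_crossovers))
  invisible(x)
}

#' Advance a simulation
#'
#' Runs `n` synchronous time steps: nucleation, per-MT plus-end transitions
#' and growth/shrinkage in id order, optional minus-end shrinkage, then one
#' severing pass over all registered crossovers.
#'
#' @param sim an [new_simulation()] handle.
#' @param n number of steps.
#' @return the handle, invisibly (state advances in place).
#' @export
sim_step <- function(sim, n = 1L) {
  stopifnot(inherits(sim, "mt_simulation"))
  engine_run_steps(sim$ptr, as.integer(n))
  invisible(sim)
}

#' Seed a simulation with explicit microtubules
#'
#' Adds a microtubule with the given vertex chain (minus end first); used by
#' fixtures and tests to prepare exact configurations.  Consecutive vertices
#' should be `ell` apart; all vertices must lie inside the domain.
#'
#' @inheritParams sim_step
#' @param vertices n x 3 numeric matrix, n >= 2.
#' @param plus_state `"growing"` or `"shrinking"`.
#' @param minus_state `"static"` or `"shrinking"`.
#' @return the handle, invisibly.
#' @export
sim_add_mt <- function(sim, vertices, plus_state = c("growing", "shrinking"),
                       minus_state = c("static", "shrinking")) {
  stopifnot(inherits(sim, "mt_simulation"))
  plus_state <- match.arg(plus_state)
  minus_state <- match.arg(minus_state)
  engine_add_mt(sim$ptr, vertices,
                if (plus_state == "growing") 0L else 1L,
                if (minus_state == "static") 0L else 1L)
  invisible(sim)
}

#' Register a crossover record by hand
#'
#' Test/fixture access to the severing registry: marks element
#' `crossing_element` (0-based) of the crossing MT as a severable crossing
#' over `host_element` of the host MT.  During normal runs records are
#' created by the collision rules.
#'
#' @inheritParams sim_step
#' @param crossing_id,host_id MT ids (distinct).
#' @param crossing_element,host_element 0-based element indices.
#' @return the handle, invisibly.
#' @export
sim_register_crossover <- function(sim, crossing_id, crossing_element,
                                   host_id, host_element) {
  stopifnot(inherits(sim, "mt_simulation"))
  engine_register_crossover(sim$ptr, as.integer(crossing_id),
                            as.integer(crossing_element),
                            as.integer(host_id), as.integer(host_element))
  invisible(sim)
}

#' Run a severing pass only
#'
#' Applies one round of independent Bernoulli(P_cross) severing tests over
#' all live crossover records, without nucleation or tip dynamics.
#'
#' @inheritParams sim_step
#' @return the handle, invisibly.
#' @export
sim_sever_pass <- function(sim) {
  stopifnot(inherits(sim, "mt_simulation"))
  engine_sever_pass(sim$ptr)
  invisible(sim)
}

#' Snapshot of the simulation state
#'
#' @inheritParams sim_step
#' @return a `sim_state` object: `step`, `mts` (list of microtubules, each
#'   with `id`, `vertices` matrix, `plus_state`, `minus_state`,
#'   `birth_step`), `crossovers` (data frame of live records), `events`
#'   (per-step event-count matrix), plus the domain and params that produced
#'   it.
#' @export
sim_state <- function(sim) {
  stopifnot(inherits(sim, "mt_simulation"))
  st <- engine_state(sim$ptr)
  st$domain <- sim$domain
  st$params <- sim$params
  st$seed <- sim$seed
  class(st) <- "sim_state"
  st
}

#' @export
print.sim_state <- function(x, ...) {
  nel <- sum(vapply(x$mts, function(m) nrow(m$vertices) - 1L, integer(1)))
  cat(sprintf("<sim_state> step %d: %d MTs, %d elements, %d live crossovers\n",
              x$step, length(x$mts), nel, nrow(x$crossovers)))
  invisible(x)
}

#' Quick counts without a full snapshot
#' @inheritParams sim_step
#' @return list with `step`, `n_mts`, `n_elements`, `n_crossovers`.
#' @export
sim_counts <- function(sim) {
  stopifnot(inherits(sim, "mt_simulation"))
  engine_counts(sim$ptr)
}

#' Run a full trajectory
#'
#' Executes `params$t_steps` steps (or `t_steps` if given) and returns the
#' final state, optionally with intermediate snapshots.
#'
#' @inheritParams new_simulation
#' @param t_steps number of steps; defaults to `params$t_steps`.
#' @param snapshot_every 0 for final state only, otherwise a snapshot is
#'   stored every this many steps.
#' @return a list with `final` (a `sim_state`) and `snapshots` (possibly
#'   empty list of `sim_state`s).
#' @export
run_simulation <- function(domain, params = simulation_params(),
                           seed = params$seed, t_steps = params$t_steps,
                           snapshot_every = 0L) {
  sim <- new_simulation(domain, params, seed)
  snapshots <- list()
  if (snapshot_every > 0) {
    done <- 0L
    while (done < t_steps) {
      k <- min(snapshot_every, t_steps - done)
      sim_step(sim, k)
      done <- done + k
      snapshots[[length(snapshots) + 1L]] <- sim_state(sim)
    }
  } else if (t_steps > 0) {
    sim_step(sim, t_steps)
  }
  list(final = sim_state(sim), snapshots = snapshots)
}

#' Run replicate trajectories
#'
#' Replicate r uses seed `seed + r - 1`.  To keep memory bounded each final
#' state is reduced by `summarize_fn` immediately (default: the state
#' itself).
#'
#' @inheritParams run_simulation
#' @param R replicate count; defaults to `params$r_replicates`.
#' @param seed base seed; defaults to `params$seed`.
#' @param summarize_fn function applied to each final `sim_state`.
#' @return list of length R of summaries.
#' @export
run_replicates <- function(domain, params = simulation_params(),
                           R = params$r_replicates, seed = params$seed,
                           t_steps = params$t_steps,
                           summarize_fn = identity) {
  lapply(seq_len(R), function(r) {
    res <- run_simulation(domain, params, seed = seed + r - 1L,
                          t_steps = t_steps)
    summarize_fn(res$final)
  })
}
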