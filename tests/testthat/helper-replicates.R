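# Shared shape-by-severing replicate protocol used by several tests:
# rectangle 40x15x15 and square 20x20x15, P_cross in {0.005, 0},
# t_steps = 2000, R = 20 replicates per cell.  Computed once per test run
# and cached; per-replicate summaries are the mean-of-faces S2 and the
# pooled-face axis ThetaS2.

.replicate_cache <- new.env(parent = emptyenv())

replicate_protocol <- function() {
  if (!is.null(.replicate_cache$runs)) return(.replicate_cache$runs)
  cells <- list(
    rect_sever = list(domain = domain_box(40, 15, 15), p_cross = 0.005),
    rect_nosever = list(domain = domain_box(40, 15, 15), p_cross = 0),
    square_sever = list(domain = domain_box(20, 20, 15), p_cross = 0.005),
    square_nosever = list(domain = domain_box(20, 20, 15), p_cross = 0))
  out <- list()
  base_seed <- 1000L
  i <- 0L
  for (nm in names(cells)) {
    cl <- cells[[nm]]
    params <- simulation_params(p_cross = cl$p_cross, t_steps = 2000L)
    reps <- run_replicates(cl$domain, params, R = 20L,
                           seed = base_seed + i * 10000L,
                           summarize_fn = function(st) {
                             op <- state_order_parameter(st)
                             ok <- all(domain_contains(cl$domain,
                                                       all_vertices(st)))
                             list(mean_S2 = op$mean_S2,
                                  theta = op$pooled$theta_S2,
                                  confined = ok)
                           })
    out[[nm]] <- data.frame(
      cell = nm,
      replicate = seq_along(reps),
      mean_S2 = vapply(reps, `[[`, numeric(1), "mean_S2"),
      theta = vapply(reps, `[[`, numeric(1), "theta"),
      confined = vapply(reps, `[[`, logical(1), "confined"))
    i <- i + 1L
  }
  .replicate_cache$runs <- do.call(rbind, out)
  .replicate_cache$runs
}
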