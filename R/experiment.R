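#' Describe an experiment grid
#'
#' An experiment is a grid of independent cells (domain x parameter set),
#' each run for `R` replicates with its own reproducible seed stream.  The
#' default axes mirror the shape-by-severing contrasts: domains x `p_cross`
#' values; an aspect-ratio sweep can be added for rectangular boxes.
#'
#' @param name experiment name (used for the output folder).
#' @param domains named list of [confinement_domain()]s.
#' @param params base [simulation_params()].
#' @param p_cross_values numeric vector of severing probabilities to sweep.
#' @param aspect_ratios optional numeric vector; for each ratio an
#'   additional box domain is added with Lx = ratio * Ly, keeping Ly, Lz of
#'   `aspect_base` (named `aspect_<ratio>`).
#' @param aspect_base length-3 numeric: Ly, Lz and the volume-matched Ly
#'   reference box edge (defaults to 15 x 15 cross-section).
#' @param snapshot_every snapshot interval in steps (0 = final state only).
#' @param seed base seed; cell i, replicate r runs at
#'   `seed + (i - 1) * 10000 + (r - 1)`.
#' @return an `experiment_spec` object.
#' @export
experiment_spec <- function(name = "experiment",
                            domains = list(rectangle = domain_box(40, 15, 15),
                                           square = domain_box(20, 20, 15)),
                            params = simulation_params(),
                            p_cross_values = c(0.005, 0),
                            aspect_ratios = NULL,
                            aspect_base = c(15, 15),
                            snapshot_every = 0L,
                            seed = params$seed) {
  if (!is.null(aspect_ratios)) {
    for (ar in aspect_ratios) {
      nm <- sprintf("aspect_%g", ar)
      domains[[nm]] <- domain_box(ar * aspect_base[1], aspect_base[1],
                                  aspect_base[2])
    }
  }
  cells <- list()
  i <- 0L
  for (dn in names(domains)) {
    for (pc in p_cross_values) {
      i <- i + 1L
      p <- params
      p$p_cross <- pc
      cells[[i]] <- list(id = sprintf("%s_pcross%g", dn, pc),
                         domain_name = dn, domain = domains[[dn]],
                         params = p,
                         seed = as.integer(seed + (i - 1L) * 10000L))
    }
  }
  structure(list(name = name, cells = cells,
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> '%s': %d cells, base seed %d\n",
              x$name, length(x$cells), x$seed))
  for (cl in x$cells)
    cat(sprintf("  %-28s R = %d, t_steps = %d, seed %d\n", cl$id,
                cl$params$r_replicates, cl$params$t_steps, cl$seed))
  invisible(x)
}

#' Run an experiment grid to disk
#'
#' Executes every cell of an [experiment_spec()]: per replicate, runs the
#' simulation, writes the final state as legacy VTK polylines, quantifies
#' S2/ThetaS2 on both analysis faces, and appends a row to the cell's CSV.
#' Every cell folder carries the exact configuration and seed that produced
#' it (`config.toml`), and a completed cell (marked by `DONE`) is skipped on
#' rerun, so interrupted experiments resume where they stopped.  An
#' aggregate `results.csv` and a plain-text run log are written at the top
#' level.
#'
#' @param spec an [experiment_spec()].
#' @param out_dir output directory (created if missing).
#' @param shell_depth face-shell depth in um for the quantification.
#' @param keep_vtk write per-replicate VTK snapshots (default TRUE).
#' @return invisibly, the aggregate results data frame (one row per
#'   replicate x face).
#' @export
run_experiment <- function(spec, out_dir, shell_depth = 0.5,
                           keep_vtk = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  root <- file.path(out_dir, spec$name)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(root, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  logline("experiment '%s' | package mtconfine %s | base seed %d",
          spec$name, as.character(utils::packageVersion("mtconfine")),
          spec$seed)
  for (cl in spec$cells) {
    cell_dir <- file.path(root, cl$id)
    done_flag <- file.path(cell_dir, "DONE")
    if (file.exists(done_flag)) {
      logline("cell %s: already complete, skipped", cl$id)
      next
    }
    dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(run_to_config(cl$domain, cl$params),
                 file.path(cell_dir, "config.toml"))
    logline("cell %s: R = %d, t_steps = %d, seeds %d..%d", cl$id,
            cl$params$r_replicates, cl$params$t_steps, cl$seed,
            cl$seed + cl$params$r_replicates - 1L)
    rows <- list()
    for (r in seq_len(cl$params$r_replicates)) {
      res <- run_simulation(cl$domain, cl$params, seed = cl$seed + r - 1L)
      if (keep_vtk)
        write_vtk_polylines(res$final,
                            file.path(cell_dir, sprintf("replicate_%03d.vtk", r)))
      op <- state_order_parameter(res$final, shell_depth = shell_depth)
      for (fc in c("top", "bottom")) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cl$id, domain = cl$domain_name,
          p_cross = cl$params$p_cross, replicate = r,
          seed = cl$seed + r - 1L, face = fc,
          S2 = op[[fc]]$S2, theta_S2 = op[[fc]]$theta_S2,
          n_segments = op[[fc]]$n_segments,
          total_weight = op[[fc]]$total_weight,
          mean_S2 = op$mean_S2, pooled_theta = op$pooled$theta_S2)
      }
    }
    cell_df <- do.call(rbind, rows)
    write.csv(cell_df, file.path(cell_dir, "quantify.csv"), row.names = FALSE)
    writeLines(format(Sys.time()), done_flag)
    logline("cell %s: done", cl$id)
  }
  agg <- do.call(rbind, lapply(spec$cells, function(cl) {
    f <- file.path(root, cl$id, "quantify.csv")
    if (file.exists(f)) read.csv(f) else NULL
  }))
  write.csv(agg, file.path(root, "results.csv"), row.names = FALSE)
  invisible(agg)
}

#' Shape-contrast statistics from experiment results
#'
#' Convenience analysis of a [run_experiment()] results table: per-cell
#' replicate summaries (one row per replicate: mean-of-faces S2 and the
#' pooled-face axis), plus the standard contrasts -- uniformity of the
#' per-replicate axes per cell, and one-sided permutation tests of mean S2
#' between cells.
#'
#' @param results data frame from [run_experiment()] (or its `results.csv`).
#' @param n_rep,n_perm,seed passed to the underlying tests.
#' @return list: `replicates` (data frame), `uniformity` (per-cell list),
#'   `s2_contrasts` (data frame of pairwise one-sided permutation tests).
#' @export
experiment_stats <- function(results, n_rep = 99L, n_perm = 9999L, seed = 1L) {
  key <- unique(results[, c("cell", "replicate")])
  reps <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sub <- results[results$cell == key$cell[i] &
                     results$replicate == key$replicate[i], ]
    data.frame(cell = key$cell[i], replicate = key$replicate[i],
               domain = sub$domain[1], p_cross = sub$p_cross[1],
               mean_S2 = sub$mean_S2[1], theta = sub$pooled_theta[1])
  }))
  cells <- unique(reps$cell)
  uniformity <- lapply(setNames(cells, cells), function(cl) {
    th <- reps$theta[reps$cell == cl]
    if (sum(is.finite(th)) >= 5)
      uniformity_test(th, n_rep = n_rep, seed = seed) else NULL
  })
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  s2_contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    a <- reps$mean_S2[reps$cell == pr[1]]
    b <- reps$mean_S2[reps$cell == pr[2]]
    pt <- perm_test_mean_greater(a, b, n_perm = n_perm, seed = seed)
    data.frame(greater = pr[1], lesser = pr[2],
               mean_diff = pt$observed, p_value = pt$p_value)
  }))
  list(replicates = reps, uniformity = uniformity,
       s2_contrasts = s2_contrasts)
}
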