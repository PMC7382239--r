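test_that("nucleation count over many steps matches Poisson moments", {
  p <- quiet_params(k_nuc = 2, p_spont_cat = 1)  # nucleate, then stall
  # p_spont_cat = 1 flips every new MT to shrinking on its next step, so MTs
  # die quickly and the engine stays small; the event log still counts births.
  sim <- new_simulation(domain_box(20, 20, 15), p, seed = 11)
  sim_step(sim, 1000)
  st <- sim_state(sim)
  n <- sum(st$events[, "nucleated"])
  expect_lt(abs(n - 2000), 4 * sqrt(2000))
  expect_equal(st$step, 1000)
})

test_that("zero nucleation leaves an empty engine empty", {
  sim <- new_simulation(domain_box(20, 20, 15), quiet_params(), seed = 5)
  sim_step(sim, 100)
  expect_equal(sim_counts(sim)$n_mts, 0)
})

test_that("surface-mode nucleation seeds minus ends on the boundary", {
  p <- quiet_params(k_nuc = 5, nucleation_mode = "surface")
  sim <- new_simulation(domain_sphere(10), p, seed = 2)
  sim_step(sim, 10)
  st <- sim_state(sim)
  expect_gt(length(st$mts), 10)
  # minus ends never move in this configuration: all sit on the surface
  r0 <- vapply(st$mts, function(m) sqrt(sum(m$vertices[1, ]^2)), numeric(1))
  expect_true(all(abs(r0 - 10) < 1e-6))
  # and the whole population stays confined
  expect_true(all(domain_contains(domain_sphere(10), all_vertices(st))))
})

test_that("growth adds exactly one element of length ell per step", {
  p <- quiet_params()
  sim <- new_simulation(domain_box(20, 20, 15), p, seed = 1)
  # two far-apart MTs growing along +x and +y
  sim_add_mt(sim, cbind(seq(-2, -1.8, by = 0.2), -5, 0))
  sim_add_mt(sim, cbind(5, seq(-2, -1.8, by = 0.2), 3))
  len0 <- total_length(sim_state(sim))
  sim_step(sim, 25)
  st <- sim_state(sim)
  expect_equal(total_length(st), len0 + 25 * 2 * p$ell, tolerance = 1e-9)
  expect_true(all(abs(element_lengths(st) - p$ell) < 1e-9))
})

test_that("spontaneous catastrophe timing follows the geometric law", {
  # lone MTs, P_spont_cat = 0.01, no rescue: growth-phase lifetime mean 1/p
  p <- quiet_params(p_spont_cat = 0.01, k_nuc = 0.2)
  sim <- new_simulation(domain_box(40, 40, 40), p, seed = 9)
  sim_step(sim, 1500)
  ev <- sim_state(sim)$events
  # exposure: each growing MT contributes one Bernoulli trial per step
  trials <- sum(ev[, "extended"] + ev[, "bundled"] + ev[, "crossover"] +
                  ev[, "boundary_deflected"] + ev[, "spontaneous_catastrophe"])
  hits <- sum(ev[, "spontaneous_catastrophe"])
  rate <- hits / trials
  se <- sqrt(0.01 * 0.99 / trials)
  expect_lt(abs(rate - 0.01), 4 * se)
})

test_that("forced rescue converts a shrinking tip without length change", {
  p <- quiet_params(p_rescue = 1)
  sim <- new_simulation(domain_box(20, 20, 15), p, seed = 1)
  sim_add_mt(sim, cbind(seq(-1, 0, by = 0.2), 0, 0), plus_state = "shrinking")
  len0 <- total_length(sim_state(sim))
  sim_step(sim, 1)
  st <- sim_state(sim)
  expect_equal(st$mts[[1]]$plus_state, "growing")
  expect_equal(total_length(st), len0, tolerance = 1e-12)
})

test_that("a shrinking MT loses one element per step and dies at zero", {
  sim <- new_simulation(domain_box(20, 20, 15), quiet_params(), seed = 1)
  sim_add_mt(sim, cbind(seq(-0.4, 0.4, by = 0.2), 0, 0),
             plus_state = "shrinking")   # 4 elements
  sim_step(sim, 1)
  expect_equal(sim_counts(sim)$n_elements, 3)
  sim_step(sim, 2)
  expect_equal(sim_counts(sim)$n_elements, 1)
  sim_step(sim, 1)
  expect_equal(sim_counts(sim)$n_mts, 0)   # died
})

test_that("identical seeds give bit-identical trajectories", {
  p <- simulation_params(t_steps = 200)
  r1 <- run_simulation(domain_box(20, 20, 15), p, seed = 123)
  r2 <- run_simulation(domain_box(20, 20, 15), p, seed = 123)
  v1 <- all_vertices(r1$final)
  v2 <- all_vertices(r2$final)
  expect_identical(v1, v2)
  expect_identical(r1$final$events, r2$final$events)
  r3 <- run_simulation(domain_box(20, 20, 15), p, seed = 124)
  expect_false(isTRUE(all.equal(all_vertices(r3$final), v1)))
})

test_that("confinement and element length hold over full interacting runs", {
  for (dom in list(domain_box(20, 20, 15), domain_sphere(8))) {
    res <- run_simulation(dom, simulation_params(t_steps = 400), seed = 21)
    v <- all_vertices(res$final)
    expect_true(all(domain_contains(dom, v)))
    expect_true(all(abs(element_lengths(res$final) - 0.2) < 1e-9))
  }
})

test_that("boundary hits deflect below the edge threshold and kill above it", {
  # grazing approach at ~10 degrees: deflected, direction turns tangential
  p <- quiet_params(theta_edge = 45)
  sim <- new_simulation(domain_box(40, 15, 15), p, seed = 1)
  rad <- 10 * pi / 180
  # build an MT aimed at the +y face at 10 degrees incidence
  d <- c(cos(rad), sin(rad), 0)  # incidence vs face normal (0,1,0) is 10 deg
  tip0 <- c(0, 7.5 - 0.01, 0)
  v <- rbind(tip0 - 0.2 * d, tip0)
  sim_add_mt(sim, v)
  sim_step(sim, 1)
  st <- sim_state(sim)
  expect_equal(st$mts[[1]]$plus_state, "growing")
  expect_equal(sum(st$events[, "boundary_deflected"]), 1)
  newdir <- diff(tail(st$mts[[1]]$vertices, 2))
  expect_equal(abs(newdir[2]) < 1e-9, TRUE)   # tangential: no +y component

  # head-on approach with P_edge_cat = 1: boundary catastrophe
  sim2 <- new_simulation(domain_box(40, 15, 15), quiet_params(), seed = 1)
  sim_add_mt(sim2, rbind(c(0, 7.15, 0), c(0, 7.35, 0)))
  sim_step(sim2, 1)
  st2 <- sim_state(sim2)
  expect_equal(st2$mts[[1]]$plus_state, "shrinking")
  expect_equal(sum(st2$events[, "boundary_catastrophe"]), 1)
})

test_that("tips slide along curved boundaries keeping exact element length", {
  p <- quiet_params(theta_edge = 89)
  sim <- new_simulation(domain_sphere(5), p, seed = 1)
  v1 <- c(4.3, 0, 0)
  sim_add_mt(sim, rbind(v1, v1 + 0.2 * c(cos(70 * pi / 180),
                                         sin(70 * pi / 180), 0)))
  sim_step(sim, 60)
  st <- sim_state(sim)
  expect_true(all(abs(element_lengths(st) - 0.2) < 1e-9))
  expect_true(all(domain_contains(domain_sphere(5), all_vertices(st))))
  expect_equal(st$mts[[1]]$plus_state, "growing")
  # the tip ends up tracking the boundary shell
  v <- st$mts[[1]]$vertices
  tipr <- sqrt(sum(v[nrow(v), ]^2))
  expect_gt(tipr, 4.8)
})
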