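test_that("interaction angle is nematic and bounded by 90 degrees", {
  expect_equal(interaction_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(interaction_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(interaction_angle(c(1, 0, 0), c(-1, 0, 0)), 0)
  d2 <- c(cos(20 * pi / 180), sin(20 * pi / 180), 0)
  expect_equal(interaction_angle(c(1, 0, 0), d2), 20, tolerance = 1e-9)
  expect_error(interaction_angle(c(2, 0, 0), c(1, 0, 0)), "unit")
})

# build a collision scene: a host MT along x through the origin, and a
# crossing MT approaching the origin in the z = 0 plane at angle theta
collision_sim <- function(theta_deg, params, seed = 1) {
  sim <- new_simulation(domain_box(20, 20, 15), params, seed = seed)
  host <- cbind(seq(-2, 2, by = 0.2), 0.05, 0)
  sim_add_mt(sim, host, plus_state = "shrinking")
  rad <- theta_deg * pi / 180
  d <- c(cos(rad), sin(rad), 0)
  tip <- c(0, -0.1, 0)   # next step crosses the host line
  v <- rbind(tip - 0.4 * d, tip - 0.2 * d, tip)
  sim_add_mt(sim, v, plus_state = "growing")
  sim
}

test_that("shallow collisions bundle with the minimal-turn sign", {
  p <- quiet_params(p_rescue = 0)   # alpha = 40
  sim2 <- collision_sim(20, p)      # 20 deg vs host at 0 deg: shallow
  sim_step(sim2, 1)
  st <- sim_state(sim2)
  ev <- st$events
  expect_equal(sum(ev[, "bundled"]), 1)
  mt <- st$mts[[2]]
  nd <- diff(tail(mt$vertices, 2))
  nd <- nd / sqrt(sum(nd^2))
  # adopted host orientation with the sign closest to the old heading (+x)
  expect_equal(as.numeric(nd), c(1, 0, 0), tolerance = 1e-9)
})

test_that("steep collisions cause induced catastrophe when forced", {
  p <- quiet_params(p_cat = 1, p_rescue = 0)
  sim <- collision_sim(70, p)
  sim_step(sim, 1)
  st <- sim_state(sim)
  expect_equal(sum(st$events[, "induced_catastrophe"]), 1)
  expect_equal(st$mts[[2]]$plus_state, "shrinking")
  expect_equal(nrow(st$crossovers), 0)
})

test_that("steep collisions cross over and register a severable record", {
  p <- quiet_params(p_cat = 0, p_rescue = 0)
  sim <- collision_sim(70, p)
  nc0 <- nrow(sim_state(sim)$mts[[2]]$vertices)
  sim_step(sim, 1)
  st <- sim_state(sim)
  expect_equal(sum(st$events[, "crossover"]), 1)
  expect_equal(nrow(st$crossovers), 1)
  rec <- st$crossovers
  expect_equal(rec$crossing_mt_id, st$mts[[2]]$id)
  expect_equal(rec$host_mt_id, st$mts[[1]]$id)
  # the crossing MT grew straight through the host
  expect_equal(nrow(st$mts[[2]]$vertices), nc0 + 1)
  # the record points at the newly added (last) element of the crossing MT
  expect_equal(rec$crossing_element_index, nrow(st$mts[[2]]$vertices) - 2L)
})

test_that("forced severing splits 10 elements at element 4 into 4 + 6", {
  p <- quiet_params(p_cross = 1)
  sim <- new_simulation(domain_box(20, 20, 15), p, seed = 1)
  host <- cbind(seq(-1, 1, by = 0.2), 0, 0)            # 10 elements
  crossing <- cbind(0.05, seq(-1, 1, by = 0.2), 0)     # 10 elements
  sim_add_mt(sim, host, plus_state = "shrinking")
  sim_add_mt(sim, crossing, plus_state = "growing")
  ids <- vapply(sim_state(sim)$mts, `[[`, integer(1), "id")
  sim_register_crossover(sim, ids[2], 4, ids[1], 5)
  n0 <- sim_counts(sim)$n_elements
  sim_sever_pass(sim)
  st <- sim_state(sim)
  expect_equal(length(st$mts), 3)
  expect_equal(sim_counts(sim)$n_elements, n0)   # elements conserved
  frags <- Filter(function(m) m$id != ids[1], st$mts)
  sizes <- sort(vapply(frags, function(m) nrow(m$vertices) - 1L, integer(1)))
  expect_equal(sizes, c(4L, 6L))
  # proximal fragment: plus end shrinking; distal: minus end shrinking,
  # plus state preserved
  prox <- Filter(function(m) m$id == ids[2], frags)[[1]]
  dist <- Filter(function(m) m$id != ids[2], frags)[[1]]
  expect_equal(prox$plus_state, "shrinking")
  expect_equal(dist$minus_state, "shrinking")
  expect_equal(dist$plus_state, "growing")
  # host untouched
  hostmt <- Filter(function(m) m$id == ids[1], st$mts)[[1]]
  expect_equal(nrow(hostmt$vertices) - 1L, 10L)
  expect_equal(nrow(st$crossovers), 0)   # record consumed
})

test_that("P_cross = 0 never severs and leaves the registry intact", {
  fix <- fixture_state("crossing_pair")
  sim <- fix$sim
  for (i in 1:50) sim_sever_pass(sim)
  expect_equal(sim_counts(sim)$n_crossovers, 1)
  expect_equal(length(sim_state(sim)$mts), 2)
})

test_that("records are dropped when their elements depolymerize", {
  p <- quiet_params()
  sim <- new_simulation(domain_box(20, 20, 15), p, seed = 1)
  host <- cbind(seq(-1, 1, by = 0.2), 0, 0)
  crossing <- cbind(0.05, seq(-1, 1, by = 0.2), 0)
  sim_add_mt(sim, host, plus_state = "shrinking")
  sim_add_mt(sim, crossing, plus_state = "shrinking")
  ids <- vapply(sim_state(sim)$mts, `[[`, integer(1), "id")
  # record at the crossing MT's last element: one shrink step removes it
  sim_register_crossover(sim, ids[2], 9, ids[1], 5)
  expect_equal(sim_counts(sim)$n_crossovers, 1)
  sim_step(sim, 1)
  expect_equal(sim_counts(sim)$n_crossovers, 0)
})

test_that("Monte-Carlo severing times follow the geometric law", {
  # small-scale distribution check (the full-scale one runs in acceptance)
  p_cross <- 0.05
  times <- severing_time_mc(p_cross, n_trials = 2000, max_steps = 2000,
                            seed = 42)
  expect_true(all(is.finite(times)))
  # mean of the geometric law (support 1, 2, ...) is 1/p
  se <- sqrt((1 - p_cross) / p_cross^2 / 2000)
  expect_lt(abs(mean(times) - 1 / p_cross), 3 * se)
  # survival at t: (1-p)^t
  for (t in c(5, 20, 50)) {
    emp <- mean(times > t)
    expected <- (1 - p_cross)^t
    se_t <- sqrt(expected * (1 - expected) / 2000)
    expect_lt(abs(emp - expected), 3.5 * se_t)
  }
})

test_that("severing preserves total element count across a dense run", {
  p <- simulation_params(t_steps = 300, p_cross = 0.05)
  res <- run_simulation(domain_box(20, 20, 15), p, seed = 17)
  ev <- res$final$events
  expect_gt(sum(ev[, "severed"]), 0)
  # every live record must reference valid elements
  st <- res$final
  if (nrow(st$crossovers) > 0) {
    ids <- vapply(st$mts, `[[`, integer(1), "id")
    nelem <- vapply(st$mts, function(m) nrow(m$vertices) - 1L, integer(1))
    for (k in seq_len(nrow(st$crossovers))) {
      ci <- match(st$crossovers$crossing_mt_id[k], ids)
      hi <- match(st$crossovers$host_mt_id[k], ids)
      expect_false(is.na(ci))
      expect_false(is.na(hi))
      expect_lt(st$crossovers$crossing_element_index[k], nelem[ci])
      expect_lt(st$crossovers$host_element_index[k], nelem[hi])
      expect_true(st$crossovers$crossing_mt_id[k] !=
                    st$crossovers$host_mt_id[k])
    }
  }
})
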