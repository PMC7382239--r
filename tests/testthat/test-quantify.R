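test_that("s2_order reproduces hand-derived cases", {
  expect_equal(s2_order(mt_segments(angle = rep(30, 5)))$S2, 1, tolerance = 1e-12)
  expect_equal(s2_order(mt_segments(angle = rep(30, 5)))$theta_S2, 30,
               tolerance = 1e-9)
  two <- mt_segments(angle = c(0, 90), weight = c(1, 1))
  expect_lt(s2_order(two)$S2, 1e-12)
  expect_true(s2_order(two)$undefined)
  three <- mt_segments(angle = c(0, 0, 90), weight = c(1, 1, 1))
  r <- s2_order(three)
  expect_equal(r$S2, 1 / 3, tolerance = 1e-12)
  expect_equal(r$theta_S2, 0, tolerance = 1e-9)
  # empty input flags undefined
  e <- s2_order(mt_segments(angle = numeric(0)))
  expect_true(e$undefined)
  expect_equal(e$n_segments, 0L)
})

test_that("s2_order equals the brute-force nematic average on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    ang <- runif(n, -90, 90)
    w <- runif(n, 0.1, 3)
    got <- s2_order(mt_segments(angle = ang, weight = w))
    want <- s2_oracle(ang, w)
    expect_equal(got$S2, want$S2, tolerance = 1e-12)
    if (got$S2 > 1e-8)
      expect_equal(got$theta_S2, want$theta, tolerance = 1e-9)
  }
})

test_that("s2_order is invariant to ordering, flips, rotation and rescaling", {
  set.seed(7)
  ang <- runif(25, -90, 90); w <- runif(25, 0.5, 2)
  base <- s2_order(mt_segments(angle = ang, weight = w))
  perm <- sample(25)
  expect_equal(s2_order(mt_segments(angle = ang[perm], weight = w[perm]))$S2,
               base$S2, tolerance = 1e-12)
  # per-segment 180-degree flips
  flip <- ang + 180 * rbinom(25, 1, 0.5)
  r <- s2_order(mt_segments(angle = flip, weight = w))
  expect_equal(r$S2, base$S2, tolerance = 1e-12)
  expect_equal(r$theta_S2, base$theta_S2, tolerance = 1e-9)
  # global rotation rotates the axis by the same amount
  rot <- s2_order(mt_segments(angle = ang + 25, weight = w))
  expect_equal(rot$S2, base$S2, tolerance = 1e-12)
  dtheta <- (rot$theta_S2 - base$theta_S2 - 25) %% 180
  expect_true(min(dtheta, 180 - dtheta) < 1e-9)
  # uniform weight rescaling
  expect_equal(s2_order(mt_segments(angle = ang, weight = 7 * w))$S2,
               base$S2, tolerance = 1e-12)
})

test_that("canonical fixtures have their documented order parameters", {
  expect_equal(s2_order(fixture_segments("parallel_array", 50, theta0 = 0))$S2,
               1, tolerance = 1e-12)
  expect_equal(s2_order(fixture_segments("orthogonal_grid", 33))$S2, 0)
  expect_equal(s2_order(fixture_segments("diagonal_square", 20))$S2, 0)
  s2s <- vapply(1:20, function(s)
    s2_order(fixture_segments("isotropic", 10000, seed = s))$S2, numeric(1))
  # E[S2] ~ sqrt(pi / (4 n)) for uniform angles; allow generous headroom
  expect_lt(mean(s2s), 0.03)
})

test_that("face projection selects the shell and weights by projected length", {
  dom <- domain_box(40, 15, 15)
  faces <- analysis_faces(dom)
  sim <- new_simulation(dom, quiet_params(), seed = 1)
  # one element just under the top face
  sim_add_mt(sim, rbind(c(0, 0, 7.4), c(0.2, 0, 7.4)))
  st <- sim_state(sim)
  top <- face_projection(st, faces$top, 0.5)
  bottom <- face_projection(st, faces$bottom, 0.5)
  expect_equal(nrow(top), 1)
  expect_equal(nrow(bottom), 0)
  expect_equal(top$weight, 0.2, tolerance = 1e-12)
  expect_equal(top$angle, 0, tolerance = 1e-9)

  # element perpendicular to the face projects to zero weight
  sim2 <- new_simulation(dom, quiet_params(), seed = 1)
  sim2 <- sim_add_mt(sim2, rbind(c(1, 1, 7.0), c(1, 1, 7.2)))
  seg <- face_projection(sim_state(sim2), faces$top, 0.5)
  expect_equal(seg$weight, 0, tolerance = 1e-12)

  # element at 45 degrees to the face: projected weight ell / sqrt(2)
  sim3 <- new_simulation(dom, quiet_params(), seed = 1)
  h <- 0.2 / sqrt(2)
  sim3 <- sim_add_mt(sim3, rbind(c(0, 0, 7.2), c(h, 0, 7.2 + h)))
  seg3 <- face_projection(sim_state(sim3), faces$top, 0.5)
  expect_equal(seg3$weight, 0.2 / sqrt(2), tolerance = 1e-9)
})

test_that("image nematic tensor recovers stripes, noise and flat images", {
  # horizontal stripes: intensity varies along y only -> fibrils along x
  img <- outer(1:64, 1:64, function(i, j) sin(2 * pi * i / 8))
  r <- nematic_tensor_image(img)
  expect_equal(r$angle, 0, tolerance = 1e-6)
  expect_gt(r$anisotropy, 0.99)
  # vertical stripes -> fibrils along y (90 degrees)
  imgv <- outer(1:64, 1:64, function(i, j) sin(2 * pi * j / 8))
  rv <- nematic_tensor_image(imgv)
  expect_equal(abs(rv$angle), 90, tolerance = 1e-6)
  # i.i.d. noise: anisotropy near zero over repeated draws
  an <- vapply(1:20, function(s) {
    set.seed(s)
    nematic_tensor_image(matrix(runif(256 * 256), 256))$anisotropy
  }, numeric(1))
  expect_lt(max(an), 0.05)
  # constant image: flat flag
  expect_true(nematic_tensor_image(matrix(1, 32, 32))$flat)
})

test_that("image anisotropy is invariant to affine intensity rescaling", {
  set.seed(3)
  segs <- fixture_segments("parallel_array", 12, theta0 = 25)
  img <- render_image(segs, pixel_size = 0.05)
  r1 <- nematic_tensor_image(img)
  r2 <- nematic_tensor_image(3.7 * img + 11)
  expect_equal(r1$anisotropy, r2$anisotropy, tolerance = 1e-9)
  expect_equal(r1$angle, r2$angle, tolerance = 1e-9)
})

test_that("roi restriction analyses only the selected polygon", {
  # left half striped, right half flat: roi over the striped half
  img <- matrix(0, 64, 64)
  img[, 1:32] <- outer(1:64, 1:32, function(i, j) sin(2 * pi * i / 8))
  roi <- cbind(c(2, 30, 30, 2), c(2, 2, 63, 63))
  r <- nematic_tensor_image(img, roi = roi)
  expect_gt(r$anisotropy, 0.9)
  expect_equal(r$angle, 0, tolerance = 0.5)
})

test_that("segment and image paths agree on rendered parallel arrays", {
  # pixels at a third of the PSF sigma: adequate sampling for the
  # central-difference gradients (coarser grids bias angles diagonal-ward)
  for (theta0 in c(0, 30, 60)) {
    segs <- fixture_segments("parallel_array", 32, theta0 = theta0)
    op <- s2_order(segs)
    img <- render_image(segs, pixel_size = 0.05)
    r <- nematic_tensor_image(img)
    d <- abs(r$angle - op$theta_S2) %% 180
    expect_lt(min(d, 180 - d), 2)
    expect_gt(r$anisotropy, 0.9)
    expect_gt(op$S2, 0.999)
  }
})

test_that("rendering a state matches the segment path and handles empties", {
  empty <- mt_segments(x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0))
  expect_true(all(render_image(empty) == 0))
  fix <- fixture_state("parallel_array", n = 14, theta0 = 30)
  img <- render_image(fix$state, face = "top", pixel_size = 0.05)
  r <- nematic_tensor_image(img)
  d <- abs(r$angle - 30) %% 180
  expect_lt(min(d, 180 - d), 2)
  # Poisson noise is reproducible given the seed and preserves determinism
  segs <- fixture_segments("parallel_array", 5, theta0 = 0)
  n1 <- render_image(segs, noise = "poisson", seed = 9)
  n2 <- render_image(segs, noise = "poisson", seed = 9)
  expect_identical(n1, n2)
})

test_that("state_order_parameter averages faces by weight", {
  dom <- domain_box(20, 20, 15)
  sim <- new_simulation(dom, quiet_params(), seed = 1)
  # aligned segments near the top, orthogonal pair near the bottom
  sim_add_mt(sim, rbind(c(0, 0, 7.4), c(0.2, 0, 7.4)))
  sim_add_mt(sim, rbind(c(1, 0, 7.4), c(1.2, 0, 7.4)))
  sim_add_mt(sim, rbind(c(0, 0, -7.4), c(0.2, 0, -7.4)))
  sim_add_mt(sim, rbind(c(1, 0, -7.4), c(1, 0.2, -7.4)))
  op <- state_order_parameter(sim_state(sim))
  expect_equal(op$top$S2, 1, tolerance = 1e-12)
  expect_equal(op$bottom$S2, 0, tolerance = 1e-12)
  expect_equal(op$mean_S2, 0.5, tolerance = 1e-12)
  expect_equal(op$top$theta_S2, 0, tolerance = 1e-9)
})
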