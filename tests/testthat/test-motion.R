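test_that("strain tensor algebra matches closed forms", {
  I2 <- diag(2)
  # dU = 0 -> F = I -> E = 0
  expect_equal(deformation_gradient(matrix(0, 2, 2)), I2)
  expect_equal(eulerian_strain(I2), matrix(0, 2, 2))
  # uniform scaling: dU = (1 - 1/a) I -> F = a I -> E = (1 - a^-2)/2 I
  a <- 1.1
  dU <- (1 - 1 / a) * I2
  Fm <- deformation_gradient(dU)
  expect_equal(Fm, a * I2, tolerance = 1e-12)
  expect_equal(eulerian_strain(Fm), 0.5 * (1 - a^-2) * I2, tolerance = 1e-12)
  expect_equal(eulerian_strain(0.8 * I2), -0.28125 * I2, tolerance = 1e-12)
  # rotations are strain-free
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(max(abs(eulerian_strain(R))), 1e-12)
  # singular guard
  expect_error(deformation_gradient(I2), "singular")
})

test_that("polar projection follows the radial/circumferential convention", {
  E <- 0.07 * diag(2)
  pr <- polar_strain(E, c(10, 30), c(20, 20))
  expect_equal(unname(pr), c(0.07, 0.07))   # isotropy
  # point due east: radial = col axis
  E2 <- diag(c(0.3, -0.1))
  pr2 <- polar_strain(E2, c(20, 35), c(20, 20))
  expect_equal(pr2[["Err"]], -0.1)
  expect_equal(pr2[["Ecc"]], 0.3)
  # pure shear at 45 degrees
  s <- 0.12
  E3 <- matrix(c(0, s, s, 0), 2, 2)
  pr3 <- polar_strain(E3, c(25, 25), c(20, 20))
  expect_equal(pr3[["Err"]], s, tolerance = 1e-12)
  expect_equal(pr3[["Ecc"]], -s, tolerance = 1e-12)
  expect_error(polar_strain(E, c(20, 20), c(20, 20)), "centroid")
})

test_that("AHA sectors are assigned counter-clockwise and half-open", {
  ctr <- c(0, 0)
  ang <- (90 + c(30, 90, 150, 210, 270, 330)) * pi / 180
  pts <- cbind(-sin(ang), cos(ang)) * 10
  lab <- assign_aha_regions(pts, ctr)
  expect_equal(as.character(lab),
               c("Anterior", "Anteroseptal", "Inferoseptal",
                 "Inferior", "Inferolateral", "Anterolateral"))
  # boundary point belongs to the sector it begins (90 deg = Anterior start)
  lab_b <- assign_aha_regions(matrix(c(-5, 0), 1, 2), ctr, reference_angle = 90)
  expect_equal(as.character(lab_b), "Anterior")
  # uniform angles split 100 per region
  th <- (seq_len(600) - 0.5) / 600 * 2 * pi
  labs <- assign_aha_regions(cbind(-sin(th), cos(th)) * 7, ctr)
  expect_true(all(table(labs) == 100))
})

test_that("displacement gradients recover uniform-field closed forms", {
  set.seed(21)
  p0 <- cbind(runif(80, 10, 50), runif(80, 10, 50))
  T_ <- 3
  mk_traj <- function(f) {
    pos <- array(0, c(nrow(p0), 2, T_))
    pos[, , 1] <- p0
    for (t in 2:T_) pos[, , t] <- f(p0, t)
    pos
  }
  # uniform translation: dU = 0
  tr <- mk_traj(function(p, t) sweep(p, 2, c(3 * t, -2 * t), "+"))
  dg <- displacement_gradient(tr, 2, radius = 12)
  expect_true(all(dg$valid))
  expect_lt(max(abs(dg$dU)), 1e-9)
  # uniform scaling about the origin: dU = (1 - 1/a) I in current coords
  a <- 1.1
  sc <- mk_traj(function(p, t) if (t == 3) a * p else p)
  dg2 <- displacement_gradient(sc, 2, radius = 12)
  target <- (1 - 1 / a) * diag(2)
  for (i in which(dg2$valid))
    expect_equal(dg2$dU[, , i], target, tolerance = 1e-6)
  # rigid rotation: dU = I - R(-theta), strain-free
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ro <- mk_traj(function(p, t) if (t == 3) p %*% t(R) else p)
  dg3 <- displacement_gradient(ro, 2, radius = 12)
  i <- which(dg3$valid)[1]
  E <- eulerian_strain(deformation_gradient(dg3$dU[, , i]))
  expect_lt(max(abs(E)), 1e-9)
  # insufficient neighbours are flagged, not errors
  lone <- mk_traj(function(p, t) p)
  lone[1, , ] <- 500
  dg4 <- displacement_gradient(lone, 2, radius = 8)
  expect_false(dg4$valid[1])
})

test_that("tracking identical frames leaves trajectories constant", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  seeds <- phantom_wall_points(cfg, radial_step = 3, angular_step_deg = 30)
  traj <- htm_track(list(f0, f0, f0), seeds)
  expect_equal(traj$n_pairs, 2)
  expect_lt(max(abs(traj$positions[, , 2] - seeds)), 1e-9)
  expect_lt(max(abs(traj$positions[, , 3] - seeds)), 1e-9)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), nrow(seeds) * 3)
  expect_error(htm_track(list(f0), seeds), "at least 2 frames")
  expect_error(htm_track(list(f0, f0), matrix(c(-5, 2), 1, 2)),
               "inside frame 0")
})

test_that("regional strain is zero for identity motion and symmetric overall", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  seeds <- phantom_wall_points(cfg, radial_step = 2, angular_step_deg = 15)
  traj <- htm_track(list(f0, f0, f0), seeds)
  rs <- regional_strain(traj, centroid = cfg$center, radius = 6)
  expect_s3_class(rs, "regional_strain")
  expect_equal(nrow(rs), 3 * 6)
  expect_true(all(abs(rs$Ecc) < 1e-8, na.rm = TRUE))
  expect_true(all(abs(rs$Err) < 1e-8, na.rm = TRUE))
  expect_true(all(rs$Ecc[rs$frame == 0] == 0))
  # per-point tensors stay symmetric through the pipeline (frame > 0)
  ps <- point_strain(traj, 2, cfg$center, radius = 6)
  expect_true(all(ps$valid))
  # symmetry is structural: E_rowcol is the single off-diagonal entry
  expect_true(all(is.finite(ps$E_rowcol)))
})

test_that("trajectory CSV round trip preserves positions", {
  pos <- array(rnorm(24), c(4, 2, 3))
  tmp <- tempfile(fileext = ".csv")
  write_trajectories(data.frame(
    frame = rep(0:2, each = 4), point_id = rep(1:4, 3),
    row = as.vector(pos[, 1, ]), col = as.vector(pos[, 2, ])), tmp)
  back <- read_trajectories(tmp)
  expect_equal(back, pos, tolerance = 1e-12)
})
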