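test_that("phantom configuration validates its geometry", {
  expect_error(phantom_config(inner_radius = 30, outer_radius = 20), "inner_radius")
  expect_error(phantom_config(frames = 1), "frames")
  expect_error(phantom_config(scale_min = 0), "scale_min")
  cfg <- phantom_config()
  expect_equal(cfg$frames, 19L)
  expect_equal(cfg$pixel_size_mm, 1.48)
  expect_equal(cfg$tag_spacing, 6)
})

test_that("rendering is deterministic and fading scales the tag amplitude", {
  cfg <- mini_phantom_config(noise_sigma = 0.02, seed = 7L)
  expect_identical(render_tag_image(cfg, 1), render_tag_image(cfg, 1))
  cfg2 <- mini_phantom_config(noise_sigma = 0.02, seed = 8L)
  expect_false(identical(render_tag_image(cfg, 1), render_tag_image(cfg2, 1)))
  # fading: modulation amplitude above the myocardial floor scales by f^t
  cfa <- mini_phantom_config(tag_fading = 0.9)
  f0 <- render_tag_image(cfa, 0)
  f2 <- render_tag_image(cfa, 2)
  amp <- function(img) {
    myo <- img[img > cfa$background + 1e-9]
    max(myo) - min(myo)
  }
  expect_equal(amp(f2) / amp(f0), 0.81, tolerance = 0.02)
})

test_that("forward and inverse motions are exact inverses", {
  set.seed(31)
  pts <- cbind(runif(50, 15, 50), runif(50, 15, 50))
  for (mo in c("translation", "rotation", "scale", "contract_twist")) {
    cfg <- mini_phantom_config(motion = mo, frames = 5L)
    for (t in c(1, 2, 4)) {
      fwd <- phantom_motion(cfg, pts, t)
      back <- phantom_motion_inverse(cfg, fwd, t)
      expect_lt(max(abs(back - pts)), 1e-10)
    }
  }
})

test_that("analytic strain matches closed forms per motion type", {
  pts <- cbind(c(20, 40, 28), c(30, 25, 44))
  # translation: phi_t = p + (t/(T-1)) c, E = 0
  cfg_t <- mini_phantom_config(motion = "translation", translation = c(3, -2),
                               frames = 5L)
  expect_equal(phantom_motion(cfg_t, pts, 2),
               sweep(pts, 2, c(3, -2) * 2 / 4, "+"))
  st <- phantom_strain(cfg_t, pts, 3)
  expect_lt(max(abs(st$E)), 1e-12)
  # rotation: E = 0 at all frames
  cfg_r <- mini_phantom_config(motion = "rotation", frames = 5L)
  expect_lt(max(abs(phantom_strain(cfg_r, pts, 2)$E)), 1e-12)
  # scale at peak: E = (1 - a^-2)/2 I with a = scale_min
  cfg_s <- mini_phantom_config(motion = "scale", scale_min = 0.8, frames = 5L)
  st_s <- phantom_strain(cfg_s, pts, 2)   # sin^2(pi/2) = 1: peak frame
  expect_equal(st_s$Ecc, rep(-0.28125, 3), tolerance = 1e-12)
  expect_equal(st_s$Err, rep(-0.28125, 3), tolerance = 1e-12)
})

test_that("contract-twist Jacobian agrees with a numerical derivative", {
  cfg <- mini_phantom_config(motion = "contract_twist", frames = 5L)
  pts <- cbind(c(20, 40, 45), c(38, 30, 45))
  st <- phantom_strain(cfg, pts, 2)
  h <- 1e-6
  for (i in 1:3) {
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dp <- matrix(0, 1, 2); dp[j] <- h
      J[, j] <- (phantom_motion(cfg, pts[i, , drop = FALSE] + dp, 2) -
                 phantom_motion(cfg, pts[i, , drop = FALSE] - dp, 2)) / (2 * h)
    }
    expect_equal(st$F[, , i], J, tolerance = 1e-6)
  }
})

test_that("tags are advected with the tissue", {
  cfg <- mini_phantom_config(motion = "contract_twist")
  f1 <- render_tag_image(cfg, 1)
  # a pixel of frame 1 pulled back to material coordinates must show the
  # frame-0 pattern of that material point
  for (x in list(c(18, 31), c(40, 40), c(31, 12))) {
    p0 <- phantom_motion_inverse(cfg, matrix(x, 1, 2), 1)
    r0 <- sqrt(sum((p0 - cfg$center)^2))
    if (r0 < cfg$inner_radius || r0 > cfg$outer_radius) next
    want <- cfg$myocardium_base +
      cfg$tag_contrast * htmotion:::tag_pattern(cfg, p0[1], p0[2])
    expect_equal(f1[x[1] + 1, x[2] + 1], unname(want), tolerance = 1e-12)
  }
})

test_that("a full study carries 18 landmarks with cyclic ground truth", {
  cfg <- mini_phantom_config()
  ph <- tag_phantom(cfg)
  expect_length(ph$frames, 3)
  expect_equal(nrow(ph$landmarks), 18)
  expect_equal(dim(ph$truth), c(18L, 2L, 3L))
  expect_equal(ph$truth[, , 1], unname(ph$landmarks))
  # cyclic profile: last frame returns to the initial configuration
  expect_lt(max(abs(ph$truth[, , 3] - ph$truth[, , 1])), 1e-9)
  expect_true(all(ph$strain_truth$Ecc[ph$strain_truth$frame == 0] == 0))
  # landmarks: 3 rings x 6 sectors, one per sector per ring
  lab <- assign_aha_regions(ph$landmarks, cfg$center, cfg$reference_angle)
  expect_true(all(table(lab) == 3))
})

test_that("a study writes and its config reads back", {
  cfg <- mini_phantom_config()
  ph <- tag_phantom(cfg)
  dir <- tempfile("phantom")
  write_phantom(ph, dir)
  expect_length(list.files(dir, pattern = "frame_\\d+\\.png"), 3)
  expect_true(file.exists(file.path(dir, "landmarks.csv")))
  tr <- read.csv(file.path(dir, "truth_trajectories.csv"))
  expect_equal(nrow(tr), 18 * 3)
  cfg2 <- read_phantom_config(file.path(dir, "config.json"))
  expect_equal(cfg2$inner_radius, cfg$inner_radius)
  expect_equal(cfg2$motion, cfg$motion)
  expect_identical(render_tag_image(cfg2, 1), ph$frames[[2]])
})
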