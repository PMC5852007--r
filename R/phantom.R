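#' Configuration of the synthetic tagged-MRI phantom
#'
#' Describes a short-axis-like scene — an annular myocardium around a dark
#' blood pool — carrying a SPAMM-like multiplicative cos^2 tag grid, deformed
#' over a cardiac cycle by a known smooth motion with closed-form ground
#' truth. The tag pattern (and a smooth low-frequency shading that breaks the
#' grid's translational periodicity, as coil shading does in real
#' acquisitions) is attached to material coordinates, so tags move with the
#' tissue.
#'
#' Motion profiles: `translation` ramps linearly over the cycle; the other
#' motions follow a smooth cyclic systole-diastole profile `sin^2(pi
#' t/(T-1))` that peaks mid-cycle and closes the cycle (the last frame
#' returns to the initial configuration).
#'
#' @param image_size `(height, width)` in pixels.
#' @param center LV centre `(row, col)`, 0-based; defaults to the image
#'   centre.
#' @param inner_radius,outer_radius endocardial / epicardial radii in pixels.
#' @param tag_spacing tag grid period in pixels (6 px at the default
#'   1.48 mm/px is a clinically typical spacing).
#' @param tag_contrast amplitude of the tag modulation, in `[0, 1]`.
#' @param background,myocardium_base intensity floor outside / inside the
#'   annulus.
#' @param motion one of `"contract_twist"`, `"translation"`, `"rotation"`,
#'   `"scale"`.
#' @param translation total in-plane drift `(rows, cols)` in pixels
#'   (translation motion).
#' @param rotation_max_deg peak rigid rotation about the centre, degrees.
#' @param scale_min peak contraction factor (radii scaled by this at
#'   mid-cycle) for `"scale"` and `"contract_twist"`.
#' @param twist_max_deg peak transmural twist, degrees: material at the outer
#'   radius is rotated by this much relative to the inner radius at
#'   mid-cycle.
#' @param frames number of cardiac phases `T >= 2` (19 is a typical cycle,
#'   i.e. 18 image pairs).
#' @param tag_fading per-frame multiplicative contrast decay (1 = none).
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param seed RNG seed for the noise stream.
#' @param pixel_size_mm isotropic pixel size, mm.
#' @param reference_angle angular origin (degrees) of AHA sector 1, measured
#'   counter-clockwise from "east" (+col) with "up" (-row) at 90 degrees.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(128L, 128L),
                           center = NULL,
                           inner_radius = 18, outer_radius = 40,
                           tag_spacing = 6, tag_contrast = 0.75,
                           background = 0.05, myocardium_base = 0.15,
                           motion = c("contract_twist", "translation",
                                      "rotation", "scale"),
                           translation = c(3, -2),
                           rotation_max_deg = 8,
                           scale_min = 0.85,
                           twist_max_deg = 8,
                           frames = 19L,
                           tag_fading = 1,
                           noise_sigma = 0,
                           seed = 1L,
                           pixel_size_mm = 1.48,
                           reference_angle = 90) {
  motion <- match.arg(motion)
  image_size <- as.integer(image_size)
  if (is.null(center)) center <- (image_size - 1) / 2
  if (!(inner_radius > 0 && inner_radius < outer_radius &&
        outer_radius < min(image_size) / 2))
    stop("need 0 < inner_radius < outer_radius < min(image_size)/2")
  if (frames < 2L) stop("frames must be >= 2")
  if (scale_min <= 0 || scale_min > 1) stop("scale_min must be in (0, 1]")
  if (tag_contrast < 0 || tag_contrast > 1) stop("tag_contrast must be in [0, 1]")
  structure(list(image_size = image_size, center = as.numeric(center),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 tag_spacing = tag_spacing, tag_contrast = tag_contrast,
                 background = background, myocardium_base = myocardium_base,
                 motion = motion, translation = as.numeric(translation),
                 rotation_max_deg = rotation_max_deg, scale_min = scale_min,
                 twist_max_deg = twist_max_deg, frames = as.integer(frames),
                 tag_fading = tag_fading, noise_sigma = noise_sigma,
                 seed = as.integer(seed), pixel_size_mm = pixel_size_mm,
                 reference_angle = reference_angle),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("Tagged phantom: %d x %d px, annulus %g-%g px, tags %g px, %d frames\n",
              x$image_size[1L], x$image_size[2L], x$inner_radius,
              x$outer_radius, x$tag_spacing, x$frames))
  cat(sprintf("  motion: %s; fading %g, noise sigma %g, seed %d\n",
              x$motion, x$tag_fading, x$noise_sigma, x$seed))
  invisible(x)
}

# motion amplitude profile in [0, 1]
motion_amplitude <- function(cfg, t) {
  s <- t / (cfg$frames - 1L)
  if (cfg$motion == "translation") s else sin(pi * s)^2
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# per-frame motion parameters
motion_params <- function(cfg, t) {
  a <- motion_amplitude(cfg, t)
  list(a = a,
       shift = a * cfg$translation,
       theta = a * cfg$rotation_max_deg * pi / 180,
       alpha = 1 - a * (1 - cfg$scale_min),
       tau = a * cfg$twist_max_deg * pi / 180)
}

#' Analytic phantom motion
#'
#' Forward map `phi_t` of the phantom's motion model applied to material
#' points given in the frame-0 configuration. `phantom_motion_inverse` is the
#' exact closed-form inverse (used for rendering).
#'
#' For `"contract_twist"` a material point at radius `r` moves to radius
#' `alpha(t) * r` and is rotated by `tau(t) * (r - inner) / (outer - inner)`,
#' i.e. a radial contraction with a transmural twist.
#'
#' @param cfg a [phantom_config()].
#' @param points numeric `P x 2` matrix of `(row, col)` positions at frame 0.
#' @param t frame index, `0 <= t < frames`.
#' @return `P x 2` matrix of deformed positions.
#' @export
phantom_motion <- function(cfg, points, t) {
  p <- as_points(points)
  mp <- motion_params(cfg, t)
  switch(cfg$motion,
    translation = sweep(p, 2L, mp$shift, "+"),
    rotation = {
      q <- sweep(p, 2L, cfg$center)
      sweep(q %*% t(rot2(mp$theta)), 2L, cfg$center, "+")
    },
    scale = {
      q <- sweep(p, 2L, cfg$center)
      sweep(mp$alpha * q, 2L, cfg$center, "+")
    },
    contract_twist = {
      q <- sweep(p, 2L, cfg$center)
      r <- sqrt(rowSums(q^2))
      psi <- mp$tau * (r - cfg$inner_radius) /
        (cfg$outer_radius - cfg$inner_radius)
      qr <- cbind(cos(psi) * q[, 1L] - sin(psi) * q[, 2L],
                  sin(psi) * q[, 1L] + cos(psi) * q[, 2L])
      sweep(mp$alpha * qr, 2L, cfg$center, "+")
    })
}

#' @rdname phantom_motion
#' @export
phantom_motion_inverse <- function(cfg, points, t) {
  p <- as_points(points)
  mp <- motion_params(cfg, t)
  switch(cfg$motion,
    translation = sweep(p, 2L, mp$shift),
    rotation = {
      q <- sweep(p, 2L, cfg$center)
      sweep(q %*% t(rot2(-mp$theta)), 2L, cfg$center, "+")
    },
    scale = {
      q <- sweep(p, 2L, cfg$center)
      sweep(q / mp$alpha, 2L, cfg$center, "+")
    },
    contract_twist = {
      q <- sweep(p, 2L, cfg$center) / mp$alpha
      r <- sqrt(rowSums(q^2))
      psi <- mp$tau * (r - cfg$inner_radius) /
        (cfg$outer_radius - cfg$inner_radius)
      qr <- cbind(cos(psi) * q[, 1L] + sin(psi) * q[, 2L],
                  -sin(psi) * q[, 1L] + cos(psi) * q[, 2L])
      sweep(qr, 2L, cfg$center, "+")
    })
}

#' Analytic deformation gradient and strain of the phantom motion
#'
#' Closed-form Jacobian `F = d phi_t / d p` of the forward map at material
#' points, the Eulerian (Almansi) strain `E = (I - (F F^T)^{-1}) / 2`, and
#' its circumferential/radial projections at the deformed positions.
#'
#' @inheritParams phantom_motion
#' @return list with `F` (`2 x 2 x P`), `E` (`2 x 2 x P`), `Ecc`, `Err`
#'   (length-`P` vectors) and `deformed` (`P x 2` positions).
#' @export
phantom_strain <- function(cfg, points, t) {
  p <- as_points(points)
  P <- nrow(p)
  mp <- motion_params(cfg, t)
  Fa <- array(0, c(2L, 2L, P))
  I2 <- diag(2)
  J <- matrix(c(0, 1, -1, 0), 2L, 2L)   # dR/dpsi = J %*% R
  for (i in seq_len(P)) {
    Fa[, , i] <- switch(cfg$motion,
      translation = I2,
      rotation = rot2(mp$theta),
      scale = mp$alpha * I2,
      contract_twist = {
        q <- p[i, ] - cfg$center
        r <- sqrt(sum(q^2))
        dpsi <- mp$tau / (cfg$outer_radius - cfg$inner_radius)
        psi <- mp$tau * (r - cfg$inner_radius) /
          (cfg$outer_radius - cfg$inner_radius)
        R <- rot2(psi)
        if (r < 1e-12) mp$alpha * R
        else mp$alpha * (R + dpsi * ((J %*% R %*% q) %*% t(q / r)))
      })
  }
  def <- phantom_motion(cfg, p, t)
  Ea <- array(0, c(2L, 2L, P))
  Ecc <- numeric(P); Err <- numeric(P)
  for (i in seq_len(P)) {
    Ea[, , i] <- eulerian_strain(Fa[, , i])
    pr <- polar_strain(Ea[, , i], def[i, ], cfg$center)
    Ecc[i] <- pr[["Ecc"]]; Err[i] <- pr[["Err"]]
  }
  list(F = Fa, E = Ea, Ecc = Ecc, Err = Err, deformed = def)
}

# material tag pattern in [0, 1]: cos^2 grid times a smooth low-frequency
# shading that makes 16x16 patches unique under translations of the grid
# period (a perfectly periodic grid would match equally well one period off)
tag_pattern <- function(cfg, row0, col0) {
  s <- cfg$tag_spacing
  tags <- cos(pi * row0 / s)^2 * cos(pi * col0 / s)^2
  H <- cfg$image_size[1L]; W <- cfg$image_size[2L]
  gain <- 0.8 + 0.1 * sin(2 * pi * 1.3 * row0 / H + 0.5) +
               0.1 * sin(2 * pi * 1.7 * col0 / W + 1.1)
  tags * gain
}

#' Render one phantom frame
#'
#' Renders the tagged annulus at frame `t` by exact inverse mapping: each
#' pixel is pulled back to material coordinates with the closed-form inverse
#' motion and the analytic material pattern is evaluated there, so the tags
#' are advected with the tissue without interpolation error. Contrast decays
#' by `tag_fading^t`; seeded Gaussian noise is added last and intensities are
#' clipped to `[0, 1]`.
#'
#' @param cfg a [phantom_config()].
#' @param t frame index, `0 <= t < frames`.
#' @return `H x W` intensity matrix in `[0, 1]`.
#' @export
render_tag_image <- function(cfg, t) {
  H <- cfg$image_size[1L]; W <- cfg$image_size[2L]
  pix <- cbind(rep(0:(H - 1L), times = W), rep(0:(W - 1L), each = H))
  mat <- phantom_motion_inverse(cfg, pix, t)
  r0 <- sqrt((mat[, 1L] - cfg$center[1L])^2 + (mat[, 2L] - cfg$center[2L])^2)
  inside <- r0 >= cfg$inner_radius & r0 <= cfg$outer_radius
  img <- rep(cfg$background, H * W)
  amp <- cfg$tag_contrast * cfg$tag_fading^t
  img[inside] <- cfg$myocardium_base +
    amp * tag_pattern(cfg, mat[inside, 1L], mat[inside, 2L])
  img <- matrix(img, H, W)
  if (cfg$noise_sigma > 0) {
    set.seed(cfg$seed + 7919L * t)
    img <- img + matrix(stats::rnorm(H * W, 0, cfg$noise_sigma), H, W)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Landmark seeds of the phantom
#'
#' 18 labelled myocardial landmarks: 3 rings (25/50/75% of the wall
#' thickness) by 6 AHA sector centres, in ring-major order.
#'
#' @param cfg a [phantom_config()].
#' @return `18 x 2` matrix of `(row, col)` frame-0 positions.
#' @export
phantom_landmarks <- function(cfg) {
  radii <- cfg$inner_radius +
    c(0.25, 0.5, 0.75) * (cfg$outer_radius - cfg$inner_radius)
  ang <- (cfg$reference_angle + 30 + (0:5) * 60) * pi / 180
  out <- matrix(0, 18L, 2L)
  for (ri in 1:3) for (ai in 1:6) {
    out[(ri - 1L) * 6L + ai, ] <- cfg$center +
      radii[ri] * c(-sin(ang[ai]), cos(ang[ai]))
  }
  colnames(out) <- c("row", "col")
  out
}

#' Dense mid-wall sampling points of the phantom
#'
#' A polar grid over the annulus (with a safety margin from both wall
#' boundaries), used as material seed points for strain estimation.
#'
#' @param cfg a [phantom_config()].
#' @param radial_step,angular_step_deg grid resolution.
#' @param margin distance (px) kept from the endo-/epicardial boundaries.
#' @return matrix of `(row, col)` frame-0 positions.
#' @export
phantom_wall_points <- function(cfg, radial_step = 2, angular_step_deg = 5,
                                margin = 3) {
  radii <- seq(cfg$inner_radius + margin, cfg$outer_radius - margin,
               by = radial_step)
  ang <- seq(0, 360 - angular_step_deg, by = angular_step_deg) * pi / 180
  out <- matrix(0, length(radii) * length(ang), 2L)
  i <- 0L
  for (r in radii) for (a in ang) {
    i <- i + 1L
    out[i, ] <- cfg$center + r * c(-sin(a), cos(a))
  }
  colnames(out) <- c("row", "col")
  out
}

#' Generate a full phantom study
#'
#' Renders every frame and tabulates analytic ground truth: landmark
#' trajectories (the forward map applied to the 18 landmarks) and analytic
#' circumferential/radial strain at the landmarks for every frame.
#'
#' @param cfg a [phantom_config()].
#' @return An object of class `tag_phantom`: list with `frames` (list of
#'   `T` intensity matrices), `config`, `landmarks` (`18 x 2`, frame 0),
#'   `truth` (`18 x 2 x T` landmark trajectories), `strain_truth` (data
#'   frame `frame`, `landmark`, `Ecc`, `Err`).
#' @examples
#' ph <- tag_phantom(phantom_config(image_size = c(64, 64), frames = 3,
#'                                  inner_radius = 10, outer_radius = 26))
#' length(ph$frames)
#' @export
tag_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  T_ <- cfg$frames
  frames <- lapply(0:(T_ - 1L), function(t) render_tag_image(cfg, t))
  lm0 <- phantom_landmarks(cfg)
  truth <- array(0, c(nrow(lm0), 2L, T_))
  st <- vector("list", T_)
  for (t in 0:(T_ - 1L)) {
    truth[, , t + 1L] <- phantom_motion(cfg, lm0, t)
    ps <- phantom_strain(cfg, lm0, t)
    st[[t + 1L]] <- data.frame(frame = t, landmark = seq_len(nrow(lm0)),
                               Ecc = ps$Ecc, Err = ps$Err)
  }
  structure(list(frames = frames, config = cfg, landmarks = lm0,
                 truth = truth, strain_truth = do.call(rbind, st)),
            class = "tag_phantom")
}

#' @export
print.tag_phantom <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d frames rendered, 18 landmarks with analytic truth\n",
              length(x$frames)))
  invisible(x)
}

#' @export
plot.tag_phantom <- function(x, t = 0L, landmarks = TRUE, ...) {
  img <- x$frames[[t + 1L]]
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(img) / ncol(img),
                  main = sprintf("phantom frame %d", t), ...)
  if (landmarks) {
    lm <- phantom_motion(x$config, x$landmarks, t)
    H <- nrow(img); W <- ncol(img)
    graphics::points(lm[, 2L] / (W - 1), 1 - lm[, 1L] / (H - 1),
                     col = "red", pch = 3)
  }
  invisible(x)
}

#' Write a phantom study to a directory
#'
#' Writes `frame_###.png` images, `landmarks.csv` (frame 0 positions),
#' `truth_trajectories.csv` (`frame,point_id,row,col`),
#' `strain_truth.csv` and `config.json`.
#'
#' @param study a [tag_phantom()] object.
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(study, dir) {
  stopifnot(inherits(study, "tag_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(study$frames)) {
    png::writePNG(study$frames[[t]],
                  file.path(dir, sprintf("frame_%03d.png", t - 1L)))
  }
  write_points(study$landmarks, file.path(dir, "landmarks.csv"))
  T_ <- dim(study$truth)[3L]
  P <- dim(study$truth)[1L]
  tr <- data.frame(
    frame = rep(0:(T_ - 1L), each = P),
    point_id = rep(seq_len(P), times = T_),
    row = as.vector(study$truth[, 1L, ]),
    col = as.vector(study$truth[, 2L, ]))
  utils::write.csv(tr, file.path(dir, "truth_trajectories.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$strain_truth, file.path(dir, "strain_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  cfgl <- unclass(study$config)
  jsonlite::write_json(cfgl, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom configuration back from JSON
#'
#' @param path `config.json` written by [write_phantom()].
#' @return a [phantom_config()] object.
#' @export
read_phantom_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_config(image_size = x$image_size, center = x$center,
                 inner_radius = x$inner_radius, outer_radius = x$outer_radius,
                 tag_spacing = x$tag_spacing, tag_contrast = x$tag_contrast,
                 background = x$background, myocardium_base = x$myocardium_base,
                 motion = x$motion, translation = x$translation,
                 rotation_max_deg = x$rotation_max_deg,
                 scale_min = x$scale_min, twist_max_deg = x$twist_max_deg,
                 frames = x$frames, tag_fading = x$tag_fading,
                 noise_sigma = x$noise_sigma, seed = x$seed,
                 pixel_size_mm = x$pixel_size_mm,
                 reference_angle = x$reference_angle)
}
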