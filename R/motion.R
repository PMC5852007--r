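#' Track material points over a cardiac cycle
#'
#' Sequential motion estimation: for every consecutive image pair
#' `(I_k, I_{k+1})` the dense window correspondences are computed by
#' [htm_correspondences()], a Local Weighted Mean transform is fitted to the
#' non-degenerate pairs, and the current positions of the tracked points are
#' pushed through it. A 19-frame cycle therefore performs 18 registrations.
#'
#' By default each pair is registered in both directions and the transform
#' is fitted to the union of the forward pairs and the inverted backward
#' pairs (inverse-consistent registration). The leading error of the
#' correlation-peak localiser is odd in the displacement, so the two
#' directions cancel it; without this the small per-pair bias accumulates
#' over a long sequential chain.
#'
#' The default search radius differs from the standalone pair-registration
#' default: between consecutive phases of a gated cine sequence the motion
#' is at most a couple of pixels, and on tag-patterned tissue the search
#' radius must stay below half the tag spacing or a template can lock onto
#' the pattern one period away (tag jumping). A radius of 2 px satisfies
#' both; pass a different [search_config()] for other regimes.
#'
#' @param frames list of numeric image matrices (equal dimensions), or a
#'   3-D array `H x W x T`; at least 2 frames.
#' @param seeds `P x 2` matrix of `(row, col)` material points on frame 0.
#' @param cfg a [search_config()].
#' @param n LWM neighbourhood size (see [lwm()]).
#' @param symmetric register each pair in both directions (see above).
#' @param extrapolate passed to [predict.lwm()]; tracking keeps going for
#'   points that drift outside the transform support (they are flagged),
#'   which suits pipeline use; set `FALSE` to make that an error.
#' @param keep_transforms keep the fitted per-pair `lwm` objects (memory!).
#' @param verbose print one line per registered pair.
#' @return An object of class `htm_trajectories`: list with `positions`
#'   (`P x 2 x T` array), `seeds`, `n_pairs`, `extrapolated` (`P x T`
#'   logical), `cfg`, `n`, `dims` and optionally `transforms`.
#' @export
htm_track <- function(frames, seeds,
                      cfg = search_config(template_search_radius = 2),
                      n = 12L, symmetric = TRUE,
                      extrapolate = TRUE, keep_transforms = FALSE,
                      verbose = FALSE) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(k) frames[, , k])
  T_ <- length(frames)
  if (T_ < 2L) stop("need at least 2 frames")
  dims <- dim(frames[[1L]])
  seeds <- as_points(seeds, "seeds")
  if (any(seeds[, 1L] < 0 | seeds[, 1L] > dims[1L] - 1 |
          seeds[, 2L] < 0 | seeds[, 2L] > dims[2L] - 1))
    stop("all seeds must lie inside frame 0")
  P <- nrow(seeds)
  pos <- array(0, c(P, 2L, T_))
  pos[, , 1L] <- seeds
  extr <- matrix(FALSE, P, T_)
  transforms <- if (keep_transforms) vector("list", T_ - 1L) else NULL
  for (k in seq_len(T_ - 1L)) {
    cc <- tryCatch(
      htm_correspondences(frames[[k]], frames[[k + 1L]], cfg = cfg),
      error = function(e) stop("registration of frame pair ", k - 1L, " -> ",
                               k, " failed: ", conditionMessage(e)))
    ok <- cc$flag == "ok"
    src <- cbind(cc$mov_row[ok], cc$mov_col[ok])
    tgt <- cbind(cc$ref_row[ok], cc$ref_col[ok])
    if (symmetric) {
      bw <- htm_correspondences(frames[[k + 1L]], frames[[k]], cfg = cfg)
      okb <- bw$flag == "ok"
      src <- rbind(src, cbind(bw$ref_row[okb], bw$ref_col[okb]))
      tgt <- rbind(tgt, cbind(bw$mov_row[okb], bw$mov_col[okb]))
      keep <- !duplicated(paste(round(src[, 1L], 6), round(src[, 2L], 6)))
      src <- src[keep, , drop = FALSE]
      tgt <- tgt[keep, , drop = FALSE]
    }
    if (nrow(src) < n)
      stop("frame pair ", k - 1L, " -> ", k, ": only ", nrow(src),
           " usable correspondences (< n = ", n, ")")
    fit <- lwm(src, tgt, n = n)
    new_pos <- predict(fit, pos[, , k], extrapolate = extrapolate)
    pos[, , k + 1L] <- new_pos
    extr[, k + 1L] <- attr(new_pos, "extrapolated")
    if (keep_transforms) transforms[[k]] <- fit
    if (verbose)
      message(sprintf("pair %d -> %d: %d control points, max step %.2f px",
                      k - 1L, k, sum(ok),
                      max(abs(pos[, , k + 1L] - pos[, , k]))))
  }
  structure(list(positions = pos, seeds = seeds, n_pairs = T_ - 1L,
                 extrapolated = extr, cfg = cfg, n = n, dims = dims,
                 transforms = transforms),
            class = "htm_trajectories")
}

#' @export
print.htm_trajectories <- function(x, ...) {
  P <- dim(x$positions)[1L]; T_ <- dim(x$positions)[3L]
  disp <- sqrt((x$positions[, 1L, ] - x$positions[, 1L, 1L])^2 +
               (x$positions[, 2L, ] - x$positions[, 2L, 1L])^2)
  cat(sprintf("HTM trajectories: %d points over %d frames (%d registrations)\n",
              P, T_, x$n_pairs))
  cat(sprintf("  peak displacement from frame 0: %.2f px; %d extrapolated point-frames\n",
              max(disp), sum(x$extrapolated)))
  invisible(x)
}

#' @export
as.data.frame.htm_trajectories <- function(x, ...) {
  P <- dim(x$positions)[1L]; T_ <- dim(x$positions)[3L]
  data.frame(frame = rep(0:(T_ - 1L), each = P),
             point_id = rep(seq_len(P), times = T_),
             row = as.vector(x$positions[, 1L, ]),
             col = as.vector(x$positions[, 2L, ]))
}

#' @export
plot.htm_trajectories <- function(x, max_points = 200L, ...) {
  P <- dim(x$positions)[1L]
  keep <- seq_len(P)
  if (P > max_points) keep <- keep[seq(1L, P, length.out = max_points)]
  graphics::plot(NA, xlim = c(0, x$dims[2L]), ylim = c(-x$dims[1L], 0),
                 xlab = "col", ylab = "-row", asp = 1,
                 main = "tracked trajectories")
  for (i in keep)
    graphics::lines(x$positions[i, 2L, ], -x$positions[i, 1L, ],
                    col = grDevices::adjustcolor("navy", 0.5))
  graphics::points(x$positions[keep, 2L, 1L], -x$positions[keep, 1L, 1L],
                   pch = 16, cex = 0.4, col = "red")
  invisible(x)
}

#' Write / read trajectories as CSV
#'
#' Schema: `frame,point_id,row,col` (frame 0-based).
#' @param x an `htm_trajectories` object (or the data frame shape above).
#' @param path CSV file path.
#' @export
write_trajectories <- function(x, path) {
  df <- if (inherits(x, "htm_trajectories")) as.data.frame(x) else x
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @return `read_trajectories` returns a `P x 2 x T` array.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "point_id", "row", "col")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","))
  frames <- sort(unique(df$frame))
  ids <- sort(unique(df$point_id))
  pos <- array(NA_real_, c(length(ids), 2L, length(frames)))
  for (ti in seq_along(frames)) {
    sub <- df[df$frame == frames[ti], ]
    sub <- sub[match(ids, sub$point_id), ]
    pos[, 1L, ti] <- sub$row
    pos[, 2L, ti] <- sub$col
  }
  pos
}

traj_positions <- function(traj) {
  if (inherits(traj, "htm_trajectories")) traj$positions
  else if (is.array(traj) && length(dim(traj)) == 3L && dim(traj)[2L] == 2L) traj
  else stop("expected an htm_trajectories object or a P x 2 x T array")
}

#' Per-point displacement gradient from scattered trajectories
#'
#' Displacement is taken relative to frame 0, `U = L - L_1`; its gradient is
#' estimated with respect to the *current* (deformed) coordinates by a local
#' least-squares plane fit of each displacement component over the tracked
#' points within `radius` of the point in the current frame. This Eulerian
#' gradient is the one for which `F = (I - dU)^{-1}` and the Almansi strain
#' identities hold.
#'
#' @param traj an [htm_track()] result or `P x 2 x T` array.
#' @param frame frame index `>= 1` (0-based).
#' @param radius neighbourhood radius in pixels (current configuration).
#' @param min_neighbours minimum points (incl. the point itself) for a fit;
#'   at least 3 non-collinear are needed for a plane.
#' @return list with `dU` (`2 x 2 x P`; `dU[a, b, i]` is
#'   `d U_a / d x_b` at point `i` with axis 1 = row, 2 = col) and `valid`
#'   (logical; FALSE where the neighbourhood was insufficient or collinear).
#' @export
displacement_gradient <- function(traj, frame, radius = 8,
                                  min_neighbours = 3L) {
  pos <- traj_positions(traj)
  T_ <- dim(pos)[3L]
  if (frame < 1L || frame > T_ - 1L) stop("frame must be in 1 .. T-1")
  cur <- pos[, , frame + 1L, drop = FALSE][, , 1L]
  U <- cur - pos[, , 1L]
  P <- nrow(cur)
  dU <- array(NA_real_, c(2L, 2L, P))
  valid <- logical(P)
  r2 <- radius^2
  for (i in seq_len(P)) {
    d2 <- (cur[, 1L] - cur[i, 1L])^2 + (cur[, 2L] - cur[i, 2L])^2
    nb <- which(d2 <= r2)
    if (length(nb) < max(3L, min_neighbours)) next
    X <- cbind(1, cur[nb, 1L] - cur[i, 1L], cur[nb, 2L] - cur[i, 2L])
    d <- svd(X, nu = 0L, nv = 0L)$d
    if (d[3L] <= 1e-8 * d[1L]) next   # collinear neighbourhood
    cf <- qr.coef(qr(X), U[nb, , drop = FALSE])
    dU[1L, , i] <- cf[2:3, 1L]   # dU_row/drow, dU_row/dcol
    dU[2L, , i] <- cf[2:3, 2L]
    valid[i] <- TRUE
  }
  list(dU = dU, valid = valid)
}

#' Deformation gradient from the displacement gradient
#'
#' `F = (I - dU)^{-1}` relates the undeformed to the deformed configuration
#' when `dU` is the Eulerian displacement gradient.
#'
#' @param dU `2 x 2` displacement gradient.
#' @return `2 x 2` deformation gradient.
#' @export
deformation_gradient <- function(dU) {
  A <- diag(2) - dU
  if (abs(det(A)) < 1e-8)
    stop("(I - dU) is singular (|det| < 1e-8); deformation gradient undefined")
  solve(A)
}

#' Eulerian (Almansi) strain tensor
#'
#' `E = (I - (F F^T)^{-1}) / 2`, symmetrised exactly. Zero for any rigid
#' motion (`F` orthogonal).
#'
#' @param F `2 x 2` invertible deformation gradient.
#' @return symmetric `2 x 2` strain tensor.
#' @export
eulerian_strain <- function(F) {
  B <- F %*% t(F)
  if (abs(det(B)) < 1e-16) stop("F F^T is singular")
  Binv <- solve(B)
  Binv <- (Binv + t(Binv)) / 2
  (diag(2) - Binv) / 2
}

#' Circumferential and radial strain components
#'
#' Projects a strain tensor onto the radial direction (unit vector from the
#' LV centroid to the point) and the circumferential direction (radial
#' rotated by 90 degrees): `E_rr = e_r' E e_r`, `E_cc = e_c' E e_c`.
#'
#' @param E symmetric `2 x 2` strain tensor in `(row, col)` axes.
#' @param point,centroid `(row, col)` positions; `point` must differ from
#'   `centroid`.
#' @return named vector `c(Ecc = , Err = )`.
#' @export
polar_strain <- function(E, point, centroid) {
  v <- as.numeric(point) - as.numeric(centroid)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("point coincides with the centroid; direction undefined")
  er <- v / nv
  ec <- c(-er[2L], er[1L])
  c(Ecc = as.numeric(ec %*% E %*% ec), Err = as.numeric(er %*% E %*% er))
}

aha_region_names <- c("Anterior", "Anteroseptal", "Inferoseptal",
                      "Inferior", "Inferolateral", "Anterolateral")

#' Assign points to the six AHA regions
#'
#' Labels each point by its 60-degree sector about the centroid. Angles are
#' measured counter-clockwise (as displayed, i.e. "up" = -row is 90 degrees)
#' from "east" (+col); sector 1 starts at `reference_angle` and the sectors
#' proceed counter-clockwise in the order Anterior, Anteroseptal,
#' Inferoseptal, Inferior, Inferolateral, Anterolateral. Sectors are
#' half-open: a point exactly on a boundary belongs to the sector that
#' begins there.
#'
#' @param points `P x 2` matrix of `(row, col)` positions.
#' @param centroid LV centre `(row, col)`.
#' @param reference_angle angular origin of sector 1, degrees.
#' @return factor of length `P` with the six region levels.
#' @export
assign_aha_regions <- function(points, centroid, reference_angle = 90) {
  p <- as_points(points)
  dr <- p[, 1L] - centroid[1L]
  dc <- p[, 2L] - centroid[2L]
  if (any(dr == 0 & dc == 0)) stop("points must differ from the centroid")
  theta <- atan2(-dr, dc) * 180 / pi
  sector <- floor(((theta - reference_angle) %% 360) / 60) + 1L
  factor(aha_region_names[sector], levels = aha_region_names)
}

#' Per-point strain at one frame
#'
#' Chains [displacement_gradient()], [deformation_gradient()],
#' [eulerian_strain()] and [polar_strain()] for every tracked point.
#'
#' @inheritParams displacement_gradient
#' @param centroid LV centre `(row, col)` used for the polar projection.
#' @return data frame with columns `point_id`, `E_rowrow`, `E_rowcol`,
#'   `E_colcol` (tensor components), `Ecc`, `Err` and `valid`.
#' @export
point_strain <- function(traj, frame, centroid, radius = 8) {
  pos <- traj_positions(traj)
  P <- dim(pos)[1L]
  if (frame == 0L) {
    return(data.frame(point_id = seq_len(P), E_rowrow = 0, E_rowcol = 0,
                      E_colcol = 0, Ecc = 0, Err = 0, valid = TRUE))
  }
  dg <- displacement_gradient(traj, frame, radius = radius)
  cur <- pos[, , frame + 1L]
  out <- data.frame(point_id = seq_len(P), E_rowrow = NA_real_,
                    E_rowcol = NA_real_, E_colcol = NA_real_,
                    Ecc = NA_real_, Err = NA_real_, valid = dg$valid)
  for (i in seq_len(P)) {
    if (!dg$valid[i]) next
    Fm <- tryCatch(deformation_gradient(dg$dU[, , i]), error = function(e) NULL)
    if (is.null(Fm)) { out$valid[i] <- FALSE; next }
    E <- eulerian_strain(Fm)
    pr <- tryCatch(polar_strain(E, cur[i, ], centroid), error = function(e) NULL)
    if (is.null(pr)) { out$valid[i] <- FALSE; next }
    out$E_rowrow[i] <- E[1L, 1L]; out$E_rowcol[i] <- E[1L, 2L]
    out$E_colcol[i] <- E[2L, 2L]
    out$Ecc[i] <- pr[["Ecc"]]; out$Err[i] <- pr[["Err"]]
  }
  out
}

#' Regional strain curves over the cardiac cycle
#'
#' Mean circumferential and radial Eulerian strain per frame in each of the
#' six AHA regions. Material points are labelled once, from their frame-0
#' positions, so each tracked point contributes to exactly one region
#' throughout the cycle; frame-0 strain is identically zero. The mean is
#' unweighted over the region's valid points; a region with no valid points
#' gets `NA` for that frame.
#'
#' @inheritParams point_strain
#' @param reference_angle angular origin of the Anterior sector, degrees.
#' @return An object of class `regional_strain`: data frame with columns
#'   `frame`, `region`, `Ecc`, `Err`, `n_points`; the centroid and reference
#'   angle are kept as attributes.
#' @export
regional_strain <- function(traj, centroid, reference_angle = 90, radius = 8) {
  pos <- traj_positions(traj)
  T_ <- dim(pos)[3L]
  labels <- assign_aha_regions(pos[, , 1L], centroid, reference_angle)
  rows <- vector("list", T_)
  for (t in 0:(T_ - 1L)) {
    ps <- point_strain(traj, t, centroid, radius = radius)
    agg <- lapply(aha_region_names, function(rg) {
      sel <- labels == rg & ps$valid
      data.frame(frame = t, region = rg,
                 Ecc = if (any(sel)) mean(ps$Ecc[sel]) else NA_real_,
                 Err = if (any(sel)) mean(ps$Err[sel]) else NA_real_,
                 n_points = sum(sel))
    })
    rows[[t + 1L]] <- do.call(rbind, agg)
  }
  out <- do.call(rbind, rows)
  out$region <- factor(out$region, levels = aha_region_names)
  attr(out, "centroid") <- centroid
  attr(out, "reference_angle") <- reference_angle
  class(out) <- c("regional_strain", "data.frame")
  out
}

#' @export
print.regional_strain <- function(x, ...) {
  T_ <- length(unique(x$frame))
  cat(sprintf("Regional strain: %d frames x 6 AHA regions\n", T_))
  pk <- stats::aggregate(cbind(Ecc, Err) ~ region, data = x,
                         function(v) v[which.max(abs(v))])
  cat("  peak strain per region:\n")
  for (i in seq_len(nrow(pk)))
    cat(sprintf("    %-14s Ecc %+0.4f  Err %+0.4f\n",
                pk$region[i], pk$Ecc[i], pk$Err[i]))
  invisible(x)
}

#' @export
plot.regional_strain <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(6, "Dark 3")
  for (comp in c("Ecc", "Err")) {
    rng <- range(x[[comp]], na.rm = TRUE)
    graphics::plot(NA, xlim = range(x$frame), ylim = rng,
                   xlab = "frame", ylab = comp,
                   main = if (comp == "Ecc") "circumferential" else "radial")
    for (i in seq_along(aha_region_names)) {
      sub <- x[x$region == aha_region_names[i], ]
      graphics::lines(sub$frame, sub[[comp]], col = cols[i], lwd = 1.5)
    }
    graphics::abline(h = 0, lty = 3)
    if (comp == "Ecc")
      graphics::legend("bottomleft", legend = aha_region_names, col = cols,
                       lwd = 1.5, cex = 0.6, bty = "n")
  }
  invisible(x)
}

#' Write regional strain as CSV
#'
#' Schema: `frame,region,Ecc,Err,n_points`.
#' @param x a [regional_strain()] result.
#' @param path CSV file path.
#' @export
write_regional_strain <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
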