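#' Compactly supported cubic blending weight
#'
#' The Local Weighted Mean kernel `W(D) = 1 - 3 D^2 + 2 D^3` for
#' `0 <= D <= 1` and `0` beyond. `W(0) = 1`, `W(1) = 0` and the derivative
#' vanishes at both ends, so blended fields are continuous with continuous
#' first derivative across neighbourhood boundaries.
#'
#' @param D nonnegative numeric vector of normalised distances.
#' @return numeric vector of weights in `[0, 1]`.
#' @examples
#' lwm_weight(c(0, 0.5, 1, 2))   # 1, 0.5, 0, 0
#' @export
lwm_weight <- function(D) {
  if (any(D < 0)) stop("normalised distance D must be nonnegative")
  w <- 1 - 3 * D^2 + 2 * D^3
  w[D > 1] <- 0
  w
}

as_points <- function(x, what = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x)) && length(x) == 2L) x <- matrix(x, 1L, 2L)
  if (!is.matrix(x) || ncol(x) != 2L || !is.numeric(x))
    stop(what, " must be a numeric matrix with 2 columns (row, col)")
  storage.mode(x) <- "double"
  unname(x)
}

# n nearest neighbour indices (including self) and the radius D_n for every
# source point; chunked O(N^2) distances with partial sort — N here is at
# most a few thousand dense window points.
nn_radii <- function(src, n) {
  N <- nrow(src)
  idx <- matrix(0L, N, n)
  Dn <- numeric(N)
  chunk <- max(1L, 2^20 %/% N)
  for (s in seq(1L, N, chunk)) {
    e <- min(s + chunk - 1L, N)
    d2 <- outer(src[s:e, 1L], src[, 1L], "-")^2 +
          outer(src[s:e, 2L], src[, 2L], "-")^2
    for (r in seq_len(e - s + 1L)) {
      o <- order(d2[r, ])[seq_len(n)]
      idx[s + r - 1L, ] <- o
      Dn[s + r - 1L] <- sqrt(d2[r, o[n]])
    }
  }
  list(idx = idx, Dn = Dn)
}

#' Fit a Local Weighted Mean transformation
#'
#' Fits the landmark-based Local Weighted Mean (LWM) non-rigid mapping from
#' `source` to `target` control points. For every control point a bivariate
#' degree-2 polynomial (6 monomials) is fitted, for each target component,
#' over the point and its `n - 1` nearest neighbours — exactly interpolating
#' when `n = 6`, least-squares when `n > 6`. Evaluation blends all local
#' polynomials whose support reaches the query point with the compactly
#' supported cubic weight [lwm_weight()], each polynomial's support radius
#' being `D_n`, its centre's distance to the `(n-1)`-th nearest neighbour.
#' No global system of equations over all `N` points is ever solved: each
#' fit is strictly local.
#'
#' Fewer than 6 points cannot determine a quadratic and yield ill-conditioned
#' polynomials, so `n < 6` is refused. Near-collinear neighbourhoods are
#' detected through a condition estimate of the local design matrix and
#' refitted with a degree-1 (affine) polynomial.
#'
#' @param source,target numeric `N x 2` matrices of matching control points,
#'   `(row, col)` coordinates. Duplicate source points are an error.
#' @param n neighbourhood size (point + `n - 1` neighbours); minimum 6,
#'   default 12, the size at which local fits are comfortably overdetermined.
#' @param condition_threshold condition-number threshold above which a local
#'   quadratic is deemed ill-conditioned and degraded to affine.
#' @return An object of class `lwm`: list with `centers`, `targets`,
#'   `coef_x`/`coef_y` (`N x 6` centred-monomial coefficients in the order
#'   `1, dr, dc, dr^2, dr*dc, dc^2`), `Dn`, `n`, `degree` (per-point 2 or 1),
#'   `condition` and `call`. Supports `predict`, `fitted`, `residuals`,
#'   `coef`, `print`, `summary` and `plot`.
#' @examples
#' set.seed(1)
#' src <- cbind(runif(40, 0, 32), runif(40, 0, 32))
#' tgt <- src + 2                       # pure translation
#' fit <- lwm(src, tgt)
#' max(abs(predict(fit, src) - tgt))    # ~ 0
#' @export
lwm <- function(source, target, n = 12L, condition_threshold = 1e8) {
  source <- as_points(source, "source")
  target <- as_points(target, "target")
  N <- nrow(source)
  if (nrow(target) != N) stop("source and target must have equal row counts")
  n <- as.integer(n)
  if (n < 6L)
    stop("n = ", n, " refused: fewer than 6 local points make the degree-2 ",
         "local polynomials ill-conditioned (6 coefficients to determine)")
  if (N < n)
    stop(sprintf("need at least n = %d control points, got %d", n, N))
  if (anyDuplicated(source))
    stop("duplicate source control points are not allowed")

  nn <- nn_radii(source, n)
  coef_x <- matrix(0, N, 6L)
  coef_y <- matrix(0, N, 6L)
  degree <- rep(2L, N)
  condition <- numeric(N)
  for (i in seq_len(N)) {
    ni <- nn$idx[i, ]
    dr <- source[ni, 1L] - source[i, 1L]
    dc <- source[ni, 2L] - source[i, 2L]
    X <- cbind(1, dr, dc, dr * dr, dr * dc, dc * dc)
    d <- svd(X, nu = 0L, nv = 0L)$d
    condition[i] <- d[1L] / max(d[6L], .Machine$double.xmin)
    Y <- target[ni, , drop = FALSE]
    if (condition[i] <= condition_threshold) {
      cf <- qr.coef(qr(X), Y)
    } else {
      # near-collinear neighbourhood: degrade to an affine local fit
      degree[i] <- 1L
      X1 <- X[, 1:3, drop = FALSE]
      cf1 <- qr.coef(qr(X1), Y)
      cf1[is.na(cf1)] <- 0
      cf <- rbind(cf1, matrix(0, 3L, 2L))
    }
    cf[is.na(cf)] <- 0
    coef_x[i, ] <- cf[, 1L]
    coef_y[i, ] <- cf[, 2L]
  }
  n_affine <- sum(degree == 1L)
  if (n_affine > 0L)
    warning(n_affine, " ill-conditioned local quadratic(s) degraded to affine")
  structure(list(centers = source, targets = target,
                 coef_x = coef_x, coef_y = coef_y,
                 Dn = nn$Dn, n = n, degree = degree,
                 condition = condition, call = match.call()),
            class = "lwm")
}

# evaluate the i-th local polynomial at query offsets (dr, dc)
eval_poly <- function(object, i, dr, dc) {
  M <- cbind(1, dr, dc, dr * dr, dr * dc, dc * dc)
  cbind(M %*% object$coef_x[i, ], M %*% object$coef_y[i, ])
}

#' Apply a Local Weighted Mean transformation to points
#'
#' Evaluates the fitted mapping at arbitrary points as the weighted mean of
#' all local polynomials whose compact support covers the point. A point
#' beyond every polynomial's support radius has zero total weight; this is an
#' error unless `extrapolate = TRUE`, in which case the nearest polynomial is
#' used alone and the point is flagged in the `"extrapolated"` attribute
#' (dense control points make this rare, and silent extrapolation would
#' corrupt downstream strain).
#'
#' @param object an [lwm()] fit.
#' @param newdata numeric `P x 2` matrix of `(row, col)` points (defaults to
#'   the control-point sources).
#' @param extrapolate logical; see above.
#' @param ... unused.
#' @return `P x 2` matrix of transformed points; attribute `"extrapolated"`
#'   is a logical vector marking out-of-support points.
#' @export
predict.lwm <- function(object, newdata = object$centers,
                        extrapolate = FALSE, ...) {
  q <- as_points(newdata, "newdata")
  P <- nrow(q)
  if (P == 0L)
    return(structure(matrix(numeric(0), 0L, 2L,
                            dimnames = list(NULL, c("row", "col"))),
                     extrapolated = logical(0)))
  out <- matrix(NA_real_, P, 2L)
  extrap <- logical(P)
  ctr <- object$centers
  Dn <- object$Dn
  N <- nrow(ctr)
  chunk <- max(1L, 2^20 %/% max(N, 1L))
  for (s in seq(1L, P, chunk)) {
    e <- min(s + chunk - 1L, P)
    d <- sqrt(outer(q[s:e, 1L], ctr[, 1L], "-")^2 +
              outer(q[s:e, 2L], ctr[, 2L], "-")^2)
    for (r in seq_len(e - s + 1L)) {
      i <- s + r - 1L
      Dnorm <- d[r, ] / Dn
      nz <- which(Dnorm < 1)
      if (length(nz) == 0L) {
        if (!extrapolate)
          stop(sprintf(
            "point %d at (%.2f, %.2f) lies outside the transform's support",
            i, q[i, 1L], q[i, 2L]))
        j <- which.min(d[r, ])
        out[i, ] <- eval_poly(object, j, q[i, 1L] - ctr[j, 1L],
                              q[i, 2L] - ctr[j, 2L])
        extrap[i] <- TRUE
        next
      }
      w <- lwm_weight(Dnorm[nz])
      dr <- q[i, 1L] - ctr[nz, 1L]
      dc <- q[i, 2L] - ctr[nz, 2L]
      M <- cbind(1, dr, dc, dr * dr, dr * dc, dc * dc)
      vx <- rowSums(M * object$coef_x[nz, , drop = FALSE])
      vy <- rowSums(M * object$coef_y[nz, , drop = FALSE])
      sw <- sum(w)
      out[i, ] <- c(sum(w * vx), sum(w * vy)) / sw
    }
  }
  colnames(out) <- c("row", "col")
  attr(out, "extrapolated") <- extrap
  out
}

#' @export
fitted.lwm <- function(object, ...) {
  predict(object, object$centers)
}

#' @export
residuals.lwm <- function(object, ...) {
  object$targets - fitted(object)
}

#' @export
coef.lwm <- function(object, ...) {
  list(centers = object$centers, x = object$coef_x, y = object$coef_y,
       Dn = object$Dn, degree = object$degree)
}

#' @export
print.lwm <- function(x, ...) {
  cat(sprintf("Local Weighted Mean transform: %d control points, n = %d, degree 2\n",
              nrow(x$centers), x$n))
  if (any(x$degree == 1L))
    cat(sprintf("  %d ill-conditioned local fits degraded to affine\n",
                sum(x$degree == 1L)))
  cat(sprintf("  support radii D_n: %.2f - %.2f px (median %.2f)\n",
              min(x$Dn), max(x$Dn), stats::median(x$Dn)))
  invisible(x)
}

#' @export
summary.lwm <- function(object, ...) {
  res <- residuals(object)
  disp <- object$targets - object$centers
  out <- list(
    n_points = nrow(object$centers),
    n = object$n,
    n_affine = sum(object$degree == 1L),
    Dn = stats::quantile(object$Dn, c(0, .5, 1)),
    rms_residual = sqrt(mean(res^2)),
    max_residual = max(abs(res)),
    mean_displacement = mean(sqrt(rowSums(disp^2))),
    max_displacement = max(sqrt(rowSums(disp^2)))
  )
  class(out) <- "summary.lwm"
  out
}

#' @export
print.summary.lwm <- function(x, ...) {
  cat(sprintf("LWM transform: %d control points, n = %d (%d affine fallbacks)\n",
              x$n_points, x$n, x$n_affine))
  cat(sprintf("  control-point residuals: RMS %.4g px, max %.4g px\n",
              x$rms_residual, x$max_residual))
  cat(sprintf("  displacement: mean %.3f px, max %.3f px\n",
              x$mean_displacement, x$max_displacement))
  invisible(x)
}

#' Plot the displacement field of an LWM transform
#'
#' Arrows from source to target control points (subsampled if dense).
#'
#' @param x an [lwm()] fit.
#' @param max_arrows maximum number of arrows to draw.
#' @param ... passed to [graphics::arrows()].
#' @export
plot.lwm <- function(x, max_arrows = 400L, ...) {
  src <- x$centers
  tgt <- x$targets
  keep <- seq_len(nrow(src))
  if (length(keep) > max_arrows)
    keep <- keep[seq(1L, length(keep), length.out = max_arrows)]
  graphics::plot(src[keep, 2L], -src[keep, 1L], pch = 16, cex = 0.3,
                 xlab = "col", ylab = "-row", asp = 1,
                 main = "LWM displacement field")
  move <- keep[rowSums((tgt[keep, ] - src[keep, ])^2) > 0]
  if (length(move))
    graphics::arrows(src[move, 2L], -src[move, 1L],
                     tgt[move, 2L], -tgt[move, 1L],
                     length = 0.04, col = "firebrick", ...)
  invisible(x)
}
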