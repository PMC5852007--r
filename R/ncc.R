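#' Normalized cross-correlation map
#'
#' Slides `template` over every offset of `region` and returns the Pearson
#' correlation coefficient between the template and the region window at each
#' offset. Local means and energies of the region are obtained from running
#' (summed-area) sums, so the map costs one pass over the region per template
#' pixel rather than a full double loop.
#'
#' Offsets where either the template or the region window has zero intensity
#' variance have no defined correlation; they are set to 0 and flagged in
#' `degenerate`. This happens routinely for 2x2 windows over flat blood-pool
#' or background areas and must not poison downstream matching with NaN.
#'
#' @param template numeric matrix (the moving part), at least 2 pixels.
#' @param region numeric matrix (the reference search area), at least as
#'   large as `template` in both dimensions.
#' @return An object of class `ncc_map`: list with `gamma` (matrix of
#'   correlation coefficients; entry `[u+1, v+1]` is the 0-based offset
#'   `(u, v)` of the template's top-left within the region) and `degenerate`
#'   (logical matrix of the same shape).
#' @examples
#' p <- matrix(rnorm(16), 4, 4)
#' m <- ncc_map(p, p)        # self-correlation
#' m$gamma                   # 1 x 1 map, value 1
#' @export
ncc_map <- function(template, region) {
  h <- nrow(template); w <- ncol(template)
  H <- nrow(region); W <- ncol(region)
  if (is.null(h) || is.null(H)) stop("template and region must be matrices")
  if (h * w < 2L) stop("template must have at least 2 pixels")
  if (H < h || W < w)
    stop(sprintf("search region (%d x %d) smaller than template (%d x %d)",
                 H, W, h, w))
  np <- h * w
  nu <- H - h + 1L
  nv <- W - w + 1L

  tsum <- sum(template)
  tss <- sum(template * template)
  tvar <- max(tss - tsum * tsum / np, 0)

  # running-sum local statistics of the region under the template footprint
  fsum <- local_sums(region, h, w)
  fss <- local_sums(region * region, h, w)
  fvar <- fss - fsum * fsum / np
  fvar[fvar < 0] <- 0

  # raw cross-correlation: accumulate over whichever index set is smaller
  if (np <= nu * nv) {
    cross <- matrix(0, nu, nv)
    for (j in seq_len(w)) {
      cols <- j:(j + nv - 1L)
      for (i in seq_len(h)) {
        tij <- template[i, j]
        if (tij != 0)
          cross <- cross + tij * region[i:(i + nu - 1L), cols, drop = FALSE]
      }
    }
  } else {
    cross <- matrix(0, nu, nv)
    for (v in seq_len(nv)) {
      cols <- v:(v + w - 1L)
      for (u in seq_len(nu)) {
        cross[u, v] <- sum(region[u:(u + h - 1L), cols] * template)
      }
    }
  }

  num <- cross - fsum * (tsum / np)
  scale_f <- pmax(fss, 1)
  degen <- (fvar <= 1e-12 * scale_f) | (tvar <= 1e-12 * max(tss, 1))
  denom <- sqrt(fvar * tvar)
  gamma <- matrix(0, nu, nv)
  ok <- !degen
  gamma[ok] <- num[ok] / denom[ok]
  structure(list(gamma = gamma, degenerate = degen), class = "ncc_map")
}

# sums of all h x w windows of m via a zero-padded summed-area table
local_sums <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- m
  S <- apply(S, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  nu <- H - h + 1L
  nv <- W - w + 1L
  i2 <- (h + 1L):(H + 1L); i1 <- 1L:nu
  j2 <- (w + 1L):(W + 1L); j1 <- 1L:nv
  S[i2, j2, drop = FALSE] - S[i1, j2, drop = FALSE] -
    S[i2, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

#' @export
print.ncc_map <- function(x, ...) {
  cat(sprintf("NCC map: %d x %d offsets, %d degenerate, max gamma %.4f\n",
              nrow(x$gamma), ncol(x$gamma), sum(x$degenerate),
              if (all(x$degenerate)) NA_real_ else max(x$gamma[!x$degenerate])))
  invisible(x)
}

#' Sub-pixel refinement of a correlation peak
#'
#' Fits a bivariate quadratic to the 3 x 3 correlation values around the
#' integer peak and returns the fractional offset of its stationary point
#' (clamped to half a pixel per axis). The full 2-D fit captures rotated,
#' anisotropic peaks — e.g. under local shear or twist — that two
#' independent 1-D parabolas would mislocate; when the 3 x 3 neighbourhood
#' is incomplete (peak at the map edge, degenerate neighbours) the per-axis
#' parabola is used for whichever axis still has both neighbours. An exact
#' peak (`gamma = 1` to rounding) needs no refinement and is returned
#' unchanged.
#'
#' @param map an [ncc_map()] result.
#' @param offset integer 0-based `(u, v)` peak location.
#' @return numeric fractional `(du, dv)` in `[-0.5, 0.5]^2`.
#' @export
subpixel_peak <- function(map, offset) {
  g <- map$gamma
  u <- offset[1L] + 1L; v <- offset[2L] + 1L
  gp <- g[u, v]
  if (gp >= 1 - 1e-9) return(c(0, 0))
  clamp <- function(x) max(-0.5, min(0.5, x))
  full <- u > 1L && u < nrow(g) && v > 1L && v < ncol(g) &&
    !any(map$degenerate[(u - 1L):(u + 1L), (v - 1L):(v + 1L)])
  if (full) {
    z <- g[(u - 1L):(u + 1L), (v - 1L):(v + 1L)]
    # least-squares quadratic a + b du + c dv + d du dv + e du^2 + f dv^2
    du1 <- rep(-1:1, times = 3); dv1 <- rep(-1:1, each = 3)
    X <- cbind(1, du1, dv1, du1 * dv1, du1^2, dv1^2)
    cf <- qr.coef(qr(X), as.vector(z))
    H <- matrix(c(2 * cf[5L], cf[4L], cf[4L], 2 * cf[6L]), 2L, 2L)
    # stationary point must be a maximum: Hessian negative definite
    if (H[1L, 1L] < 0 && det(H) > 0) {
      st <- -solve(H, cf[2:3])
      return(c(clamp(st[1L]), clamp(st[2L])))
    }
  }
  refine1 <- function(lo, hi) {
    den <- lo - 2 * gp + hi
    if (den >= 0) return(0)            # not a proper local maximum
    clamp((lo - hi) / (2 * den))
  }
  du <- 0
  if (u > 1L && u < nrow(g) && !map$degenerate[u - 1L, v] &&
      !map$degenerate[u + 1L, v])
    du <- refine1(g[u - 1L, v], g[u + 1L, v])
  dv <- 0
  if (v > 1L && v < ncol(g) && !map$degenerate[u, v - 1L] &&
      !map$degenerate[u, v + 1L])
    dv <- refine1(g[u, v - 1L], g[u, v + 1L])
  c(du, dv)
}

#' Best match of a correlation map
#'
#' Location of the maximum non-degenerate correlation. Ties are broken
#' deterministically by smallest row offset, then smallest column offset.
#' If every offset is degenerate the centre offset is returned with
#' `degenerate = TRUE` so that a flat patch keeps its relative position.
#'
#' When `prefer` is given, all offsets whose correlation lies within
#' `tolerance` of the peak are treated as equivalent matches and the one
#' closest to the preferred offset wins (row-major order breaks remaining
#' ties). Patches with little structure — near-uniform or near-planar 2x2
#' windows — correlate almost perfectly with many windows at once, so their
#' argmax carries no localisation information; resolving such near-ties
#' towards the position predicted by the parent level keeps the cascade's
#' coarse-to-fine information instead of replacing it with noise. `n_ties`
#' reports the size of the equivalence set.
#'
#' @param map an [ncc_map()] result.
#' @param prefer optional 0-based `(u, v)` offset to prefer among near-ties.
#' @param tolerance correlation slack defining a near-tie (only used with
#'   `prefer`; exact floating-point ties are always broken row-major).
#' @return list with `offset` (0-based `(u, v)` of the match), `peak_cc`
#'   (the correlation at the chosen offset, 0 if degenerate), `degenerate`,
#'   `n_ties` and `border` (TRUE when the chosen peak lies on the edge of
#'   the offset domain, where it is not localised: the true optimum may lie
#'   outside the searched area).
#' @export
best_match <- function(map, prefer = NULL, tolerance = 0) {
  stopifnot(inherits(map, "ncc_map"))
  g <- map$gamma
  if (all(map$degenerate)) {
    ctr <- c((nrow(g) - 1L) %/% 2L, (ncol(g) - 1L) %/% 2L)
    return(list(offset = ctr, peak_cc = 0, degenerate = TRUE, n_ties = 0L,
                border = FALSE))
  }
  g[map$degenerate] <- -Inf
  peak <- max(g)
  tol <- if (is.null(prefer)) 0 else tolerance
  hits <- which(g >= peak - tol, arr.ind = TRUE)
  ord <- if (is.null(prefer)) {
    order(hits[, 1L], hits[, 2L])
  } else {
    d2 <- (hits[, 1L] - 1L - prefer[1L])^2 + (hits[, 2L] - 1L - prefer[2L])^2
    order(d2, hits[, 1L], hits[, 2L])
  }
  best <- hits[ord[1L], ]
  off <- c(best[[1L]] - 1L, best[[2L]] - 1L)
  border <- (nrow(g) > 1L && (best[[1L]] == 1L || best[[1L]] == nrow(g))) ||
            (ncol(g) > 1L && (best[[2L]] == 1L || best[[2L]] == ncol(g)))
  list(offset = off, peak_cc = g[best[[1L]], best[[2L]]],
       degenerate = FALSE, n_ties = nrow(hits), border = border)
}
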