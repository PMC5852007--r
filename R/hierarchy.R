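#' Search configuration for hierarchical matching
#'
#' @param template_search_radius pixels of padding around a moving template's
#'   own location when searching the reference image. Inter-frame cardiac
#'   motion is small, so the default of 8 px keeps the search local; use
#'   `Inf` to search the whole reference image.
#' @param overlap_margin pixels of search padding around a child part's (or
#'   overlap section's) expected position inside its matched parent region:
#'   how far a child may move relative to its parent. `0` pins children to
#'   their parent-relative positions.
#' @param min_peak_cc correlation threshold below which a window
#'   correspondence is flagged low-confidence. The default 0 keeps every
#'   non-degenerate pair.
#' @param peak_tolerance correlation differences smaller than this are
#'   considered insignificant when localising a match: offsets within the
#'   tolerance of the peak are resolved towards the position the parent
#'   level predicts (see [best_match()]). The value given applies to a 2 x 2
#'   window and is scaled by `2 / sqrt(npix)` for larger parts, mirroring how
#'   the sampling noise of a correlation coefficient shrinks with patch
#'   size: a 16 x 16 template must separate offsets by only an eighth of
#'   what a 4-pixel window must. Structured patches separate competing
#'   offsets by far more than this; near-planar patches do not separate them
#'   at all.
#' @return object of class `search_config`.
#' @export
search_config <- function(template_search_radius = 8, overlap_margin = 2,
                          min_peak_cc = 0, peak_tolerance = 0.04,
                          subpixel = TRUE) {
  if (template_search_radius < 0) stop("template_search_radius must be >= 0")
  if (overlap_margin < 0) stop("overlap_margin must be >= 0")
  if (min_peak_cc < -1 || min_peak_cc > 1) stop("min_peak_cc must be in [-1, 1]")
  if (peak_tolerance < 0) stop("peak_tolerance must be >= 0")
  structure(list(template_search_radius = template_search_radius,
                 overlap_margin = overlap_margin,
                 min_peak_cc = min_peak_cc,
                 peak_tolerance = peak_tolerance,
                 subpixel = isTRUE(subpixel)),
            class = "search_config")
}

#' @export
print.search_config <- function(x, ...) {
  cat(sprintf(
    "search_config(template_search_radius = %s, overlap_margin = %g, min_peak_cc = %g, peak_tolerance = %g)\n",
    format(x$template_search_radius), x$overlap_margin, x$min_peak_cc,
    x$peak_tolerance))
  invisible(x)
}

# preference tolerance for a patch of npix pixels (cfg value is for 2x2)
tol_for <- function(cfg, npix) cfg$peak_tolerance * 2 / sqrt(npix)

# crop image by 0-based origin and size; caller guarantees bounds
crop0 <- function(img, origin, size_r, size_c = size_r) {
  img[(origin[1L] + 1L):(origin[1L] + size_r),
      (origin[2L] + 1L):(origin[2L] + size_c), drop = FALSE]
}

# clip a 0-based square region so it lies inside the image; may shrink
clip_region <- function(origin, size, dims) {
  r0 <- max(origin[1L], 0L); c0 <- max(origin[2L], 0L)
  r1 <- min(origin[1L] + size, dims[1L]); c1 <- min(origin[2L] + size, dims[2L])
  list(origin = c(r0, c0), size_r = r1 - r0, size_c = c1 - c0)
}

# shift a 0-based origin so that an s x s part anchored there fits the image
clamp_origin <- function(origin, s, dims) {
  c(min(max(origin[1L], 0L), dims[1L] - s),
    min(max(origin[2L], 0L), dims[2L] - s))
}

#' Match one moving template against the reference image
#'
#' Runs NCC of a `t x t` moving template over a reference search area: the
#' template's own location dilated by `cfg$template_search_radius` (clipped
#' to the image; an infinite radius searches the whole reference image as in
#' the literal global formulation). A flat template, or a search area clipped
#' below the template size, falls back to the template's own location and is
#' flagged degenerate.
#'
#' @param moving,reference numeric image matrices of equal dimensions.
#' @param origin 0-based `(row, col)` origin of the template in `moving`.
#' @param t template side length (pixels).
#' @param cfg a [search_config()].
#' @return list `region` (`origin`, `size`), `peak_cc`, `degenerate`.
#' @export
match_template <- function(moving, reference, origin, t = 16L,
                           cfg = search_config()) {
  dims <- dim(reference)
  r <- cfg$template_search_radius
  if (!is.finite(r)) {
    search <- list(origin = c(0L, 0L), size_r = dims[1L], size_c = dims[2L])
  } else {
    search <- clip_region(origin - r, t + 2L * r, dims)
  }
  tmpl <- crop0(moving, origin, t)
  if (search$size_r < t || search$size_c < t) {
    return(list(region = list(origin = clamp_origin(origin, t, dims), size = t),
                peak_cc = 0, degenerate = TRUE))
  }
  reg <- crop0(reference, search$origin, search$size_r, search$size_c)
  bm <- best_match(ncc_map(tmpl, reg), prefer = origin - search$origin,
                   tolerance = tol_for(cfg, t * t))
  if (bm$degenerate || bm$border) {
    return(list(region = list(origin = clamp_origin(origin, t, dims), size = t),
                peak_cc = 0, degenerate = TRUE))
  }
  list(region = list(origin = search$origin + bm$offset, size = t),
       peak_cc = bm$peak_cc, degenerate = FALSE)
}

#' Refine a matched region through centred overlap sections
#'
#' Implements the overlapping layers of the cascade: at each step the centred
#' section of the moving parent at the next (smaller) size is matched by NCC
#' inside the current reference region padded by `cfg$overlap_margin`, and
#' the matched section becomes the new, smaller reference region. Under a
#' template the section sizes are 14, 12, 10; between segment and chunk a
#' single 6 px layer is used. Sections chain: each output feeds the next.
#'
#' @param moving numeric moving image matrix.
#' @param reference numeric reference image matrix.
#' @param parent_origin 0-based origin of the moving parent part.
#' @param parent_size side length of the moving parent.
#' @param ref_region list(`origin`, `size`): current matched reference region.
#' @param section_sizes strictly decreasing integer sizes of the sections.
#' @param cfg a [search_config()].
#' @return list `region` (final matched reference section), `peak_cc` (of the
#'   last refinement), `degenerate` (TRUE if any step fell back).
#' @export
refine_by_overlap <- function(moving, reference, parent_origin, parent_size,
                              ref_region, section_sizes, cfg = search_config()) {
  if (any(diff(section_sizes) >= 0))
    stop("section_sizes must be strictly decreasing")
  dims <- dim(reference)
  margin <- cfg$overlap_margin
  degenerate <- FALSE
  peak <- NA_real_
  for (s in section_sizes) {
    ctr <- (parent_size - s) %/% 2L        # section centred in the moving parent
    rel <- (ref_region$size - s) %/% 2L    # expected: centred in the current region
    sec <- crop0(moving, parent_origin + ctr, s)
    search <- clip_region(ref_region$origin + rel - margin, s + 2L * margin, dims)
    if (search$size_r < s || search$size_c < s) {
      ref_region <- list(origin = clamp_origin(ref_region$origin + rel, s, dims),
                         size = s)
      degenerate <- TRUE
      peak <- 0
      next
    }
    reg <- crop0(reference, search$origin, search$size_r, search$size_c)
    bm <- best_match(ncc_map(sec, reg),
                     prefer = ref_region$origin + rel - search$origin,
                     tolerance = tol_for(cfg, s * s))
    if (bm$degenerate) {
      orig <- clamp_origin(ref_region$origin + rel, s, dims)
      degenerate <- TRUE
      bm$peak_cc <- 0
    } else {
      orig <- search$origin + bm$offset
    }
    peak <- bm$peak_cc
    ref_region <- list(origin = orig, size = s)
  }
  list(region = ref_region, peak_cc = peak, degenerate = degenerate)
}

#' Match child parts inside a matched parent region
#'
#' For each moving child part, NCC against a local reference search area
#' gives the child-sized reference region; the peak correlation is recorded.
#'
#' The search area is centred on the child's *expected* position — its
#' parent-relative offset applied to the estimated parent origin — and
#' extends `cfg$overlap_margin` pixels beyond the child on every side, which
#' is how far a child may plausibly move relative to its parent between
#' consecutive frames (local deformation within a part is a small fraction of
#' the part size). When the matched reference region is a refined (centred,
#' shrunken) section of the moving parent, the parent origin is estimated by
#' undoing the centring, `(parent_size - region_size) / 2` per side, so
#' corner children are reachable. Keeping the search this local also stops a
#' child of a periodic tag pattern from latching onto the match one tag
#' period away.
#'
#' A degenerate (flat) child, a tied correlation peak (see [best_match()]),
#' or a search clipped below the child size falls back to the child's
#' expected position and is flagged.
#'
#' @param moving,reference numeric image matrices.
#' @param child_origins matrix of 0-based child origins (one row per child).
#' @param child_size side length of the children.
#' @param parent_origin 0-based origin of the moving parent part.
#' @param parent_size side length of the moving parent part (>=
#'   `ref_region$size`).
#' @param ref_region list(`origin`, `size`) of the matched reference region.
#' @param cfg a [search_config()].
#' @param subpixel refine each non-degenerate match with [subpixel_peak()];
#'   the fractional part is returned in `frac` while `region` keeps integer
#'   pixel coordinates. Used at the final (window) level, where the matched
#'   first points become correspondences rather than further search regions.
#' @return list of per-child lists `region`, `peak_cc`, `degenerate`, `frac`.
#' @export
match_children <- function(moving, reference, child_origins, child_size,
                           parent_origin, parent_size, ref_region,
                           cfg = search_config(), subpixel = FALSE) {
  dims <- dim(reference)
  ex <- (parent_size - ref_region$size) %/% 2L
  est_parent <- ref_region$origin - ex           # estimated parent origin
  out <- vector("list", nrow(child_origins))
  for (idx in seq_len(nrow(child_origins))) {
    co <- child_origins[idx, ]
    rel <- co - parent_origin
    expected <- est_parent + rel
    fallback <- clamp_origin(expected, child_size, dims)
    search <- clip_region(expected - cfg$overlap_margin,
                          child_size + 2L * cfg$overlap_margin, dims)
    if (search$size_r < child_size || search$size_c < child_size) {
      out[[idx]] <- list(region = list(origin = fallback, size = child_size),
                         peak_cc = 0, degenerate = TRUE,
                         frac = c(NA_real_, NA_real_))
      next
    }
    child <- crop0(moving, co, child_size)
    reg <- crop0(reference, search$origin, search$size_r, search$size_c)
    m <- ncc_map(child, reg)
    bm <- best_match(m, prefer = expected - search$origin,
                     tolerance = tol_for(cfg, child_size * child_size))
    if (bm$degenerate) {
      out[[idx]] <- list(region = list(origin = fallback, size = child_size),
                         peak_cc = 0, degenerate = TRUE,
                         frac = c(NA_real_, NA_real_))
    } else {
      fr <- if (subpixel && !bm$border) subpixel_peak(m, bm$offset)
            else c(NA_real_, NA_real_)
      out[[idx]] <- list(
        region = list(origin = search$origin + bm$offset, size = child_size),
        peak_cc = bm$peak_cc, degenerate = FALSE, frac = fr,
        n_ties = bm$n_ties, border = bm$border)
    }
  }
  out
}

#' Dense point correspondences by hierarchical template matching
#'
#' Runs the full matching cascade for every template of the moving image:
#' template (16) -> overlap sections 14/12/10 -> segments (8) -> overlap 6 ->
#' chunks (4) -> windows (2). Each 2x2 window contributes one correspondence:
#' the window's first (top-left) pixel in the moving image paired with the
#' first pixel of its matched reference region, together with the window-level
#' peak correlation and a status flag.
#'
#' The cascade uses no tunable regularisation and no iterative optimisation;
#' the only knobs are the purely mechanical search extents in `cfg`.
#'
#' @param moving,reference numeric image matrices of identical dimensions,
#'   at least 16 x 16.
#' @param cfg a [search_config()].
#' @param t base template size (16 by default; must be a multiple of 8).
#' @return An object of class `htm_correspondences`: a data frame with
#'   columns `id`, `mov_row`, `mov_col`, `ref_row`, `ref_col`, `peak_cc`,
#'   `flag` (`"ok"`, `"degenerate"` or `"low_confidence"`), in template-major
#'   window order, with the part grid and config as attributes.
#' @examples
#' img <- matrix(rnorm(32 * 32), 32, 32)
#' cc <- htm_correspondences(img, img)   # identity: zero displacement
#' all(cc$mov_row == cc$ref_row)
#' @export
htm_correspondences <- function(moving, reference, cfg = search_config(),
                                t = 16L) {
  if (!identical(dim(moving), dim(reference)))
    stop("moving and reference images must have identical dimensions")
  grid <- part_grid(dim(moving), t = t)
  seg_sizes <- c(t - 2L, t - 4L, t - 6L)          # 14, 12, 10 for t = 16
  s_seg <- t %/% 2L; s_chk <- t %/% 4L; s_win <- t %/% 8L
  off_s <- child_offsets(t)
  off_c <- child_offsets(s_seg)
  off_w <- child_offsets(s_chk)
  n_t <- nrow(grid$template_origins)
  n_win <- 64L * n_t
  mov_pts <- matrix(0L, n_win, 2L)
  ref_pts <- matrix(0, n_win, 2L)
  peak <- numeric(n_win)
  degen <- logical(n_win)
  ambig <- logical(n_win)
  w_idx <- 0L

  for (i in seq_len(n_t)) {
    to <- grid$template_origins[i, ]
    mt <- match_template(moving, reference, to, t = t, cfg = cfg)
    rx <- refine_by_overlap(moving, reference, to, t, mt$region,
                            seg_sizes, cfg = cfg)
    t_bad <- mt$degenerate || rx$degenerate
    seg_origins <- sweep(off_s, 2L, to, "+")
    rs_list <- match_children(moving, reference, seg_origins, s_seg,
                              to, t, rx$region, cfg = cfg,
                              subpixel = cfg$subpixel)
    for (j in 1:4) {
      so <- seg_origins[j, ]
      ry <- refine_by_overlap(moving, reference, so, s_seg,
                              rs_list[[j]]$region, s_seg - 2L, cfg = cfg)
      s_bad <- t_bad || rs_list[[j]]$degenerate || ry$degenerate
      chk_origins <- sweep(off_c, 2L, so, "+")
      rc_list <- match_children(moving, reference, chk_origins, s_chk,
                                so, s_seg, ry$region, cfg = cfg,
                                subpixel = cfg$subpixel)
      for (k in 1:4) {
        co <- chk_origins[k, ]
        c_bad <- s_bad || rc_list[[k]]$degenerate
        win_origins <- sweep(off_w, 2L, co, "+")
        rw_list <- match_children(moving, reference, win_origins, s_win,
                                  co, s_chk, rc_list[[k]]$region, cfg = cfg,
                                  subpixel = cfg$subpixel)
        # Window positions anchor to the segment estimate: an 8x8 segment
        # localises with reliable sub-pixel precision (parabolic peak
        # refinement), while a 2x2 window localises only to +-1 px and its
        # rematch would replace the precise parent displacement with
        # quantisation scatter. The window- and chunk-level matches still
        # run and provide degeneracy/ambiguity flags. Windows whose segment
        # carries no usable sub-pixel peak (degenerate, tied or border peak)
        # keep their own integer match and are flagged, as is every
        # descendant of a fallback anywhere in its ancestor chain: its
        # search was centred on a guessed position.
        sfrac <- rs_list[[j]]$frac
        frac_ok <- !rs_list[[j]]$degenerate && !anyNA(sfrac)
        seg_disp <- rs_list[[j]]$region$origin - so + if (frac_ok) sfrac else c(0, 0)
        for (l in 1:4) {
          w_idx <- w_idx + 1L
          mov_pts[w_idx, ] <- win_origins[l, ]
          ref_pts[w_idx, ] <- if (frac_ok && !rw_list[[l]]$degenerate)
            win_origins[l, ] + seg_disp else rw_list[[l]]$region$origin
          peak[w_idx] <- rw_list[[l]]$peak_cc
          degen[w_idx] <- rw_list[[l]]$degenerate
          ambig[w_idx] <- !degen[w_idx] &&
            (c_bad || !frac_ok || rw_list[[l]]$n_ties > 1L)
        }
      }
    }
  }

  flag <- rep("ok", n_win)
  flag[peak < cfg$min_peak_cc | ambig] <- "low_confidence"
  flag[degen] <- "degenerate"
  out <- data.frame(id = seq_len(n_win),
                    mov_row = mov_pts[, 1L], mov_col = mov_pts[, 2L],
                    ref_row = ref_pts[, 1L], ref_col = ref_pts[, 2L],
                    peak_cc = peak, flag = flag)
  attr(out, "grid") <- grid
  attr(out, "cfg") <- cfg
  class(out) <- c("htm_correspondences", "data.frame")
  out
}

#' @export
print.htm_correspondences <- function(x, ...) {
  n <- nrow(x)
  disp <- sqrt((x$ref_row - x$mov_row)^2 + (x$ref_col - x$mov_col)^2)
  ok <- x$flag == "ok"
  cat(sprintf("HTM correspondences: %d window pairs (%d ok, %d degenerate, %d low-confidence)\n",
              n, sum(ok), sum(x$flag == "degenerate"),
              sum(x$flag == "low_confidence")))
  if (any(ok))
    cat(sprintf("  displacement (ok pairs): mean %.3f px, max %.3f px; mean peak CC %.4f\n",
                mean(disp[ok]), max(disp[ok]), mean(x$peak_cc[ok])))
  invisible(x)
}

#' Write / read correspondences as CSV
#'
#' Schema: `id,mov_row,mov_col,ref_row,ref_col,peak_cc,flag`.
#' @param x an `htm_correspondences` object.
#' @param path CSV file path.
#' @export
write_correspondences <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "mov_row", "mov_col", "ref_row", "ref_col", "peak_cc", "flag")
  if (!all(need %in% names(out)))
    stop("correspondence CSV must have columns ", paste(need, collapse = ","))
  class(out) <- c("htm_correspondences", "data.frame")
  out
}
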