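# Direct-definition oracle for the correlation map: a double loop over all
# offsets computing the Pearson correlation between the template and each
# region window. Deliberately naive and independent of the running-sums path.
ncc_oracle <- function(template, region) {
  h <- nrow(template); w <- ncol(template)
  nu <- nrow(region) - h + 1L
  nv <- ncol(region) - w + 1L
  out <- matrix(NA_real_, nu, nv)
  for (u in seq_len(nu)) {
    for (v in seq_len(nv)) {
      win <- as.vector(region[u:(u + h - 1L), v:(v + w - 1L)])
      tp <- as.vector(template)
      if (stats::sd(win) == 0 || stats::sd(tp) == 0) next
      out[u, v] <- stats::cor(win, tp)
    }
  }
  out
}

# small, quick phantom used across test files (64 x 64, 3 frames)
mini_phantom_config <- function(frames = 3L, ...) {
  phantom_config(image_size = c(64L, 64L), inner_radius = 9,
                 outer_radius = 22, frames = frames, ...)
}

# enumeration oracle for the window ordering: plain nested loops over
# template (row-major), segment, chunk, window
window_order_oracle <- function(dims, t = 16L) {
  out <- NULL
  for (tr in seq(0L, dims[1L] - t, by = t)) for (tc in seq(0L, dims[2L] - t, by = t))
    for (sr in c(0L, t %/% 2L)) for (sc in c(0L, t %/% 2L))
      for (cr in c(0L, t %/% 4L)) for (cc in c(0L, t %/% 4L))
        for (wr in c(0L, t %/% 8L)) for (wc in c(0L, t %/% 8L))
          out <- rbind(out, c(tr + sr + cr + wr, tc + sc + cc + wc))
  out
}
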