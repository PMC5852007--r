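#' Target registration error of tracked landmarks
#'
#' Per-frame root-mean-square Euclidean error between tracked and true
#' landmark positions, in pixels and millimetres, with the mean and standard
#' deviation pooled over the tracked frames (frames 1..T-1; frame 0 is the
#' common initialisation and trivially exact). Landmarks are expected to be
#' withheld from the transform estimation — with dense window control points
#' on an integer lattice and off-lattice landmarks this holds by
#' construction, but it is the caller's responsibility.
#'
#' @param tracked,truth [htm_track()] results or `P x 2 x T` arrays with
#'   identical dimensions.
#' @param pixel_size_mm isotropic pixel size for the mm scale.
#' @return An object of class `tre_report`: list with `per_frame` (data
#'   frame `frame`, `rmse_px`, `rmse_mm`), `mean_px`, `sd_px`, `mean_mm`,
#'   `sd_mm`, `n_landmarks`, `pixel_size_mm`.
#' @examples
#' tr <- array(0, c(2, 2, 3)); tt <- tr
#' tr[, , 2] <- c(3, 0, 4, 0)       # one landmark off by (3,4), one exact
#' tre(tr, tt)$per_frame$rmse_px    # 0, sqrt(12.5), 0
#' @export
tre <- function(tracked, truth, pixel_size_mm = 1) {
  a <- traj_positions(tracked)
  b <- traj_positions(truth)
  if (!identical(dim(a), dim(b)))
    stop("tracked and truth must have identical point x 2 x frame dimensions")
  T_ <- dim(a)[3L]
  rmse_px <- vapply(seq_len(T_), function(t) {
    sqrt(mean(rowSums((a[, , t, drop = FALSE][, , 1L] -
                       b[, , t, drop = FALSE][, , 1L])^2)))
  }, numeric(1L))
  per_frame <- data.frame(frame = 0:(T_ - 1L), rmse_px = rmse_px,
                          rmse_mm = rmse_px * pixel_size_mm)
  pooled <- rmse_px[-1L]
  structure(list(per_frame = per_frame,
                 mean_px = mean(pooled), sd_px = stats::sd(pooled),
                 mean_mm = mean(pooled) * pixel_size_mm,
                 sd_mm = stats::sd(pooled) * pixel_size_mm,
                 n_landmarks = dim(a)[1L],
                 pixel_size_mm = pixel_size_mm),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("Target registration error over %d landmarks, %d frame pairs\n",
              x$n_landmarks, nrow(x$per_frame) - 1L))
  cat(sprintf("  mean %.4f +/- %.4f px  =  %.4f +/- %.4f mm (pixel %.3g mm)\n",
              x$mean_px, x$sd_px, x$mean_mm, x$sd_mm, x$pixel_size_mm))
  cat(sprintf("  worst frame: %.4f px\n", max(x$per_frame$rmse_px)))
  invisible(x)
}

#' Paired comparison of two models' errors
#'
#' Compares per-image errors of a baseline model A against model B: mean
#' errors, B's error as a percentage of A's (A = 100%), the percentage
#' reduction `100 (mean_A - mean_B) / mean_A`, and a paired t-test on the
#' per-image differences. When the paired differences have zero variance the
#' t statistic is undefined; the exact reduction is still reported and the
#' test is flagged degenerate instead of emitting infinities.
#'
#' @param errors_a,errors_b numeric vectors of paired per-image errors
#'   (baseline first), equal length >= 2.
#' @param names labels for the two models.
#' @return An object of class `model_comparison`: list with `mean_a`,
#'   `mean_b`, `percent_error_b`, `percent_reduction`, `t_statistic`,
#'   `p_value`, `df`, `degenerate`, `note`, `names`, `n`.
#' @examples
#' a <- c(2, 2.5, 3, 2.2)
#' compare_models(a, 0.69 * a)$percent_reduction   # 31
#' @export
compare_models <- function(errors_a, errors_b, names = c("A", "B")) {
  if (length(errors_a) != length(errors_b))
    stop("errors_a and errors_b must be paired (equal length)")
  if (length(errors_a) < 2L) stop("need at least 2 paired errors")
  mean_a <- mean(errors_a); mean_b <- mean(errors_b)
  if (mean_a == 0) stop("baseline mean error is 0; percentages undefined")
  d <- errors_a - errors_b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    t_stat <- NA_real_; p <- NA_real_; df <- length(d) - 1L
    note <- if (all(d == 0)) "no difference" else
      "constant paired difference (zero variance): t-test undefined"
    if (all(d == 0)) p <- 1
  } else {
    tt <- stats::t.test(errors_a, errors_b, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    note <- ""
  }
  structure(list(mean_a = mean_a, mean_b = mean_b,
                 percent_error_b = 100 * mean_b / mean_a,
                 percent_reduction = 100 * (mean_a - mean_b) / mean_a,
                 t_statistic = t_stat, p_value = p, df = df,
                 degenerate = degenerate, note = note,
                 names = names, n = length(d)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison over %d images (%s = 100%%)\n", x$n, x$names[1L]))
  cat(sprintf("  mean error: %s %.4f, %s %.4f (%.1f%% of %s)\n",
              x$names[1L], x$mean_a, x$names[2L], x$mean_b,
              x$percent_error_b, x$names[1L]))
  cat(sprintf("  error reduction: %.2f%%\n", x$percent_reduction))
  if (x$degenerate) {
    cat(sprintf("  paired t-test: degenerate (%s)\n", x$note))
  } else {
    cat(sprintf("  paired t-test: t = %.3f, df = %d, p = %.3g\n",
                x$t_statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' @export
plot.model_comparison <- function(x, ...) {
  graphics::barplot(c(100, x$percent_error_b), names.arg = x$names,
                    col = c("gold", "darkgreen"),
                    ylab = "error relative to baseline (%)",
                    main = sprintf("%.1f%% error reduction", x$percent_reduction))
  graphics::abline(h = 100, lty = 3)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Works for [tre()] and [compare_models()] results.
#' @param x report object.
#' @param path output JSON file.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
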