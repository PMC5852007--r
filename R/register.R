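#' Register one image pair
#'
#' Convenience wrapper for a single moving/reference pair: computes the dense
#' hierarchical correspondences and fits the Local Weighted Mean transform to
#' the usable (non-degenerate, confident) pairs.
#'
#' @param moving,reference numeric image matrices of identical dimensions.
#' @param cfg a [search_config()]; its `min_peak_cc` controls which pairs are
#'   flagged low-confidence and excluded from the fit.
#' @param n LWM neighbourhood size.
#' @return An object of class `htm_registration`: list with
#'   `correspondences` (the full [htm_correspondences()] table),
#'   `transform` (the fitted [lwm()] object), `cfg` and `dims`. `predict`
#'   maps points from the moving to the reference frame; `residuals` are the
#'   transform's control-point residuals.
#' @examples
#' cfgp <- phantom_config(image_size = c(64, 64), frames = 3,
#'                        inner_radius = 10, outer_radius = 26)
#' reg <- htm_register(render_tag_image(cfgp, 0), render_tag_image(cfgp, 1))
#' summary(reg)
#' @export
htm_register <- function(moving, reference, cfg = search_config(), n = 12L) {
  cc <- htm_correspondences(moving, reference, cfg = cfg)
  ok <- cc$flag == "ok"
  if (sum(ok) < n)
    stop("only ", sum(ok), " usable correspondences; cannot fit LWM with n = ", n)
  fit <- lwm(cbind(cc$mov_row[ok], cc$mov_col[ok]),
             cbind(cc$ref_row[ok], cc$ref_col[ok]), n = n)
  structure(list(correspondences = cc, transform = fit, cfg = cfg,
                 dims = dim(moving)),
            class = "htm_registration")
}

#' @export
predict.htm_registration <- function(object, newdata, ...) {
  predict(object$transform, newdata, ...)
}

#' @export
residuals.htm_registration <- function(object, ...) {
  residuals(object$transform)
}

#' @export
print.htm_registration <- function(x, ...) {
  cat("HTM registration\n")
  print(x$correspondences)
  print(x$transform)
  invisible(x)
}

#' @export
summary.htm_registration <- function(object, ...) {
  cc <- object$correspondences
  out <- list(dims = object$dims,
              n_pairs = nrow(cc),
              n_ok = sum(cc$flag == "ok"),
              n_degenerate = sum(cc$flag == "degenerate"),
              n_low_conf = sum(cc$flag == "low_confidence"),
              mean_peak_cc = mean(cc$peak_cc[cc$flag == "ok"]),
              lwm = summary(object$transform))
  class(out) <- "summary.htm_registration"
  out
}

#' @export
print.summary.htm_registration <- function(x, ...) {
  cat(sprintf("HTM registration of a %d x %d pair\n", x$dims[1L], x$dims[2L]))
  cat(sprintf("  %d window pairs: %d ok, %d degenerate, %d low-confidence; mean peak CC %.4f\n",
              x$n_pairs, x$n_ok, x$n_degenerate, x$n_low_conf, x$mean_peak_cc))
  print(x$lwm)
  invisible(x)
}

#' @export
plot.htm_registration <- function(x, ...) {
  plot(x$transform, ...)
  invisible(x)
}
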