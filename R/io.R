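#' Read an image sequence
#'
#' Accepts a directory of PNG/TIFF frames (sorted by file name), a character
#' vector of image files, or a single 2D+t NIfTI volume. Intensities are
#' normalised to `[0, 1]` on load (the matcher's correlation measure is
#' invariant to affine intensity changes, so this is safe) and multi-channel
#' images are averaged to grayscale.
#'
#' @param path directory, vector of image files, or a `.nii`/`.nii.gz` file.
#' @return list of `H x W` intensity matrices.
#' @export
read_frames <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
      stop("no PNG/TIFF frames found in directory ", path)
    return(lapply(sort(files), read_image))
  }
  if (length(path) == 1L && grepl("\\.nii(\\.gz)?$", path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI volumes requires the RNifti package")
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) == 2L) d <- c(d, 1L)
    if (length(d) == 4L && d[3L] == 1L) {       # H x W x 1 x T single slice
      vol <- array(vol, c(d[1L], d[2L], d[4L])); d <- dim(vol)
    }
    if (length(d) != 3L)
      stop("expected a 2D+t NIfTI volume, got dims ", paste(d, collapse = "x"))
    frames <- lapply(seq_len(d[3L]), function(k) vol[, , k])
    mx <- max(vapply(frames, max, numeric(1L)))
    if (mx > 1) frames <- lapply(frames, function(f) f / mx)
    return(frames)
  }
  missing <- path[!file.exists(path)]
  if (length(missing)) stop("file not found: ", missing[1L])
  lapply(path, read_image)
}

#' Read a single grayscale image
#'
#' @param file PNG or TIFF file.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
read_image <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else if (grepl("\\.tiff?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(file)
  } else stop("unsupported image format: ", file)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3L]),
                                               drop = FALSE], c(1L, 2L), mean)
  if (max(img) > 1) img <- img / max(img)
  img
}

#' Serialise an LWM transform to JSON (and back)
#'
#' Stores centres, both coefficient sets, support radii, neighbourhood size
#' and per-point degree, so a fitted transform can be reused across frames or
#' sessions.
#'
#' @param fit an [lwm()] object.
#' @param path JSON file path.
#' @export
write_lwm_json <- function(fit, path) {
  stopifnot(inherits(fit, "lwm"))
  obj <- list(centers = fit$centers, targets = fit$targets,
              coef_x = fit$coef_x, coef_y = fit$coef_y,
              Dn = fit$Dn, n = fit$n, degree = fit$degree,
              condition = fit$condition)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_lwm_json
#' @export
read_lwm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = as.matrix(x$centers), targets = as.matrix(x$targets),
                 coef_x = as.matrix(x$coef_x), coef_y = as.matrix(x$coef_y),
                 Dn = as.numeric(x$Dn), n = as.integer(x$n),
                 degree = as.integer(x$degree),
                 condition = as.numeric(x$condition),
                 call = quote(read_lwm_json())),
            class = "lwm")
}
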