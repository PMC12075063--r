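#' @useDynLib mnmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom quantile sd median coef residuals
#' @importFrom utils write.csv read.csv head
NULL

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("mnmorph_parameter_error", "error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("mnmorph_data_error", "error")))
}

as_spacing <- function(spacing_um) {
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 3L)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop_param("spacing_um must be 3 strictly positive values (z, y, x)")
  as.numeric(spacing_um)
}

#' 3D grayscale image stack
#'
#' A 3D scalar volume with per-axis voxel spacing in micrometres. Axis order
#' is (z, y, x): `data[i, j, k]` is the voxel on z-slice `i`. The physical
#' coordinate of a voxel is `(index - 1) * spacing_um` per axis (voxel
#' centres, 0-based physical origin). Intensity units are arbitrary.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param spacing_um voxel size per axis in micrometres; scalar or length 3.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, spacing_um) {
  if (length(dim(data)) != 3L) stop_param("image stack data must be 3-dimensional")
  if (any(!is.finite(data))) stop_param("image stack contains non-finite values")
  structure(list(data = data, spacing_um = as_spacing(spacing_um)),
            class = "image_stack")
}

#' Binary mask over an image stack
#'
#' @param data 3D logical array, same shape as its source stack.
#' @param spacing_um voxel size per axis (µm).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing_um) {
  if (length(dim(data)) != 3L) stop_param("mask data must be 3-dimensional")
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing_um = as_spacing(spacing_um)),
            class = "binary_mask")
}

#' Integer-labelled instance volume
#'
#' Background is 0; each positive id marks one instance. Labels partition the
#' foreground (each voxel carries exactly one id).
#'
#' @param data 3D integer array, axis order (z, y, x).
#' @param spacing_um voxel size per axis (µm).
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, spacing_um) {
  if (length(dim(data)) != 3L) stop_param("label data must be 3-dimensional")
  if (any(data < 0)) stop_param("labels must be non-negative")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing_um = as_spacing(spacing_um)),
            class = "label_volume")
}

voxel_volume_um3 <- function(spacing_um) prod(as_spacing(spacing_um))

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s voxels, spacing (z,y,x) = %s um, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_um, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d instances\n",
              paste(dim(x$data), collapse = "x"), n_labels(x)))
  invisible(x)
}

#' Number of distinct instances in a label volume
#' @param labels a `label_volume`.
#' @return integer count of nonzero ids present.
#' @export
n_labels <- function(labels) {
  m <- max(labels$data)
  if (m == 0L) return(0L)
  sum(tabulate(labels$data[labels$data > 0L], nbins = m) > 0L)
}

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a$data), dim(b$data)))
    stop_param(what, ": shapes disagree (",
               paste(dim(a$data), collapse = "x"), " vs ",
               paste(dim(b$data), collapse = "x"), ")")
  invisible(TRUE)
}

# physical coordinates (um) of voxels given 1-based array indices (z,y,x cols)
index_to_um <- function(idx, spacing_um) {
  sweep(idx - 1, 2, spacing_um, `*`)
}
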