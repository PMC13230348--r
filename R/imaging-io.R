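#' Min-max normalize a volume to the intensity range [0, 1]
#'
#' Rescales all voxels of a 3D volume (or 2D image) affinely so that the
#' minimum maps to 0 and the maximum to 1. Normalization is per volume, not
#' per slice: relative intensities between slices of the same subject are
#' preserved.
#'
#' @param volume Numeric array (any dimensionality) with finite values and
#'   `max > min`.
#' @return Array of the same shape with minimum 0 and maximum 1.
#' @examples
#' normalize_intensity(array(c(10, 15, 20), dim = c(3, 1, 1)))
#' @export
normalize_intensity <- function(volume) {
  if (!is.numeric(volume)) stop_data("volume must be numeric")
  if (any(!is.finite(volume))) stop_data("volume contains non-finite values")
  lo <- min(volume)
  hi <- max(volume)
  if (hi <= lo) {
    stop_data("degenerate input: constant volume (max == min) cannot be normalized")
  }
  (volume - lo) / (hi - lo)
}

#' Extract the central axial slice of a 3D volume
#'
#' The axial (third) axis is indexed 0-based and the slice at `floor(Z/2)` is
#' returned, i.e. the true middle slice for odd `Z` and the upper-middle one
#' for even `Z`.
#'
#' @param volume 3D numeric array X x Y x Z.
#' @param index Optional explicit 0-based slice index overriding the central
#'   convention.
#' @return 2D matrix X x Y.
#' @export
extract_central_slice <- function(volume, index = NULL) {
  if (length(dim(volume)) != 3L) stop_data("volume must be a 3D array")
  z <- dim(volume)[3L]
  if (z < 1L) stop_data("empty axial axis")
  i0 <- if (is.null(index)) floor(z / 2) else as.integer(index)
  if (i0 < 0L || i0 >= z) stop_data("slice index ", i0, " out of range [0, ", z - 1L, "]")
  volume[, , i0 + 1L, drop = TRUE]
}

#' Zero-pad an image onto a square canvas, centered
#'
#' The image is placed centrally; when the total padding on an axis is odd,
#' the smaller half (`floor(pad/2)`) goes on the top/left. Padded margins are
#' exactly zero, so the sum of pixel intensities is preserved.
#'
#' @param image 2D numeric matrix H x W.
#' @param canvas Integer side length of the square output; must be >= both
#'   image dimensions (no cropping).
#' @return `canvas` x `canvas` matrix.
#' @export
pad_to_canvas <- function(image, canvas = 256L) {
  if (is.null(dim(image)) || length(dim(image)) != 2L) stop_data("image must be a 2D matrix")
  canvas <- as.integer(canvas)
  h <- nrow(image)
  w <- ncol(image)
  if (h > canvas || w > canvas) {
    stop_data("image ", h, "x", w, " larger than canvas ", canvas, "; cropping is not supported")
  }
  out <- matrix(0, canvas, canvas)
  top <- floor((canvas - h) / 2)
  left <- floor((canvas - w) / 2)
  out[(top + 1L):(top + h), (left + 1L):(left + w)] <- image
  out
}

#' Construct a slice stack
#'
#' A slice stack is a set of N same-sized 2D grayscale images with
#' intensities in \[0, 1\], stored as one H x W x N array — the container in
#' which preprocessed per-subject slices are concatenated and written to a
#' single NIfTI volume.
#'
#' @param images H x W x N numeric array, or a list of H x W matrices.
#' @param labels Optional character vector of per-slice provenance labels.
#' @return Object of class `slice_stack`.
#' @export
slice_stack <- function(images, labels = NULL) {
  if (is.list(images)) {
    if (length(images) == 0L) stop_data("empty image list")
    dims <- vapply(images, function(m) dim(as.matrix(m)), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop_data("mixed image shapes; all slices must share H x W")
    }
    arr <- array(unlist(images, use.names = FALSE),
                 dim = c(dims[1, 1], dims[2, 1], length(images)))
  } else {
    arr <- images
    if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
    if (length(dim(arr)) != 3L) stop_data("images must be a 3D array or list of matrices")
  }
  if (any(!is.finite(arr))) stop_data("non-finite intensities in slice stack")
  if (min(arr) < 0 || max(arr) > 1) {
    stop_data("intensities outside [0, 1]; normalize before stacking")
  }
  n <- dim(arr)[3L]
  if (!is.null(labels) && length(labels) != n) stop_data("labels length must equal N")
  structure(list(images = arr, labels = labels), class = "slice_stack")
}

#' Stack a list of preprocessed 2D images into a slice stack
#'
#' Order is preserved: slice i of the result is `images[[i]]`.
#'
#' @inheritParams slice_stack
#' @return `slice_stack` with `N = length(images)`.
#' @export
stack_slices <- function(images, labels = NULL) {
  if (!is.list(images)) stop_data("stack_slices expects a list of 2D matrices")
  slice_stack(images, labels = labels)
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("slice_stack: %d images of %d x %d, intensities in [%.3g, %.3g]\n",
              d[3], d[1], d[2], min(x$images), max(x$images)))
  invisible(x)
}

#' @export
dim.slice_stack <- function(x) dim(x$images)

n_slices <- function(stack) dim(stack$images)[3L]

#' Write a slice stack to a NIfTI-1 file
#'
#' Slices are stored along the third axis with an identity-scaled affine;
#' intensities are written as 32-bit floats (pass `datatype = "double"` for
#' lossless storage of arbitrary doubles — values on a 1/256 grid are already
#' exact in 32-bit).
#'
#' @param stack A `slice_stack`.
#' @param path Output file path (`.nii`).
#' @param datatype NIfTI on-disk datatype, default `"float"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, datatype = "float") {
  stopifnot(inherits(stack, "slice_stack"))
  img <- RNifti::asNifti(stack$images)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a slice stack from a NIfTI file
#'
#' The last axis is taken as the slice index; a 2D (single-slice) file yields
#' `N = 1`. Intensities must already lie in \[0, 1\] unless `normalize = TRUE`,
#' in which case a per-volume min-max rescale is applied.
#'
#' @param path NIfTI file path.
#' @param normalize Rescale out-of-range intensities to \[0, 1\]?
#' @return A `slice_stack`.
#' @export
read_stack <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  arr <- tryCatch(as.array(RNifti::readNifti(path)),
                  error = function(e) stop_data("malformed NIfTI file: ", conditionMessage(e)))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop_data("expected a 2D or 3D NIfTI volume, got ", length(dim(arr)), "D")
  if (min(arr) < 0 || max(arr) > 1) {
    if (!normalize) {
      stop_data("intensities in [", signif(min(arr), 4), ", ", signif(max(arr), 4),
                "] outside [0, 1]; pass normalize = TRUE to rescale")
    }
    arr <- normalize_intensity(arr)
  }
  slice_stack(arr)
}

#' Export one slice of a stack as a grayscale PNG
#'
#' Used to render individual images for visual Turing-test sessions.
#'
#' @param stack A `slice_stack`.
#' @param i Slice index (1-based).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_slice_png <- function(stack, i, path) {
  stopifnot(inherits(stack, "slice_stack"))
  n <- n_slices(stack)
  if (i < 1L || i > n) stop_data("slice index ", i, " out of range [1, ", n, "]")
  png::writePNG(stack$images[, , i], target = path)
  invisible(path)
}
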