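# Preprocessing: per-image min-max normalisation, bilinear resizing to a
# square target, geometric augmentation (rotation for whole images, flips for
# ROI crops) and stratified train/validation/test splitting.

#' Min-max normalise an image to [0, 1]
#'
#' `xN = (x - xmin) / (xmax - xmin)` using, by default, a single minimum and
#' maximum over the whole image ("each input image" normalisation);
#' `perChannel = TRUE` normalises each channel independently.  A constant
#' image has no dynamic range: the documented degenerate-input rule emits an
#' all-zero image with a warning.
#'
#' @param image numeric array (H x W or H x W x C).
#' @param perChannel normalise channels independently.
#' @return array of the same shape with range [0, 1] (or all zeros).
#' @examples
#' minMaxNormalize(c(0, 127.5, 255))   # 0, 0.5, 1
#' @export
minMaxNormalize <- function(image, perChannel = FALSE) {
  if (length(image) == 0L) stop("image is empty")
  norm1 <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning("constant image: no dynamic range, emitting zeros")
      return(x * 0)
    }
    (x - lo) / (hi - lo)
  }
  if (perChannel && length(dim(image)) == 3L) {
    out <- image
    for (c in seq_len(dim(image)[3])) out[, , c] <- norm1(image[, , c])
    out
  } else norm1(image)
}

#' Bilinearly resize an image to a square target
#'
#' Aspect ratio is not preserved: both dimensions are mapped to
#' `target` x `target`, matching a pipeline that compresses every input to a
#' fixed square before the network.
#'
#' @param image numeric matrix or H x W x C array with H, W >= 8.
#' @param target output side length.
#' @return the resized image.
#' @export
resizeImage <- function(image, target = 256L) {
  if (!is.numeric(image) || is.null(dim(image)))
    stop("image must be a numeric matrix or array")
  d <- dim(image)
  if (d[1] < 8L || d[2] < 8L) stop("image must be at least 8x8")
  if (d[1] == target && d[2] == target) return(image)
  if (length(d) == 2L)
    return(as.matrix(EBImage::resize(image, w = target, h = target)))
  out <- array(0, c(target, target, d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- as.matrix(EBImage::resize(image[, , c], w = target, h = target))
  out
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation, output size unchanged, exposed corners filled
#' with 0 (black); values clipped back to [0, 1].
#'
#' @param image matrix or H x W x C array with values in [0, 1].
#' @param angle rotation angle in degrees.
#' @return the rotated image.
#' @export
rotateImage <- function(image, angle) {
  d <- dim(image)
  rot1 <- function(m) clip01(as.matrix(
    EBImage::rotate(m, angle, filter = "bilinear",
                    output.dim = c(nrow(m), ncol(m)), bg.col = 0)))
  if (length(d) == 2L) return(rot1(image))
  out <- image
  for (c in seq_len(d[3])) out[, , c] <- rot1(image[, , c])
  out
}

#' Flip an image
#' @param image matrix or H x W x C array.
#' @param axis `"horizontal"` (left-right mirror) or `"vertical"`
#'   (top-bottom mirror).
#' @return the flipped image.
#' @export
flipImage <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  d <- dim(image)
  if (length(d) == 2L) {
    if (axis == "horizontal") image[, ncol(image):1] else image[nrow(image):1, ]
  } else {
    if (axis == "horizontal") image[, d[2]:1, , drop = FALSE]
    else image[d[1]:1, , , drop = FALSE]
  }
}

#' Augment one image according to a plan
#'
#' `"whole"` mode emits one rotated copy per configured angle (default 15,
#' 25, 35, 45 degrees); `"roi"` mode emits a horizontally and a vertically
#' flipped copy.  The original image is retained by the caller, not
#' re-emitted here.  Augmentation never takes values outside [0, 1]
#' (rotation fill is 0).
#'
#' @param image matrix or H x W x C array in [0, 1].
#' @param plan an [AugmentationPlan-class] object.
#' @return list of augmented images.
#' @export
augmentImage <- function(image, plan = AugmentationPlan("whole")) {
  stopifnot(is(plan, "AugmentationPlan"))
  validObject(plan)
  if (plan@mode == "whole") {
    if (length(plan@rotationAngles) == 0L)
      stop("whole-image augmentation requires a non-empty set of rotation angles")
    lapply(plan@rotationAngles, function(a) rotateImage(image, a))
  } else {
    lapply(plan@flips, function(ax) flipImage(image, ax))
  }
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Stratified train/validation/test split
#'
#' Per class of size n: `n_train = round-half-up(f_train * n)`,
#' `n_val = round-half-up(f_val * n)`, and the remainder goes to test.  The
#' within-class shuffle is governed by `rngSeed`; the three index sets are
#' disjoint and cover all indices.
#'
#' @param labels vector of class labels (any type).
#' @param spec a [SplitSpec-class] object.
#' @param rngSeed integer seed for the shuffle.
#' @return list of integer index vectors `train`, `val`, `test` (1-based
#'   positions in `labels`).
#' @examples
#' sp <- stratifiedSplit(rep(0, 154), rngSeed = 1)
#' lengths(sp)   # 108 / 31 / 15
#' @export
stratifiedSplit <- function(labels, spec = SplitSpec(), rngSeed = 1L) {
  stopifnot(is(spec, "SplitSpec"))
  validObject(spec)
  set.seed(rngSeed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (n < 3L)
      stop("class '", cl, "' has only ", n, " members; at least 3 are required")
    idx <- idx[sample.int(n)]
    nTrain <- roundHalfUp(spec@fractions[1] * n)
    nVal <- roundHalfUp(spec@fractions[2] * n)
    if (nTrain + nVal > n) nVal <- n - nTrain
    out$train <- c(out$train, idx[seq_len(nTrain)])
    out$val <- c(out$val, idx[nTrain + seq_len(nVal)])
    out$test <- c(out$test, idx[setdiff(seq_len(n), seq_len(nTrain + nVal))])
  }
  out
}

#' Stack a list of H x W x 3 images into an (N, 3, H, W) training tensor
#' @param images list of H x W x 3 arrays (all the same size).
#' @return a 4-d array.
#' @export
imagesToTensor <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(length(images), d[3], d[1], d[2]))
  for (i in seq_along(images)) x[i, , , ] <- aperm(images[[i]], c(3, 1, 2))
  x
}
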