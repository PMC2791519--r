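#' Construct an evidence-volume set
#'
#' Bundles N x K co-registered 3-D log-evidence volumes with their shared
#' affine and an analysis mask. When `mask` is `NULL`, the mask is derived
#' as the set of voxels at which every volume is finite.
#'
#' @param data numeric 5-D array `[x, y, z, subject, model]` (nats).
#' @param affine numeric 4 x 4 voxel-to-world transform.
#' @param mask optional logical (or 0/1 numeric) 3-D array.
#' @param subjectIds,modelNames optional labels.
#' @return An [EvidenceVolumeSet-class].
#' @export
EvidenceVolumeSet <- function(data, affine = diag(4), mask = NULL,
                              subjectIds = NULL, modelNames = NULL) {
  d <- dim(data)
  if (length(d) != 5L) {
    stop("'data' must be a 5-D array [x, y, z, subject, model]",
         call. = FALSE)
  }
  if (is.null(subjectIds)) subjectIds <- sprintf("subject%02d", seq_len(d[4L]))
  if (is.null(modelNames)) modelNames <- sprintf("model%d", seq_len(d[5L]))
  finiteMask <- array(
    apply(is.finite(data), 1:3, all),
    dim = d[1:3]
  )
  if (is.null(mask)) {
    mask <- finiteMask
  } else {
    if (!all(dim(mask) == d[1:3])) {
      stop("'mask' dimensions must match the voxel grid", call. = FALSE)
    }
    mask <- array(as.logical(mask != 0 & !is.na(mask)), dim = d[1:3]) &
      finiteMask
  }
  if (!any(mask)) {
    stop("no analysable voxels: every voxel is masked out or non-finite",
         call. = FALSE)
  }
  new("EvidenceVolumeSet", data = data, affine = affine, mask = mask,
      subjectIds = as.character(subjectIds),
      modelNames = as.character(modelNames))
}

# Read a single NIfTI volume as (array, affine).
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(aff), 4L, 4L))
}

# Write a 3-D array as NIfTI with the given affine (pixdim must be set
# before the xforms or RNifti rescales the rotation part).
writeVolume <- function(data, affine, path) {
  img <- RNifti::asNifti(array(data, dim = dim(data)))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read co-registered log-evidence volumes
#'
#' Loads one NIfTI volume per subject per model from an explicit manifest
#' and validates that all volumes (and the optional mask) share the same
#' grid and affine (affines must agree within 1e-4 elementwise). Without a
#' mask the analysis mask is the set of voxels finite in every volume; a
#' supplied mask is additionally intersected with that finite set.
#'
#' @param manifest a `data.frame` with columns `subject`, `model`, `path`
#'   (one row per volume, every subject x model pair present exactly once),
#'   or the path to a tab-separated file with those columns.
#' @param maskPath optional path to a binary NIfTI mask on the same grid.
#' @return An [EvidenceVolumeSet-class].
#' @export
readEvidenceVolumes <- function(manifest, maskPath = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  req <- c("subject", "model", "path")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest))) {
    stop("manifest must be a data.frame (or TSV file) with columns ",
         "'subject', 'model', 'path'", call. = FALSE)
  }
  subjects <- unique(as.character(manifest$subject))
  models <- unique(as.character(manifest$model))
  n <- length(subjects)
  k <- length(models)
  if (nrow(manifest) != n * k) {
    stop(sprintf(
      "manifest must contain every subject x model pair exactly once (%d rows, expected %d)",
      nrow(manifest), n * k
    ), call. = FALSE)
  }

  ref <- NULL
  dat <- NULL
  for (i in seq_len(nrow(manifest))) {
    p <- as.character(manifest$path[i])
    if (!file.exists(p)) stop("volume file not found: ", p, call. = FALSE)
    vol <- readVolume(p)
    if (is.null(ref)) {
      ref <- vol
      dat <- array(NA_real_, dim = c(dim(vol$data), n, k))
    } else {
      if (!all(dim(vol$data) == dim(ref$data))) {
        stop("grid shape of ", p, " does not match the first volume",
             call. = FALSE)
      }
      if (max(abs(vol$affine - ref$affine)) > 1e-4) {
        stop("affine of ", p, " does not match the first volume",
             call. = FALSE)
      }
    }
    si <- match(as.character(manifest$subject[i]), subjects)
    mi <- match(as.character(manifest$model[i]), models)
    dat[, , , si, mi] <- vol$data
  }

  mask <- NULL
  if (!is.null(maskPath)) {
    mv <- readVolume(maskPath)
    if (!all(dim(mv$data) == dim(ref$data))) {
      stop("mask grid shape of ", maskPath, " does not match the volumes",
           call. = FALSE)
    }
    mask <- mv$data
  }
  EvidenceVolumeSet(dat, affine = ref$affine, mask = mask,
                    subjectIds = subjects, modelNames = models)
}

# Separable zero-padded convolution of a 3-D array with a 1-D kernel along
# one axis, by shift-and-accumulate.
convolveAxis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    if (abs(off) >= n) next
    src <- if (off >= 0L) seq_len(n - off) else seq(1L - off, n)
    dst <- src + off
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + kernel[j] * a[src, , ]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + kernel[j] * a[, src, ]
    else out[, , dst] <- out[, , dst] + kernel[j] * a[, , src]
  }
  out
}

gaussianKernel <- function(sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

smoothArray <- function(a, sigmaVox) {
  for (axis in 1:3) {
    if (sigmaVox[axis] > 0) {
      a <- convolveAxis(a, gaussianKernel(sigmaVox[axis]), axis)
    }
  }
  a
}

#' Gaussian-smooth log-evidence volumes
#'
#' Convolves every subject x model volume with an axis-separable Gaussian
#' kernel of the requested full width at half maximum, specified in
#' millimetres and converted to voxels through the affine's voxel sizes
#' (`sigma = FWHM / (2 sqrt(2 ln 2))` per axis). Smoothing is
#' mask-renormalised: the masked data and the mask itself are convolved
#' separately and divided, so voxels outside the mask neither dilute in-mask
#' values nor leak into them; out-of-mask voxels are set to `NA`.
#' `fwhmMm = c(0, 0, 0)` returns the input unchanged.
#'
#' @param set an [EvidenceVolumeSet-class].
#' @param fwhmMm kernel FWHM in millimetres, a single value or one per axis;
#'   all values must be >= 0.
#' @return A smoothed [EvidenceVolumeSet-class] on the same grid and mask.
#' @export
smoothVolumes <- function(set, fwhmMm) {
  stopifnot(is(set, "EvidenceVolumeSet"))
  if (length(fwhmMm) == 1L) fwhmMm <- rep(fwhmMm, 3L)
  if (length(fwhmMm) != 3L || any(!is.finite(fwhmMm)) || any(fwhmMm < 0)) {
    stop("'fwhmMm' must be three non-negative finite values", call. = FALSE)
  }
  if (all(fwhmMm == 0)) return(set)

  voxMm <- sqrt(colSums(set@affine[1:3, 1:3]^2))
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / voxMm

  mask <- set@mask
  maskNum <- array(as.numeric(mask), dim = dim(mask))
  den <- smoothArray(maskNum, sigmaVox)
  dat <- set@data
  d <- dim(dat)
  for (s in seq_len(d[4L])) {
    for (m in seq_len(d[5L])) {
      v <- dat[, , , s, m]
      v[!mask] <- 0
      num <- smoothArray(v, sigmaVox)
      out <- array(NA_real_, d[1:3])
      out[mask] <- num[mask] / den[mask]
      dat[, , , s, m] <- out
    }
  }
  new("EvidenceVolumeSet", data = dat, affine = set@affine, mask = mask,
      subjectIds = set@subjectIds, modelNames = set@modelNames)
}
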