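# Shared helpers. Image convention throughout the package: a frame is a plain
# numeric matrix with intensities in [0, 255], indexed frame[row, col] where
# row = y + 1 and col = x + 1; all user-facing pixel coordinates (x, y) are
# 0-based, x to the right, y down, and may be fractional.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Centroid of a binary mask
#'
#' @param mask logical or 0/1 matrix.
#' @return numeric `c(x, y)`, 0-based, possibly fractional.
#' @keywords internal
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty mask has no centroid")
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

# EBImage stores images [x, y]; we store [row = y, col = x]. All EBImage
# operations used here (morphology with symmetric brushes, median, labelling,
# hull filling, FFT convolution with kernels in the same layout) are
# layout-consistent as long as image and kernel share the convention, so no
# transposition is needed. ocontour() coordinates come back 0-based as
# (first-dim, second-dim) = (y, x) and are swapped where exposed.
as_ebi <- function(m) EBImage::Image(m)

ebi_data <- function(img) {
  d <- EBImage::imageData(img)
  dim(d) <- dim(d)[1:2]
  d
}

# Largest connected component (8-connectivity) of a logical matrix.
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- ebi_data(EBImage::bwlabel(as_ebi(mask * 1)))
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  lab == keep
}

# 2-D convolution with reflect padding, via EBImage's FFT filter. The kernel
# must have odd dimensions. Output has the same size as `img`.
conv2_reflect <- function(img, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  padded <- pad_reflect(img, kh, kw)
  out <- ebi_data(EBImage::filter2(as_ebi(padded), kernel, boundary = "circular"))
  out[(kh + 1):(kh + nrow(img)), (kw + 1):(kw + ncol(img)), drop = FALSE]
}

pad_reflect <- function(img, ph, pw) {
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(rev(seq_len(min(ph, nr))), seq_len(nr), nr + 1 - seq_len(min(ph, nr)))
  if (ph > nr) ridx <- rep(ridx, length.out = nr + 2 * ph)  # degenerate tiny images
  cidx <- c(rev(seq_len(min(pw, nc))), seq_len(nc), nc + 1 - seq_len(min(pw, nc)))
  if (pw > nc) cidx <- rep(cidx, length.out = nc + 2 * pw)
  img[ridx, cidx, drop = FALSE]
}

# Rasterize a disk: logical matrix, TRUE where (x,y) within radius of center.
disk_mask <- function(nrow, ncol, cx, cy, r) {
  xs <- matrix(0:(ncol - 1), nrow, ncol, byrow = TRUE)
  ys <- matrix(0:(nrow - 1), nrow, ncol)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite scalar number", name))
  }
}
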