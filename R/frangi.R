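#' Frangi vesselness filter
#'
#' Multiscale Hessian-eigenvalue ridge enhancement for bright curvilinear
#' structures. At each scale the image is Gaussian-smoothed, the
#' scale-normalized Hessian computed by central differences, and the
#' two-parameter vesselness response
#' \eqn{\exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))}
#' evaluated (blobness \eqn{R_b = \lambda_1/\lambda_2}, structureness
#' \eqn{S = \sqrt{\lambda_1^2+\lambda_2^2}}), zero where the principal
#' curvature is not negative. The final map is the pixelwise maximum over
#' scales.
#'
#' @param img Numeric matrix.
#' @param scales Gaussian scales (sigma, pixels).
#' @param beta Blobness sensitivity.
#' @param c_frac Structureness sensitivity as a fraction of the maximum
#'   structureness at each scale (the usual "half the maximum" default).
#' @return Matrix of vesselness values >= 0, same size as `img`.
#' @export
frangi_vesselness <- function(img, scales = 1:4, beta = 0.5, c_frac = 0.5) {
  if (!is.matrix(img)) abort_field("img", "must be a matrix")
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- EBImage::gblur(img, sigma = s)
    dxx <- shift2(sm, 1, 0) - 2 * sm + shift2(sm, -1, 0)
    dyy <- shift2(sm, 0, 1) - 2 * sm + shift2(sm, 0, -1)
    dxy <- (shift2(sm, 1, 1) - shift2(sm, 1, -1) -
              shift2(sm, -1, 1) + shift2(sm, -1, -1)) / 4
    # scale normalization (gamma = 2)
    dxx <- dxx * s^2; dyy <- dyy * s^2; dxy <- dxy * s^2
    tr2 <- (dxx + dyy) / 2
    rad <- sqrt(pmax(((dxx - dyy) / 2)^2 + dxy^2, 0))
    l1 <- tr2 + rad; l2 <- tr2 - rad
    # order so |lambda1| <= |lambda2|
    swap <- abs(l1) > abs(l2)
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
    s2 <- l1^2 + l2^2
    cc <- c_frac * sqrt(max(s2))
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * max(cc, 1e-12)^2)))
    v[l2 >= 0] <- 0 # bright ridges only
    best <- pmax(best, v)
  }
  best
}

# shift a matrix by (di, dj) with edge replication
shift2 <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) - di, 1L), n)
  rj <- pmin(pmax(seq_len(p) - dj, 1L), p)
  m[ri, rj]
}

# Hysteresis support: weak-threshold regions kept when they contain at
# least one strong pixel (8-connectivity via EBImage::bwlabel)
hysteresis_support <- function(v, strong, weak) {
  s <- v >= strong
  w <- v >= weak
  if (!any(s)) return(s)
  lab <- EBImage::bwlabel(w)
  keep <- unique(lab[s & lab > 0])
  w & matrix(lab %in% keep, nrow(v))
}

# Otsu threshold on positive values, via EBImage on the normalized histogram
otsu_cutoff <- function(v) {
  pos <- v[v > 0]
  if (!length(pos)) return(Inf)
  vmax <- max(pos)
  if (vmax <= 0) return(Inf)
  EBImage::otsu(matrix(v / vmax, nrow = 1), range = c(0, 1)) * vmax
}
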