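#' Hessian eigenvalues of a smoothed intensity volume
#'
#' Smooths the volume with an isotropic (in mm) Gaussian of standard
#' deviation \code{scale}, computes the Hessian of second derivatives with
#' respect to physical coordinates (gamma-normalised by \code{scale^2}), and
#' returns per-voxel eigenvalues sorted by absolute value, so that at a
#' bright tube axis \code{lambda1 ~ 0} and \code{lambda2, lambda3 << 0}.
#'
#' @param image intensity [VoxelVolume-class] or numeric array.
#' @param scale Gaussian scale in mm (> 0).
#' @param spacing voxel spacing (taken from the volume when omitted).
#' @return list of three arrays \code{lambda1, lambda2, lambda3} with
#'   \code{|lambda1| <= |lambda2| <= |lambda3|} at every voxel.
#' @export
hessianEigenvalues <- function(image, scale, spacing = NULL) {
  img <- .asNumericArray(image)
  if (any(!is.finite(img))) stop("image contains non-finite voxels")
  stopifnot(scale > 0)
  spacing <- .spacingOf(image, spacing)
  .hessian_eig_cpp(img, dim(img), spacing, scale)
}

#' Tubular vesselness from Hessian eigenvalues
#'
#' The measure is 0 wherever \code{lambda2 >= 0} or \code{lambda3 >= 0}
#' (bright tubes require both strongly negative), and otherwise
#' \deqn{(1 - e^{-R_a^2 / 2\alpha^2}) \, e^{-R_b^2 / 2\beta^2}
#'       \, (1 - e^{-R_c^2 / 2 c^2})}
#' with \eqn{R_a = |\lambda_2|/|\lambda_3|} (plate vs line),
#' \eqn{R_b = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}} (blob deviation) and
#' \eqn{R_c = \sqrt{\lambda_1^2 + \lambda_2^2 + \lambda_3^2}} (structure
#' strength). Output values lie in \[0, 1). The degenerate case
#' \code{lambda3 == 0, lambda2 < 0} is mapped to 0 as the limit of the zero
#' branch.
#'
#' @param eig list with \code{lambda1, lambda2, lambda3} as returned by
#'   [hessianEigenvalues()] (sorted by absolute value).
#' @param alpha,beta sensitivity parameters (defaults 0.3 and 0.7).
#' @param c intensity-scale sensitivity; defaults to half the brightest
#'   expected vessel intensity \code{imax/2} when \code{imax} is given.
#' @param imax brightest vessel intensity (used only to default \code{c}).
#' @return numeric array of vesselness values.
#' @examples
#' e <- list(lambda1 = array(0, c(1, 1, 1)), lambda2 = array(-5, c(1, 1, 1)),
#'           lambda3 = array(-5, c(1, 1, 1)))
#' vesselness(e, c = 5)  # ~ 0.6297
#' @export
vesselness <- function(eig, alpha = 0.3, beta = 0.7, c = NULL, imax = NULL) {
  stopifnot(alpha > 0, beta > 0)
  if (is.null(c)) {
    if (is.null(imax)) stop("supply either c or imax")
    c <- imax / 2
  }
  stopifnot(c > 0)
  l1 <- eig$lambda1; l2 <- eig$lambda2; l3 <- eig$lambda3
  v <- if (is.null(dim(l1))) numeric(length(l1)) else array(0, dim(l1))
  ok <- (l2 < 0) & (l3 < 0)
  if (any(ok)) {
    a1 <- abs(l1[ok]); a2 <- abs(l2[ok]); a3 <- abs(l3[ok])
    Ra2 <- (a2 / a3)^2
    Rb2 <- a1^2 / (a2 * a3)
    Rc2 <- a1^2 + a2^2 + a3^2
    v[ok] <- (1 - exp(-Ra2 / (2 * alpha^2))) *
             exp(-Rb2 / (2 * beta^2)) *
             (1 - exp(-Rc2 / (2 * c^2)))
  }
  v
}

#' Multiscale vesselness of an intensity volume
#'
#' Evaluates [vesselness()] at each scale and takes the voxelwise maximum,
#' which never decreases any voxel's single-scale response.
#'
#' @inheritParams hessianEigenvalues
#' @inheritParams vesselness
#' @param scales numeric vector of Gaussian scales in mm.
#' @return numeric array of vesselness values.
#' @export
multiscaleVesselness <- function(image, scales, alpha = 0.3, beta = 0.7,
                                 c = NULL, imax = NULL, spacing = NULL) {
  stopifnot(length(scales) >= 1, all(scales > 0))
  img <- .asNumericArray(image)
  if (is.null(c) && is.null(imax)) imax <- as.numeric(quantile(img, 0.99))
  out <- NULL
  for (s in scales) {
    v <- vesselness(hessianEigenvalues(image, s, spacing), alpha, beta, c, imax)
    out <- if (is.null(out)) v else pmax(out, v)
  }
  out
}

#' Segment the vessel region from a vesselness volume
#'
#' Region growing (26-connected) from the global-maximum vesselness voxel
#' inside the liver mask, accepting voxels with vesselness at or above
#' \code{growThreshold}, followed by one morphological closing with a 3x3x3
#' cube to fill small cavities. The result is clipped to the liver mask.
#'
#' @param vness vesselness [VoxelVolume-class] or numeric array.
#' @param liver binary liver mask of the same dimensions.
#' @param growThreshold acceptance threshold; defaults to the Otsu threshold
#'   of the nonzero vesselness values inside the liver.
#' @param spacing voxel spacing (taken from the volume when omitted).
#' @return binary [VoxelVolume-class] vessel mask.
#' @export
segmentVessels <- function(vness, liver, growThreshold = NULL, spacing = NULL) {
  v <- .asNumericArray(vness)
  L <- .asMask(liver)
  spacing <- .spacingOf(vness, spacing)
  if (!any(L)) stop("empty liver mask")
  v[!L] <- 0
  if (is.null(growThreshold)) {
    nz <- v[v > 0]
    growThreshold <- if (length(nz) < 2) 0 else .otsu(nz)
  }
  if (!any(v >= growThreshold & v > 0) && growThreshold > 0) {
    warning("no voxel above the growing threshold; returning empty mask")
    return(VoxelVolume(array(FALSE, dim(v)), spacing))
  }
  seed <- which.max(v)           # first maximum in linear-index order
  accept <- (v >= growThreshold) & L
  accept[seed] <- TRUE
  lab <- .cc_label_cpp(accept, dim(v), 26L)
  grown <- array(lab == lab[seed], dim(v))
  closed <- array(.binary_closing_cpp(grown, dim(v), 1L), dim(v)) & L
  VoxelVolume(closed, spacing)
}

# Otsu threshold of a numeric sample (histogram with 256 bins): maximises
# between-class variance.
.otsu <- function(x, bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * bins) + 1L, 1L), bins),
                nbins = bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(bins) - 0.5) / bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[bins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Select the portal-vein connected component
#'
#' Keeps the single largest 26-connected component of a binary vessel mask
#' (the portal system is the dominant connected structure after
#' enhancement); ties go to the component containing the smallest linear
#' voxel index. A user-supplied seed voxel overrides the size rule when the
#' portal trunk is known.
#'
#' @param vessels binary [VoxelVolume-class] or logical array (nonempty).
#' @param seedVoxel optional integer(3) voxel coordinate known to lie on the
#'   portal vein.
#' @return binary mask of the selected component, same carrier type.
#' @export
selectPortalComponent <- function(vessels, seedVoxel = NULL) {
  m <- .asMask(vessels)
  if (!any(m)) stop("empty vessel mask")
  lab <- array(.cc_label_cpp(m, dim(m), 26L), dim(m))
  if (!is.null(seedVoxel)) {
    seedVoxel <- as.integer(seedVoxel)
    k <- lab[seedVoxel[1], seedVoxel[2], seedVoxel[3]]
    if (k == 0) stop("seed voxel is not foreground")
  } else {
    sizes <- tabulate(lab[lab > 0])
    k <- which.max(sizes)        # labels follow linear-index order: ties
  }                              # resolve to the smallest-index component
  out <- lab == k
  if (is(vessels, "VoxelVolume")) VoxelVolume(out, voxelSpacing(vessels)) else out
}
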