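#' Build an embedded point cloud from a multichannel epoch
#'
#' Each time sample of the epoch becomes one point whose coordinates are the
#' instantaneous values of the channels, so an 8-channel, 500-sample epoch
#' becomes 500 points in \eqn{R^8}. The cloud is the transpose of the epoch
#' matrix; no delay embedding and, by default, no amplitude normalization is
#' applied.
#'
#' @param epoch Numeric matrix, channels x samples (microvolts).
#' @param zscore Logical; if `TRUE`, z-score each channel (coordinate) before
#'   embedding. Default `FALSE`: the raw amplitudes define the geometry.
#' @return An object of class `embedded_point_cloud`: a numeric matrix with
#'   one row per time sample and one column per channel.
#' @examples
#' ep <- matrix(rnorm(8 * 100), nrow = 8)
#' epc <- build_point_cloud(ep)
#' dim(epc) # 100 x 8
#' @export
build_point_cloud <- function(epoch, zscore = FALSE) {
  if (!is.matrix(epoch) || !is.numeric(epoch))
    stop("`epoch` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(epoch))) stop("`epoch` contains non-finite values")
  pts <- t(epoch)
  if (zscore) {
    pts <- scale(pts)
    # constant channels have zero variance; they carry no geometry
    pts[, attr(pts, "scaled:scale") == 0] <- 0
    pts <- pts[, , drop = FALSE]
    attributes(pts)[c("scaled:center", "scaled:scale")] <- NULL
  }
  structure(pts, class = c("embedded_point_cloud", class(pts)))
}

#' Vietoris-Rips persistence diagram of a point cloud
#'
#' Computes the persistent homology of the Vietoris-Rips filtration on the
#' Euclidean distances between points, with Z/2 coefficients, in homology
#' dimensions 0 and 1. The filtration is truncated at the enclosing radius
#' (the smallest radius at which some point sees every other point), which
#' leaves every interval unchanged while guaranteeing that no 1-cycle
#' survives to infinity. Zero-persistence pairs are omitted.
#'
#' @param epc Point cloud: a matrix with one row per point (e.g. from
#'   [build_point_cloud()]).
#' @param max_dimension Maximum homology dimension; only 0 and 1 are
#'   supported (1-cycles are the objects of interest here).
#' @return A `persistence_diagram`: a data frame with columns `dimension`
#'   (0 or 1), `birth` and `death` (`Inf` for the essential connected
#'   component), ordered by dimension then birth.
#' @examples
#' square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' rips_diagram(square) # one 1-cycle born at 1, dying at sqrt(2)
#' @export
rips_diagram <- function(epc, max_dimension = 1) {
  pts <- unclass(epc)
  if (!is.matrix(pts)) pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 1) stop("point cloud is empty")
  if (!all(is.finite(pts))) stop("point cloud contains non-finite values")
  if (!max_dimension %in% c(0, 1))
    stop("only homology dimensions 0 and 1 are supported")
  m <- .rips_pairs(pts)
  dg <- data.frame(dimension = as.integer(m[, "dimension"]),
                   birth = m[, "birth"], death = m[, "death"])
  if (max_dimension < 1) dg <- dg[dg$dimension == 0, , drop = FALSE]
  dg <- dg[order(dg$dimension, dg$birth, dg$death), , drop = FALSE]
  rownames(dg) <- NULL
  class(dg) <- c("persistence_diagram", "data.frame")
  dg
}

#' @export
print.persistence_diagram <- function(x, ...) {
  n1 <- sum(x$dimension == 1)
  cat("Persistence diagram:", nrow(x), "intervals (",
      sum(x$dimension == 0), "in H0,", n1, "in H1 )\n")
  print.data.frame(x, ...)
  invisible(x)
}
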