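## The DPCoA space: a weighted principal coordinate analysis of the species
## dissimilarities in which species are weighted by their global proportions.
## Communities and factor levels live in the same space as weighted centroids
## of the species points, so inertias of the point clouds reproduce the
## quadratic-entropy partition exactly.

#' Weighted principal coordinate space of the species
#'
#' Applies PCoA to the species dissimilarity matrix `Delta` with each species
#' weighted by `w` (its global proportion): Gower centering of `-Delta^2/2`
#' under the weighted centering operator, followed by an eigen-decomposition
#' in the `diag(w)` metric.  The rows of the returned coordinate matrix `X`
#' place the species so that
#' * Euclidean distances reproduce `Delta` exactly,
#' * the `w`-weighted centroid of the species is the origin,
#' * axes are `w`-orthogonal with variances equal to the eigenvalues, and
#' * the total inertia (sum of eigenvalues) equals `QE(w, Delta^2/2)`.
#'
#' Axes with eigenvalues at or below `tol * lambda_max` are discarded; an
#' eigenvalue below `-tol * lambda_max` means `Delta` is not Euclidean and is
#' a hard error (see [is_euclidean()]; no Lingoes/Cailliez correction is
#' applied).  Axis signs are fixed so the species coordinate of largest
#' absolute value on each axis is positive.
#'
#' @param d Euclidean species dissimilarity matrix `Delta`.
#' @param w species weights (positive, normalised to sum 1); default even.
#' @param tol relative eigenvalue tolerance.
#' @return an object of class `"dpcoa_space"`: list with `coords` (S x nu
#'   matrix X), `eig` (decreasing positive eigenvalues), `weights`.
#' @seealso [place_points()], [inertia()], [crossed_dpcoa()]
#' @export
dpcoa_space <- function(d, w = NULL, tol = 1e-9) {
  d <- validate_dist(d)
  S <- nrow(d)
  if (is.null(w)) w <- rep(1 / S, S)
  w <- as.numeric(w)
  if (length(w) != S) stop("species weights length does not match d")
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("species weights must be positive (drop zero-weight species first)")
  }
  w <- w / sum(w)

  g <- gower_center(d, w)
  sw <- sqrt(w)
  sym <- g * outer(sw, sw)
  e <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (lmax > 0 && min(e$values) < -tol * lmax) {
    stop("dissimilarity matrix is not Euclidean-embeddable ",
         "(negative eigenvalue in the weighted Gower form; see is_euclidean)")
  }
  keep <- which(e$values > tol * max(lmax, .Machine$double.eps))
  lam <- e$values[keep]
  X <- sweep(e$vectors[, keep, drop = FALSE] / sw, 2, sqrt(lam), "*")
  X <- fix_signs(X)
  rownames(X) <- rownames(d)
  colnames(X) <- if (length(keep)) paste0("Axis", seq_along(keep)) else character(0)
  names(w) <- rownames(d)
  structure(list(coords = X, eig = lam, weights = w, tol = tol),
            class = "dpcoa_space")
}

## deterministic axis orientation: largest |coordinate| positive
fix_signs <- function(X) {
  if (!ncol(X)) return(X)
  for (a in seq_len(ncol(X))) {
    i <- which.max(abs(X[, a]))
    if (X[i, a] < 0) X[, a] <- -X[, a]
  }
  X
}

#' @export
print.dpcoa_space <- function(x, ...) {
  cat("DPCoA species space\n")
  cat("  species:", nrow(x$coords), "  axes:", ncol(x$coords), "\n")
  cat("  inertia (sum of eigenvalues):", format(sum(x$eig)), "\n")
  if (length(x$eig)) {
    cat("  leading eigenvalues:",
        paste(signif(utils::head(x$eig, 5), 4), collapse = ", "),
        if (length(x$eig) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' Place profile points in a DPCoA space
#'
#' Each column of `P` is a species profile (proportions summing to 1, or a
#' centred contrast); its point is the weighted centroid of the species
#' points under that profile, `coords = t(P) %*% X`.  Clouds built from
#' communities or factor levels of a table whose global profile defined the
#' species weights are centred at the origin.
#'
#' @param space a [dpcoa_space()] object.
#' @param P S x n matrix of profiles (species rows aligned with the space).
#' @param weights point weights (positive, normalised); default even.
#' @param role optional label (`"species"`, `"community"`, `"levelA"`,
#'   `"levelB"`, `"interaction"`) carried along for reporting.
#' @return an object of class `"point_cloud"`: list with `coords`
#'   (n x nu), `weights`, `role`.
#' @export
place_points <- function(space, P, weights = NULL, role = "community") {
  stopifnot(inherits(space, "dpcoa_space"))
  P <- as.matrix(P)
  if (nrow(P) != nrow(space$coords)) {
    stop("profile matrix rows (", nrow(P), ") do not match species (",
         nrow(space$coords), ")")
  }
  if (!is.null(rownames(P)) &&
      !identical(rownames(P), rownames(space$coords))) {
    P <- P[rownames(space$coords), , drop = FALSE]
  }
  n <- ncol(P)
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("weights length does not match profile count")
  weights <- weights / sum(weights)
  coords <- crossprod(P, space$coords)
  rownames(coords) <- colnames(P)
  structure(list(coords = coords, weights = weights, role = role),
            class = "point_cloud")
}

#' Inertia of a point cloud
#'
#' Weighted sum of squared distances of the points from the origin.  For the
#' clouds of a DPCoA this reproduces the quadratic-entropy components: the
#' species cloud gives SST, the community cloud SS(C), the factor-level
#' clouds SS(A) and SS(B), and the interaction cloud SS(A,B).
#'
#' @param cloud a `"point_cloud"` (from [place_points()] or
#'   [interaction_points()]), or a [dpcoa_space()] (its species cloud).
#' @param centred assert that the weighted centroid is at the origin (all
#'   DPCoA clouds are); set `FALSE` for a raw cloud.
#' @return a nonnegative number.
#' @export
inertia <- function(cloud, centred = TRUE) {
  if (inherits(cloud, "dpcoa_space")) {
    cloud <- structure(list(coords = cloud$coords, weights = cloud$weights,
                            role = "species"), class = "point_cloud")
  }
  stopifnot(inherits(cloud, "point_cloud"))
  if (!nrow(cloud$coords) || !ncol(cloud$coords)) return(0)
  if (centred) {
    ctr <- as.vector(cloud$weights %*% cloud$coords)
    scale <- max(1, max(abs(cloud$coords)))
    if (max(abs(ctr)) > 1e-8 * scale) {
      stop("point cloud is not centred at the origin; ",
           "pass centred = FALSE to compute raw inertia")
    }
  }
  sum(cloud$weights * rowSums(cloud$coords^2))
}

#' Doubly re-centred interaction points
#'
#' The point `Sigma_ij` at coordinates `(p_ij - p_i+ - p_+j + p_global)' X`
#' is where community `ij` would sit if the levels of both factors were moved
#' to the centre of the space: the re-centring removes both main effects, so
#' the inertia of this cloud is the interaction component
#' `SS(A,B) = SS(C) - SS(A) - SS(B)`.
#'
#' @param space a [dpcoa_space()] built on the table's global weights.
#' @param x the [community_table()].
#' @return a `"point_cloud"` with one point per community.
#' @export
interaction_points <- function(space, x) {
  stopifnot(inherits(space, "dpcoa_space"), inherits(x, "community_table"))
  agg <- aggregate_proportions(x)
  P <- x$props -
    agg$P_A[, x$design$A, drop = FALSE] -
    agg$P_B[, x$design$B, drop = FALSE] +
    agg$p_global
  colnames(P) <- colnames(x$props)
  place_points(space, P, weights = x$community_weights, role = "interaction")
}
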