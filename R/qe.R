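## Rao's quadratic entropy, the cross-entropy dissimilarity between profiles
## and the ANOQE partition over a crossed design.  These are computed purely
## from the QE formulas, independently of the ordination, so the partition
## doubles as an oracle for the geometric identities of the DPCoA space.

#' Rao's quadratic entropy
#'
#' The expected dissimilarity between two individuals drawn (with
#' replacement) from a community with species proportions `p`:
#' `QE(p) = sum_kl p_k p_l d_kl`.
#'
#' For the DPCoA diversity decomposition the dissimilarities must be supplied
#' on the half-squared scale, `D = Delta^2 / 2`, where `Delta` is the
#' Euclidean species dissimilarity; on that scale QE equals the inertia of
#' the community's species points.  The function itself accepts any
#' symmetric zero-diagonal `D` for general use.
#'
#' @param p proportion vector (nonnegative, sums to 1).
#' @param D S x S symmetric dissimilarity matrix with zero diagonal.
#' @return a nonnegative number.
#' @seealso [cross_entropy()], [anoqe()]
#' @export
quadratic_entropy <- function(p, D) {
  p <- check_profile(p, nrow(D))
  as.numeric(p %*% D %*% p)
}

#' Rao's cross-entropy (DISC) between two proportion vectors
#'
#' `DISC(p1, p2) = p1' D p2 - (p1' D p1 + p2' D p2) / 2`.  With
#' `D = Delta^2 / 2` and `Delta` Euclidean this is nonnegative and equals
#' half the squared Euclidean distance between the centroids of the two
#' profiles in the DPCoA space — the "double" embedding that gives the
#' method its name.
#'
#' @param p1,p2 proportion vectors over the same species.
#' @param D S x S symmetric dissimilarity matrix with zero diagonal.
#' @return a number (nonnegative when `D = Delta^2/2` with Euclidean `Delta`).
#' @export
cross_entropy <- function(p1, p2, D) {
  p1 <- check_profile(p1, nrow(D))
  p2 <- check_profile(p2, nrow(D))
  as.numeric(p1 %*% D %*% p2) -
    0.5 * (as.numeric(p1 %*% D %*% p1) + as.numeric(p2 %*% D %*% p2))
}

check_profile <- function(p, S) {
  p <- as.numeric(p)
  if (length(p) != S) stop("proportion vector length does not match D")
  if (anyNA(p) || any(p < -1e-12)) stop("proportions must be nonnegative")
  p
}

#' Analysis of quadratic entropy (ANOQE) over a crossed design
#'
#' Partitions the total quadratic entropy of a balanced two-factor community
#' table into within-community diversity and among-community diversity, the
#' latter split into the two main effects and their interaction:
#'
#' \deqn{SST = SSW + SS(C), \qquad SS(C) = SS(A) + SS(B) + SS(A,B).}
#'
#' All components are computed on the half-squared scale `D = delta^2 / 2`,
#' where they coincide with the inertias of the corresponding point clouds of
#' the DPCoA space (species, communities, factor levels, and the doubly
#' re-centred interaction points):
#' `SST = QE(p_global)`, `SSW = sum_ij c_ij QE(p_ij)`,
#' `SS(A) = QE(p_global) - sum_i a_i QE(p_i+)` (and analogously for B),
#' `SS(A,B) = SS(C) - SS(A) - SS(B)`.
#'
#' Tiny negative components (above `-1e-12`) arising from floating-point
#' cancellation are clamped to zero.
#'
#' @param x a [community_table()] object (balanced crossing enforced there).
#' @param d Euclidean species dissimilarity matrix `Delta` (labels matching
#'   the table's species).
#' @return an object of class `"anoqe"`: named numeric vector with components
#'   `SST`, `SSW`, `SSC`, `SSA`, `SSB`, `SSAB` and an attribute `percent`
#'   (each component as a percentage of SST).
#' @examples
#' sim <- simulate_table(S = 12, r = 2, m = 3, seed = 1)
#' anoqe(sim$table, dist_sqrt_branch(sim$tree))
#' @export
anoqe <- function(x, d) {
  stopifnot(inherits(x, "community_table"))
  d <- align_dist(d, rownames(x$props))
  D <- d^2 / 2
  agg <- aggregate_proportions(x)
  cw <- x$community_weights

  SST <- quadratic_entropy(agg$p_global, D)
  SSW <- sum(vapply(seq_along(cw), function(j)
    cw[j] * quadratic_entropy(x$props[, j], D), numeric(1)))
  SSC <- SST - SSW
  SSA <- SST - sum(vapply(seq_along(x$levelA_weights), function(i)
    x$levelA_weights[i] * quadratic_entropy(agg$P_A[, i], D), numeric(1)))
  SSB <- SST - sum(vapply(seq_along(x$levelB_weights), function(j)
    x$levelB_weights[j] * quadratic_entropy(agg$P_B[, j], D), numeric(1)))
  SSAB <- SSC - SSA - SSB

  comp <- c(SST = SST, SSW = SSW, SSC = SSC, SSA = SSA, SSB = SSB, SSAB = SSAB)
  tiny <- comp < 0 & comp > -1e-12
  comp[tiny] <- 0
  pct <- if (SST > 0) 100 * comp / comp[["SST"]] else comp * NA
  structure(comp, percent = pct, class = "anoqe")
}

#' @export
print.anoqe <- function(x, digits = 6, ...) {
  cat("Analysis of quadratic entropy (ANOQE)\n")
  tab <- data.frame(component = c("total (SST)", "within communities (SSW)",
                                  "among communities (SSC)",
                                  "factor A main effect (SSA)",
                                  "factor B main effect (SSB)",
                                  "interaction (SSAB)"),
                    QE = signif(unclass(x), digits),
                    percent = round(attr(x, "percent"), 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

## align a dissimilarity matrix to the table's species order
align_dist <- function(d, species) {
  d <- validate_dist(d)
  if (!all(species %in% rownames(d))) {
    stop("species missing from dissimilarity matrix: ",
         paste(utils::head(setdiff(species, rownames(d)), 5), collapse = ", "))
  }
  d[species, species, drop = FALSE]
}
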