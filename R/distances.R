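## Species dissimilarity constructors and the Euclidean-embeddability check.
##
## DPCoA requires a Euclidean dissimilarity matrix Delta: S points must embed
## in some Euclidean space so that pairwise distances equal delta_kl.  The
## constructors below cover the standard phylogenetic and taxonomic choices;
## is_euclidean() is the predicate the fitting functions rely on.

#' Nodal distance between the leaves of a phylogeny
#'
#' Counts the number of edges on the (unique) path connecting each pair of
#' leaves.  This topology-only metric treats every edge as length one, so the
#' result is an integer matrix in edge units.
#'
#' A rooted binary tree has a degree-2 root node; by default the two root
#' edges are counted separately (the root is treated as a real node), so the
#' two leaves of a cherry through the root are at distance 2.  Set
#' `collapse_root = TRUE` to merge the two root edges into one before
#' counting, which reproduces the unrooted reading of the same topology.
#'
#' Nodal distances are not guaranteed to be Euclidean-embeddable; check with
#' [is_euclidean()] before ordination (the fit functions do this for you).
#'
#' @param tree an [ape::phylo] tree (rooted or unrooted, >= 2 uniquely
#'   labelled leaves); branch lengths, if present, are ignored.
#' @param collapse_root logical; collapse a degree-2 root before counting.
#' @return a labelled S x S symmetric numeric matrix of edge counts with zero
#'   diagonal.
#' @seealso [dist_sqrt_branch()], [dist_taxonomic()], [is_euclidean()]
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' dist_nodal(tr)
#' @export
dist_nodal <- function(tree, collapse_root = FALSE) {
  tree <- check_tree(tree)
  if (collapse_root && ape::is.rooted(tree) && length(tree$tip.label) > 2L) {
    tree <- ape::unroot(tree)
  }
  tree$edge.length <- rep(1, nrow(tree$edge))
  d <- ape::cophenetic.phylo(tree)
  validate_dist(d[sort(rownames(d)), sort(rownames(d)), drop = FALSE])
}

#' Square-root patristic distance between the leaves of a phylogeny
#'
#' The dissimilarity between two species is the square root of the sum of
#' branch lengths on the shortest path connecting them.  This transform of
#' the patristic distance is always Euclidean-embeddable for a tree with
#' nonnegative branch lengths, which makes it the recommended phylogenetic
#' input for DPCoA.
#'
#' @param tree an [ape::phylo] tree with nonnegative branch lengths on all
#'   edges.
#' @return a labelled S x S symmetric matrix, units = sqrt(branch-length).
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:3);")
#' dist_sqrt_branch(tr)  # sqrt(4) = 2
#' @export
dist_sqrt_branch <- function(tree) {
  tree <- check_tree(tree)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; use dist_nodal() for topology-only distances")
  }
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  d <- sqrt(ape::cophenetic.phylo(tree))
  validate_dist(d[sort(rownames(d)), sort(rownames(d)), drop = FALSE])
}

#' Taxonomic distance from an ordered classification
#'
#' Species in the same genus are at distance 1, species in the same family
#' but different genera at distance 2, and so on: the distance is the 1-based
#' index of the finest taxonomic rank the two species share.  Species sharing
#' none of the `L` listed ranks are placed at `L + 1` (they meet only at the
#' implicit root).  The result is ultrametric.
#'
#' @param taxonomy a data.frame whose rownames (or first character column
#'   named `"species"`) are species labels, remaining columns the rank labels
#'   ordered finest (e.g. genus) to coarsest; no missing entries allowed.
#' @return a labelled S x S symmetric integer-valued matrix.
#' @examples
#' tax <- data.frame(genus  = c("Parus", "Parus", "Sylvia"),
#'                   family = c("Paridae", "Paridae", "Sylviidae"),
#'                   row.names = c("sp1", "sp2", "sp3"))
#' dist_taxonomic(tax)
#' @export
dist_taxonomic <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  if ("species" %in% names(taxonomy)) {
    rownames(taxonomy) <- as.character(taxonomy$species)
    taxonomy$species <- NULL
  }
  if (ncol(taxonomy) < 1L) stop("taxonomy needs at least one rank column")
  labs <- rownames(taxonomy)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("taxonomy must have unique species rownames")
  }
  mat <- as.matrix(taxonomy)
  mode(mat) <- "character"
  if (anyNA(mat) || any(!nzchar(mat))) {
    stop("ragged taxonomy: every species needs a complete label path")
  }
  S <- nrow(mat)
  L <- ncol(mat)
  d <- matrix(0, S, S, dimnames = list(labs, labs))
  for (k in seq_len(S - 1L)) {
    for (l in seq.int(k + 1L, S)) {
      eq <- mat[k, ] == mat[l, ]
      ## trailing run of matches on the coarse side; finest shared rank
      ## is L + 1 - run (ultrametric for any labelling)
      run <- 0L
      for (j in L:1) {
        if (!eq[j]) break
        run <- run + 1L
      }
      d[k, l] <- d[l, k] <- L + 1L - run
    }
  }
  validate_dist(d)
}

#' Equidistant species dissimilarity
#'
#' All distinct species pairs at constant distance `c`.  With `c = sqrt(2)`
#' the induced DPCoA coincides with non-symmetrical correspondence analysis,
#' which makes this constructor the bridge between distance-aware and
#' classical (species-identity only) diversity analyses.
#'
#' @param labels character vector of species labels.
#' @param c positive constant distance.
#' @return a labelled S x S matrix with `c` off the diagonal.
#' @export
dist_equidistant <- function(labels, c = sqrt(2)) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate species labels")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("constant distance 'c' must be a single positive number")
  }
  S <- length(labels)
  d <- matrix(c, S, S, dimnames = list(labels, labels))
  diag(d) <- 0
  validate_dist(d)
}

#' Is a dissimilarity matrix Euclidean-embeddable?
#'
#' Tests whether S points can be placed in a Euclidean space with pairwise
#' distances `d`.  The classical Gower criterion is used: the double-centred
#' matrix of `-d^2/2` (uniform centering) must be positive semi-definite.
#' Eigenvalues down to `-tol` times the largest eigenvalue are tolerated as
#' numerical noise.
#'
#' @param d square symmetric nonnegative matrix with zero diagonal.
#' @param tol relative tolerance on the smallest eigenvalue.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_euclidean(dist_equidistant(letters[1:4]))           # TRUE
#' bad <- matrix(c(0, 1, 1, 1, 0, 2.5, 1, 2.5, 0), 3, 3)  # breaks the
#' is_euclidean(bad)                                      # triangle inequality
#' @export
is_euclidean <- function(d, tol = 1e-10) {
  d <- validate_dist(d)
  S <- nrow(d)
  if (S < 2L) return(TRUE)
  g <- gower_center(d, rep(1 / S, S))
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  top <- max(ev, 0)
  if (top == 0) return(TRUE)  # all distances zero
  min(ev) >= -tol * top
}

## -- internal helpers ------------------------------------------------------

## Gower double-centering of -d^2/2 with centering weights w (sum 1):
## G = -(1/2) (I - 1 w^t) D2 (I - w 1^t).  G w = 0 and
## G_kk + G_ll - 2 G_kl = d_kl^2 for any w.
gower_center <- function(d, w) {
  d2 <- d * d
  m1 <- as.vector(d2 %*% w)
  m0 <- sum(w * m1)
  -0.5 * (d2 - outer(m1, rep(1, length(w))) -
            outer(rep(1, length(w)), m1) + m0)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape \"phylo\" object")
  if (length(tree$tip.label) < 2L) {
    stop("degenerate tree: at least two leaves are required")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  tree
}

validate_dist <- function(d, what = "dissimilarity matrix") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(what, " must be square")
  if (!is.numeric(d) || anyNA(d)) stop(what, " must be numeric with no NA")
  if (any(d < 0)) stop(what, " must be nonnegative")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(d))) {
    stop(what, " must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop(what, " must have a zero diagonal")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("sp", seq_len(nrow(d)))
  }
  colnames(d) <- rownames(d)
  d
}
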