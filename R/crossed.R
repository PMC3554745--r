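## Crossed-DPCoA: the fitting function and its methods.
##
## Starting from the DPCoA space (species at PCoA coordinates, communities
## and factor levels at weighted centroids), the conditional effect of the
## target factor given the co-factor is displayed by
##   main   - principal axes of the target factor's level cloud (no
##            adjustment; the preliminary analysis of a main effect),
##   v1     - mean-based: co-factor level centroids moved to the origin
##            (communities re-centred), then principal axes of the target
##            level cloud, whose positions are unchanged; eigenvalues sum to
##            the target factor's SS component,
##   v2     - structure-based: every point projected onto the orthogonal
##            complement of the subspace spanned by the co-factor's level
##            cloud before the principal axes of the target cloud are taken;
##            inertia can only shrink, and vanishes for any target structure
##            lying inside the co-factor subspace.

#' Crossed-factor double principal coordinate analysis
#'
#' Fits the DPCoA ordination of a balanced two-factor community table and
#' analyses the effect of one factor conditionally on the other.  This is
#' the package's central fitting function; [anoqe()] gives the matching
#' diversity partition and is carried in the fitted object.
#'
#' Exactly one of `dist`, `tree` or `taxonomy` must describe the species
#' dissimilarities.  A tree is converted with [dist_sqrt_branch()] (default)
#' or [dist_nodal()]; a taxonomy with [dist_taxonomic()].  The matrix must
#' be Euclidean-embeddable (hard error otherwise).
#'
#' For `version = "v1"` the eigenvalues sum to the target factor's SS
#' component and the re-centred community cloud has inertia
#' `SS(target) + SS(interaction)`.  For `version = "v2"` both inertias can
#' only be smaller, and the co-factor's projected level points are at the
#' origin; v2 requires the species space to have more principal axes than
#' the co-factor's level cloud.  The two versions agree when the two
#' factors structure the space in orthogonal directions.
#'
#' @param comm a [community_table()] object, or a species x community matrix
#'   (then `design` is required).
#' @param design design data.frame (community, A, B); ignored when `comm`
#'   is already a `community_table`.
#' @param dist Euclidean species dissimilarity matrix `Delta`.
#' @param tree an [ape::phylo] phylogeny (alternative to `dist`).
#' @param taxonomy a taxonomy data.frame (alternative to `dist`).
#' @param tree_metric `"sqrt_branch"` or `"nodal"`, used when `tree` is given.
#' @param factor target factor, `"A"` or `"B"`.
#' @param version `"v1"` (mean-based), `"v2"` (structure-based), or `"main"`
#'   (principal axes of the target factor's level cloud, unadjusted).
#' @param transform optional importance-value transform before
#'   normalisation, see [transform_values()].
#' @param presence_absence reduce the table to presence/absence first.
#' @param tol relative eigenvalue tolerance (axis retention, Euclidean check,
#'   co-factor subspace rank).
#' @param q number of axes shown by default in print/plot (all retained
#'   axes are stored and written).
#' @return an object of class `"crossed_dpcoa"`; see Details.  Components
#'   include `eig` (axis eigenvalues of the target level cloud),
#'   `percent` (share of the retained-axis total), `percent_ss` (share of
#'   the exact SS reference), `scores` (species, communities, levelsA,
#'   levelsB), `partition` (the [anoqe()] object), `inertia_report`, and
#'   `space` (the underlying [dpcoa_space()]).
#' @examples
#' sim <- simulate_table(S = 16, r = 3, m = 3, effect_A = 1.5, seed = 7)
#' fit <- crossed_dpcoa(sim$table, tree = sim$tree, factor = "A", version = "v1")
#' fit
#' head(scores(fit, display = "communities"))
#' @seealso [anoqe()], [dpcoa_space()], [write_results()]
#' @export
crossed_dpcoa <- function(comm, design = NULL, dist = NULL, tree = NULL,
                          taxonomy = NULL,
                          tree_metric = c("sqrt_branch", "nodal"),
                          factor = c("A", "B"),
                          version = c("v1", "v2", "main"),
                          transform = c("none", "sqrt", "log1p"),
                          presence_absence = FALSE,
                          tol = 1e-9, q = 2) {
  version <- match.arg(version)
  factor <- match.arg(factor)
  tree_metric <- match.arg(tree_metric)
  transform <- match.arg(transform)

  x <- if (inherits(comm, "community_table")) comm else {
    if (is.null(design)) stop("a design table is required with a raw community matrix")
    community_table(comm, design)
  }
  if (presence_absence) x <- presence_absence(x)
  if (transform != "none") x <- transform_values(x, transform)

  n_src <- sum(!is.null(dist), !is.null(tree), !is.null(taxonomy))
  if (n_src != 1L) stop("supply exactly one of 'dist', 'tree' or 'taxonomy'")
  d <- if (!is.null(dist)) validate_dist(dist)
       else if (!is.null(tree)) switch(tree_metric,
                                       sqrt_branch = dist_sqrt_branch(tree),
                                       nodal = dist_nodal(tree))
       else dist_taxonomic(taxonomy)
  d <- align_dist(d, rownames(x$props))

  agg <- aggregate_proportions(x)
  space <- dpcoa_space(d, w = agg$p_global, tol = tol)
  part <- anoqe(x, d)

  X <- space$coords
  Y_C <- crossprod(x$props, X)
  Y_A <- crossprod(agg$P_A, X)
  Y_B <- crossprod(agg$P_B, X)

  if (factor == "A") {
    Y_t <- Y_A; Y_c <- Y_B
    tw <- x$levelA_weights; cw_co <- x$levelB_weights
    co_of_comm <- x$design$B; lev_co <- x$levelsB
    ss_main <- part[["SSA"]]; ss_total <- part[["SSA"]] + part[["SSAB"]]
  } else {
    Y_t <- Y_B; Y_c <- Y_A
    tw <- x$levelB_weights; cw_co <- x$levelA_weights
    co_of_comm <- x$design$A; lev_co <- x$levelsA
    ss_main <- part[["SSB"]]; ss_total <- part[["SSB"]] + part[["SSAB"]]
  }

  report <- list()
  if (version == "main") {
    sp_amb <- X
    comm_amb <- Y_C
    t_amb <- Y_t
    c_amb <- Y_c
    ss_ref <- ss_main
  } else {
    ## v1 re-centring: co-factor level centroids to the origin; the target
    ## level positions are unchanged
    comm_amb <- Y_C - Y_c[match(co_of_comm, lev_co), , drop = FALSE]
    sp_amb <- X
    t_amb <- Y_t
    c_amb <- Y_c - Y_c  # co-factor levels at the origin after re-centring
    if (version == "v2") {
      U_B <- cloud_axes(Y_c, cw_co, tol)$vectors
      dimGB <- ncol(U_B)
      dimGX <- ncol(X)
      if (dimGX <= dimGB) {
        stop("structure-based analysis impossible: the species space has ",
             dimGX, " principal axes, which does not exceed the ", dimGB,
             " principal axes of the co-factor's level cloud ",
             "(dim G_X must be greater than dim G_B)")
      }
      proj <- function(M) M - (M %*% U_B) %*% t(U_B)
      sp_amb <- proj(sp_amb)
      comm_amb <- proj(comm_amb)
      t_amb <- proj(t_amb)
      c_amb <- proj(Y_c)  # ~0 by construction
      report$dim_GX <- dimGX
      report$dim_GB <- dimGB
    }
    report$level_cloud_inertia <- sum(tw * rowSums(t_amb^2))
    report$community_cloud_inertia <-
      sum(x$community_weights * rowSums(comm_amb^2))
    report$ss_main <- ss_main
    report$ss_main_plus_interaction <- ss_total
    ss_ref <- ss_main
  }

  ax <- cloud_axes(t_amb, tw, tol)
  if (!ncol(ax$vectors)) {
    warning("degenerate ", if (version == "main") "level" else "target-level",
            " cloud: all level profiles coincide; no axes retained")
  }
  U <- ax$vectors
  eig <- ax$values

  sc_species <- orient(sp_amb %*% U)
  flip <- attr(sc_species, "flip")
  sc <- list(
    species = sc_species,
    communities = sweep_flip(comm_amb %*% U, flip),
    levelsA = sweep_flip((if (factor == "A") t_amb else c_amb) %*% U, flip),
    levelsB = sweep_flip((if (factor == "A") c_amb else t_amb) %*% U, flip)
  )
  axnames <- if (ncol(U)) paste0("CDP", seq_len(ncol(U))) else character(0)
  for (nm in names(sc)) colnames(sc[[nm]]) <- axnames
  rownames(sc$species) <- rownames(x$props)
  rownames(sc$communities) <- colnames(x$props)
  rownames(sc$levelsA) <- x$levelsA
  rownames(sc$levelsB) <- x$levelsB

  structure(list(
    version = version, factor = factor,
    eig = eig,
    percent = if (length(eig) && sum(eig) > 0) 100 * eig / sum(eig) else eig,
    percent_ss = if (length(eig) && ss_ref > 0) 100 * eig / ss_ref else eig * NA,
    ss_ref = ss_ref,
    scores = sc,
    partition = part,
    inertia_report = report,
    space = space, table = x, q = q,
    call = match.call()
  ), class = "crossed_dpcoa")
}

## principal axes of a weighted, origin-centred cloud in ambient coordinates:
## eigen of t(Y) diag(w) Y; vectors are orthonormal in the ambient metric
cloud_axes <- function(Y, w, tol) {
  w <- w / sum(w)
  C <- crossprod(Y, Y * w)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  keep <- which(e$values > tol * max(e$values, .Machine$double.eps))
  list(values = e$values[keep],
       vectors = e$vectors[, keep, drop = FALSE])
}

orient <- function(M) {
  flip <- rep(1, ncol(M))
  if (ncol(M)) {
    for (a in seq_len(ncol(M))) {
      i <- which.max(abs(M[, a]))
      if (length(i) && M[i, a] < 0) flip[a] <- -1
    }
  }
  M <- sweep(M, 2, flip, "*")
  attr(M, "flip") <- flip
  M
}

sweep_flip <- function(M, flip) {
  if (!ncol(M)) return(M)
  sweep(M, 2, flip, "*")
}

#' Main-effect DPCoA of one factor
#'
#' The preliminary analysis: principal axes of the chosen factor's level
#' cloud in the DPCoA space, with species and communities projected onto
#' them.  Equivalent to applying DPCoA to the species x factor-level table
#' of aggregated proportions.  Eigenvalues sum to that factor's SS
#' component.  A convenience wrapper around
#' `crossed_dpcoa(..., version = "main")`.
#'
#' @inheritParams crossed_dpcoa
#' @param ... passed on to [crossed_dpcoa()].
#' @return a `"crossed_dpcoa"` object with `version = "main"`.
#' @export
main_effect_dpcoa <- function(comm, factor = c("A", "B"), ...) {
  factor <- match.arg(factor)
  crossed_dpcoa(comm, factor = factor, version = "main", ...)
}

#' @export
print.crossed_dpcoa <- function(x, ...) {
  lab <- switch(x$version,
                main = paste0("main effect of factor ", x$factor),
                v1 = paste0("conditional effect of factor ", x$factor,
                            " (mean-based, version 1)"),
                v2 = paste0("conditional effect of factor ", x$factor,
                            " (structure-based, version 2)"))
  cat("Crossed-DPCoA: ", lab, "\n", sep = "")
  cat("  species: ", nrow(x$scores$species),
      "   communities: ", nrow(x$scores$communities),
      "   axes retained: ", length(x$eig), "\n", sep = "")
  k <- min(x$q, length(x$eig))
  if (k) {
    for (a in seq_len(k)) {
      cat(sprintf("  axis %d: eigenvalue %.6g  (%.1f%% of retained, %.1f%% of SS(%s))\n",
                  a, x$eig[a], x$percent[a], x$percent_ss[a], x$factor))
    }
  } else cat("  (no axes retained)\n")
  invisible(x)
}

#' @export
summary.crossed_dpcoa <- function(object, ...) {
  structure(list(fit = object), class = "summary.crossed_dpcoa")
}

#' @export
print.summary.crossed_dpcoa <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n")
  print(f$partition)
  if (length(f$inertia_report)) {
    cat("\nInertia report\n")
    for (nm in names(f$inertia_report)) {
      cat(sprintf("  %-28s %.8g\n", nm, f$inertia_report[[nm]]))
    }
  }
  if (length(f$eig)) {
    cat("\nAxes\n")
    tab <- data.frame(axis = seq_along(f$eig),
                      eigenvalue = f$eig,
                      pct_retained = round(f$percent, 2),
                      pct_of_SS = round(f$percent_ss, 2))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Extract ordination scores from a crossed-DPCoA fit
#'
#' @param x a `"crossed_dpcoa"` object.
#' @param choices axes to return.
#' @param display one of `"species"`, `"communities"` (alias `"sites"`),
#'   `"levelsA"`, `"levelsB"`.
#' @param ... ignored.
#' @return a numeric matrix of scores.
#' @importFrom vegan scores
#' @export
scores.crossed_dpcoa <- function(x, choices = NULL,
                                 display = c("communities", "species",
                                             "levelsA", "levelsB", "sites"),
                                 ...) {
  display <- match.arg(display)
  if (display == "sites") display <- "communities"
  sc <- x$scores[[display]]
  if (is.null(choices)) choices <- seq_len(ncol(sc))
  choices <- choices[choices <= ncol(sc)]
  sc[, choices, drop = FALSE]
}

#' Plot a crossed-DPCoA ordination
#'
#' Displays communities and the target factor's level positions (and
#' optionally species) on two axes, labelled with the share of variance.
#'
#' @param x a `"crossed_dpcoa"` object.
#' @param choices the two axes to draw.
#' @param what which clouds to draw.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crossed_dpcoa <- function(x, choices = c(1, 2),
                               what = c("communities", "levels", "species"),
                               ...) {
  if (length(x$eig) < 1) {
    warning("nothing to plot: no axes retained")
    return(invisible(x))
  }
  choices <- choices[choices <= length(x$eig)]
  if (length(choices) == 1L) choices <- c(choices, choices)
  lev <- x$scores[[paste0("levels", x$factor)]][, choices, drop = FALSE]
  com <- x$scores$communities[, choices, drop = FALSE]
  sp <- x$scores$species[, choices, drop = FALSE]
  pts <- rbind(lev, com, if ("species" %in% what) sp)
  xlab <- sprintf("Axis %d (%.1f%%)", choices[1], x$percent[choices[1]])
  ylab <- sprintf("Axis %d (%.1f%%)", choices[2], x$percent[choices[2]])
  graphics::plot(pts[, 1], pts[, 2], type = "n", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  if ("species" %in% what) {
    graphics::points(sp[, 1], sp[, 2], pch = 3, col = "grey60", cex = 0.6)
  }
  if ("communities" %in% what) {
    graphics::points(com[, 1], com[, 2], pch = 21, bg = "white")
    graphics::text(com[, 1], com[, 2], rownames(com), pos = 3, cex = 0.6,
                   col = "grey30")
  }
  if ("levels" %in% what) {
    graphics::points(lev[, 1], lev[, 2], pch = 19, cex = 1.2)
    graphics::text(lev[, 1], lev[, 2], rownames(lev), pos = 3, font = 2)
  }
  invisible(x)
}
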