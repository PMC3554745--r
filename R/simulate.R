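## Synthetic balanced factorial community data on a random phylogeny, with
## controllable main and interaction effects applied to tree-structured
## clades.  Every stage of the pipeline can be exercised without external
## data.

## run `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Random phylogeny with positive branch lengths
#'
#' A random binary topology on `S` leaves labelled `sp1...spS`, with
#' uniform(0, 1] branch lengths.  Deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param S number of leaves (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
random_tree <- function(S, seed = 1L) {
  if (!is.numeric(S) || S < 2L) stop("S must be at least 2")
  with_seed(seed, {
    tr <- ape::rtree(S, tip.label = paste0("sp", seq_len(S)))
    ## guard against zero-length edges
    tr$edge.length <- pmax(tr$edge.length, 1e-3)
    tr
  })
}

#' Simulate a balanced factorial community table on a random phylogeny
#'
#' Baseline species log-abundances are i.i.d. standard normal.  Each level
#' of factor A adds a shift of magnitude `effect_A` to a level-specific
#' clade of the tree (a contiguous block of leaves in cladewise order), and
#' analogously for factor B and, per cell, for the interaction.  A softmax
#' maps log-abundances to strictly positive proportions; with finite
#' `n_individuals` a multinomial sample of that depth is drawn per community
#' and renormalised, introducing sampling noise and zeros.
#'
#' `clade_assignment` controls where the clades sit: `"disjoint"` draws the
#' A- and B-clades from disjoint parts of the tree (so with only an A effect
#' the B and interaction components are exactly zero at infinite depth);
#' `"overlapping"` draws them independently; `"collinear"` reuses the
#' B-clade patterns for the A levels, so the A structure lies (to first
#' order) inside the subspace spanned by the B levels — the situation the
#' structure-based version 2 is designed to reveal.
#'
#' The defaults emulate the shape of a two-region factorial survey: a few
#' dozen species, `r = 5` levels of factor A crossed with `m = 6` levels of
#' factor B, exact proportions (infinite sampling depth), and moderate
#' clade-level shifts.
#'
#' @param S species count.
#' @param r,m level counts of factors A and B.
#' @param effect_A,effect_B,effect_AB nonnegative log-scale shift magnitudes.
#' @param n_individuals multinomial sampling depth per community, or `Inf`
#'   for exact proportions.
#' @param clade_assignment `"disjoint"`, `"overlapping"` or `"collinear"`.
#' @param seed integer seed; one stream per run, with fixed sub-seeds for
#'   the tree, the abundances and the sampling stage.
#' @return a list with `table` (a [community_table()]), `tree` (the
#'   [ape::phylo]), `truth` (per-level target species), and `config`.
#' @examples
#' sim <- simulate_table(S = 12, r = 2, m = 2, effect_A = 2, seed = 42)
#' anoqe(sim$table, dist_sqrt_branch(sim$tree))
#' @export
simulate_table <- function(S = 40, r = 5, m = 6,
                           effect_A = 1, effect_B = 1, effect_AB = 0.5,
                           n_individuals = Inf,
                           clade_assignment = c("disjoint", "overlapping",
                                                "collinear"),
                           seed = 1L) {
  clade_assignment <- match.arg(clade_assignment)
  if (S < 2L || r < 2L || m < 2L) stop("need S >= 2, r >= 2, m >= 2")
  if (any(c(effect_A, effect_B, effect_AB) < 0)) stop("effects must be >= 0")
  if (!(is.infinite(n_individuals) || n_individuals >= 1)) {
    stop("n_individuals must be >= 1 or Inf")
  }

  subseeds <- with_seed(seed, sample.int(2147483647L, 3L))
  tree <- random_tree(S, seed = subseeds[1])

  ## leaves in cladewise visiting order: contiguous blocks are clade-like
  ord <- local({
    tr <- ape::reorder.phylo(tree, "cladewise")
    tips <- tr$edge[tr$edge[, 2] <= S, 2]
    tr$tip.label[tips]
  })

  blocks <- function(labels, k) {
    idx <- split(seq_along(labels), cut(seq_along(labels), k, labels = FALSE))
    lapply(idx, function(i) labels[i])
  }

  if (clade_assignment == "disjoint") {
    if (S < r + m + 2L) {
      stop("clade_assignment = \"disjoint\" infeasible: need S >= r + m + 2 ",
           "to give every level its own clade")
    }
    half <- floor(S / 2)
    cladesA <- blocks(ord[seq_len(half)], r)
    cladesB <- blocks(ord[seq.int(half + 1L, S)], m)
  } else {
    cladesB <- blocks(ord, m)
    if (clade_assignment == "collinear") {
      cladesA <- cladesB[((seq_len(r) - 1L) %% m) + 1L]
    } else {
      cladesA <- with_seed(subseeds[2] %/% 2L + 1L, lapply(seq_len(r), function(i) {
        len <- max(1L, floor(S / r))
        start <- sample.int(S - len + 1L, 1L)
        ord[start:(start + len - 1L)]
      }))
    }
  }

  levA <- paste0("A", seq_len(r))
  levB <- paste0("B", seq_len(m))
  comms <- as.vector(outer(levA, levB, paste, sep = "."))
  design <- data.frame(community = comms,
                       A = rep(levA, times = m),
                       B = rep(levB, each = r),
                       stringsAsFactors = FALSE)

  sim <- with_seed(subseeds[2], {
    base <- stats::rnorm(S)
    names(base) <- tree$tip.label
    cladesAB <- if (effect_AB > 0) {
      lapply(seq_len(r * m), function(ij) {
        len <- max(1L, floor(S / max(r, m)))
        start <- sample.int(S - len + 1L, 1L)
        ord[start:(start + len - 1L)]
      })
    } else NULL
    lp <- matrix(base, nrow = S, ncol = r * m,
                 dimnames = list(tree$tip.label, comms))
    for (col in seq_len(r * m)) {
      i <- match(design$A[col], levA)
      j <- match(design$B[col], levB)
      lp[cladesA[[i]], col] <- lp[cladesA[[i]], col] + effect_A
      lp[cladesB[[j]], col] <- lp[cladesB[[j]], col] + effect_B
      if (!is.null(cladesAB)) {
        lp[cladesAB[[col]], col] <- lp[cladesAB[[col]], col] + effect_AB
      }
    }
    list(lp = lp, cladesAB = cladesAB)
  })

  props <- apply(sim$lp, 2, function(v) {
    e <- exp(v - max(v))
    e / sum(e)
  })
  rownames(props) <- tree$tip.label

  values <- if (is.infinite(n_individuals)) props else {
    with_seed(subseeds[3], {
      counts <- apply(props, 2, function(p)
        stats::rmultinom(1, size = as.integer(n_individuals), prob = p))
      rownames(counts) <- rownames(props)
      counts
    })
  }

  tab <- community_table(values, design)
  names(cladesA) <- levA
  names(cladesB) <- levB
  list(table = tab, tree = tree,
       truth = list(clades_A = cladesA, clades_B = cladesB,
                    clades_AB = sim$cladesAB),
       config = list(S = S, r = r, m = m, effect_A = effect_A,
                     effect_B = effect_B, effect_AB = effect_AB,
                     n_individuals = n_individuals,
                     clade_assignment = clade_assignment, seed = seed))
}
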