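## Factorial community tables: species x community importance values plus the
## crossed A/B design, normalised to proportions with the stratum weights the
## quadratic-entropy decomposition needs.

#' Build a factorial community table
#'
#' Validates a species x community table of nonnegative importance values
#' (densities, abundances, biomass, cover...) against a complete balanced
#' two-factor design (exactly one community per cell of factor A x factor B),
#' and normalises each community column to proportions.
#'
#' Species whose proportion is zero in every community carry zero weight in
#' the DPCoA metric and are dropped with a warning.  Community weights
#' default to even (`1/(r*m)`); a user-supplied weight vector is accepted and
#' propagated to the factor-level weights as marginal sums.  The exact
#' three-way split of among-community diversity holds for product-form
#' weights (even weights included); non-product weights draw a warning.
#'
#' @param comm numeric matrix (or data.frame), species as rows, communities
#'   as columns, nonnegative, no all-zero column; dimnames required.
#' @param design data.frame with columns `community`, `A`, `B` (extra names
#'   tolerated: the first three columns are used) mapping every community
#'   label to one level of each factor.
#' @param community_weights optional positive weights for the communities
#'   (recycled order = `colnames(comm)`), normalised to sum 1.
#' @return an object of class `"community_table"`: a list with elements
#'   `raw`, `props` (S x rm), `design`, `levelsA`, `levelsB`,
#'   `community_weights`, `levelA_weights`, `levelB_weights`.
#' @seealso [read_community_table()], [aggregate_proportions()],
#'   [presence_absence()], [transform_values()]
#' @export
community_table <- function(comm, design, community_weights = NULL) {
  comm <- as.matrix(comm)
  if (!is.numeric(comm) || anyNA(comm)) stop("community table must be numeric with no NA")
  if (any(comm < 0)) stop("community table entries must be nonnegative")
  if (is.null(rownames(comm)) || is.null(colnames(comm))) {
    stop("community table needs species rownames and community colnames")
  }
  if (anyDuplicated(rownames(comm))) stop("duplicate species labels")
  if (anyDuplicated(colnames(comm))) stop("duplicate community labels")

  design <- as.data.frame(design)
  if (ncol(design) < 3L) stop("design needs columns community, A, B")
  design <- design[, 1:3]
  names(design) <- c("community", "A", "B")
  design$community <- as.character(design$community)
  design$A <- as.character(design$A)
  design$B <- as.character(design$B)
  if (anyDuplicated(design$community)) stop("duplicate community in design")

  missing_in_design <- setdiff(colnames(comm), design$community)
  if (length(missing_in_design)) {
    stop("communities missing from design: ", paste(missing_in_design, collapse = ", "))
  }
  missing_in_table <- setdiff(design$community, colnames(comm))
  if (length(missing_in_table)) {
    stop("design communities missing from table: ",
         paste(missing_in_table, collapse = ", "))
  }
  ## bind by label, not order
  design <- design[match(colnames(comm), design$community), ]

  levA <- sort(unique(design$A))
  levB <- sort(unique(design$B))
  r <- length(levA)
  m <- length(levB)
  cell <- paste(design$A, design$B, sep = "\r")
  if (anyDuplicated(cell)) stop("unbalanced design: duplicated (A,B) cell")
  if (nrow(design) != r * m) {
    stop("unbalanced design: expected one community per cell (", r, " x ", m,
         " = ", r * m, "), got ", nrow(design))
  }

  cs <- colSums(comm)
  if (any(cs == 0)) {
    stop("empty community: column(s) ",
         paste(colnames(comm)[cs == 0], collapse = ", "), " sum to 0")
  }
  props <- sweep(comm, 2, cs, "/")

  n <- ncol(comm)
  if (is.null(community_weights)) {
    cw <- rep(1 / n, n)
  } else {
    cw <- as.numeric(community_weights)
    if (length(cw) != n || any(!is.finite(cw)) || any(cw <= 0)) {
      stop("community_weights must be ", n, " positive numbers")
    }
    cw <- cw / sum(cw)
  }
  names(cw) <- colnames(comm)

  aw <- vapply(levA, function(a) sum(cw[design$A == a]), numeric(1))
  bw <- vapply(levB, function(b) sum(cw[design$B == b]), numeric(1))
  ## exact ANOQE three-way split needs c_ij = a_i * b_j
  prod_w <- aw[design$A] * bw[design$B]
  if (max(abs(prod_w - cw)) > 1e-8) {
    warning("community weights are not of product form a_i * b_j; ",
            "the SS(C) = SS(A) + SS(B) + SS(A,B) split is approximate")
  }

  x <- structure(list(raw = comm, props = props, design = design,
                      levelsA = levA, levelsB = levB,
                      community_weights = cw,
                      levelA_weights = aw, levelB_weights = bw),
                 class = "community_table")
  drop_zero_species(x)
}

drop_zero_species <- function(x) {
  glob <- as.vector(x$props %*% x$community_weights)
  zero <- glob <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " species with zero global proportion: ",
            paste(utils::head(rownames(x$props)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    x$raw <- x$raw[!zero, , drop = FALSE]
    x$props <- x$props[!zero, , drop = FALSE]
    if (nrow(x$props) < 2L) stop("fewer than two species remain")
    x$props <- sweep(x$props, 2, colSums(x$props), "/")
  }
  x
}

#' @export
print.community_table <- function(x, ...) {
  cat("Factorial community table\n")
  cat("  species:    ", nrow(x$props), "\n", sep = "")
  cat("  communities:", ncol(x$props), " (", length(x$levelsA), " levels of A x ",
      length(x$levelsB), " levels of B)\n", sep = "")
  cat("  factor A:   ", paste(x$levelsA, collapse = ", "), "\n", sep = "")
  cat("  factor B:   ", paste(x$levelsB, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a community table and its crossed design from delimited files
#'
#' The community table has species as rows (first column or rownames) and
#' communities as columns; the design file maps each community label to one
#' level of factor A and one level of factor B.  The field separator is
#' sniffed (tab vs comma) from the header line unless given.
#'
#' @param table_path path to the species x community table (TSV or CSV).
#' @param design_path path to the design table with columns community,
#'   factor A level, factor B level (TSV or CSV).
#' @param sep `"auto"` (default), `"\t"` or `","`.
#' @param ... passed to [community_table()] (e.g. `community_weights`).
#' @return a [community_table()] object.
#' @export
read_community_table <- function(table_path, design_path, sep = "auto", ...) {
  comm <- utils::read.table(table_path, header = TRUE, sep = sniff_sep(table_path, sep),
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
  design <- utils::read.table(design_path, header = TRUE,
                              sep = sniff_sep(design_path, sep),
                              check.names = FALSE, stringsAsFactors = FALSE)
  community_table(as.matrix(comm), design, ...)
}

#' Write a community table and its design to TSV files
#'
#' Writes the proportion matrix (so a read/write/read round trip reproduces
#' proportions exactly) and the design.
#'
#' @param x a [community_table()] object.
#' @param table_path,design_path output paths.
#' @return `x`, invisibly.
#' @export
write_community_table <- function(x, table_path, design_path) {
  stopifnot(inherits(x, "community_table"))
  df <- data.frame(species = rownames(x$props), x$props,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

sniff_sep <- function(path, sep) {
  if (!identical(sep, "auto")) return(sep)
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_com > n_tab) "," else "\t"
}

#' Reduce a community table to presence/absence proportions
#'
#' Every species present in a community gets proportion `1/S_ij`, where
#' `S_ij` is the number of species observed in community `ij`; absent species
#' stay at zero.  Idempotent.
#'
#' @param x a [community_table()] object.
#' @return a new `community_table` with even within-community proportions.
#' @export
presence_absence <- function(x) {
  stopifnot(inherits(x, "community_table"))
  pa <- (x$raw > 0) * 1
  colnames(pa) <- colnames(x$raw)
  community_table(pa, x$design, community_weights = x$community_weights)
}

#' Transform importance values before normalisation
#'
#' Dampens the dominance of highly abundant species by transforming the raw
#' importance values, then renormalising columns to proportions.
#'
#' @param x a [community_table()] object.
#' @param transform one of `"none"`, `"sqrt"`, `"log1p"`.
#' @return a new `community_table` built on the transformed values.
#' @export
transform_values <- function(x, transform = c("none", "sqrt", "log1p")) {
  stopifnot(inherits(x, "community_table"))
  transform <- match.arg(transform)
  raw <- switch(transform, none = x$raw, sqrt = sqrt(x$raw), log1p = log1p(x$raw))
  community_table(raw, x$design, community_weights = x$community_weights)
}

#' Stratum-aggregated species proportions
#'
#' Aggregates community proportion vectors to the factor levels and to the
#' whole design: `p_i+` is the weighted mean profile over the communities of
#' level `i` of factor A (arithmetic mean under even weights), `p_+j` the
#' analogue for factor B, and `p_global` the weighted mean over all `r*m`
#' communities.  `p_global` is also the species weight vector of the DPCoA.
#'
#' @param x a [community_table()] object.
#' @return a list with `P_A` (S x r), `P_B` (S x m), `p_global` (length S);
#'   every column sums to 1.
#' @export
aggregate_proportions <- function(x) {
  stopifnot(inherits(x, "community_table"))
  cw <- x$community_weights
  P_A <- vapply(x$levelsA, function(a) {
    j <- x$design$A == a
    as.vector(x$props[, j, drop = FALSE] %*% (cw[j] / sum(cw[j])))
  }, numeric(nrow(x$props)))
  P_B <- vapply(x$levelsB, function(b) {
    j <- x$design$B == b
    as.vector(x$props[, j, drop = FALSE] %*% (cw[j] / sum(cw[j])))
  }, numeric(nrow(x$props)))
  dimnames(P_A) <- list(rownames(x$props), x$levelsA)
  dimnames(P_B) <- list(rownames(x$props), x$levelsB)
  p_global <- as.vector(x$props %*% cw)
  names(p_global) <- rownames(x$props)
  list(P_A = P_A, P_B = P_B, p_global = p_global)
}
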