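# Fixtures built in code: tiny hand-checkable designs, exactly constructed
# proportion tables for the orthogonal / collinear geometry, and a directly
# coded non-symmetrical correspondence analysis used as an independent
# oracle.

# 2 x 2 single-species communities on two species at distance sqrt(2)
# (so delta^2/2 = 1): "pureA" varies only with factor A, "pureI" is a pure
# interaction pattern.
fixture_2x2 <- function(kind = c("pureA", "pureI")) {
  kind <- match.arg(kind)
  e1 <- c(1, 0); e2 <- c(0, 1)
  cols <- if (kind == "pureA") cbind(e1, e1, e2, e2) else cbind(e1, e2, e2, e1)
  dimnames(cols) <- list(c("s1", "s2"), c("c11", "c12", "c21", "c22"))
  design <- data.frame(community = colnames(cols),
                       A = c("a1", "a1", "a2", "a2"),
                       B = c("b1", "b2", "b1", "b2"))
  list(table = community_table(cols, design),
       d = dist_equidistant(c("s1", "s2"), sqrt(2)))
}

# Balanced 2 x 2 table over 4 equidistant species whose A and B shifts act
# on orthogonal zero-sum directions u and v of the profile simplex; with
# equidistant species the embedding is a linear isometry of profiles, so the
# A and B level clouds are exactly orthogonal.
fixture_orthogonal <- function(eps = 0.1) {
  p0 <- rep(0.25, 4)
  u <- c(1, -1, 0, 0) * eps
  v <- c(0, 0, 1, -1) * eps
  alpha <- c(1, -1); beta <- c(1, -1)
  cols <- sapply(1:2, function(i) sapply(1:2, function(j) p0 + alpha[i] * u + beta[j] * v))
  P <- matrix(cols, nrow = 4)
  colnames(P) <- c("c11", "c12", "c21", "c22")
  rownames(P) <- paste0("s", 1:4)
  design <- data.frame(community = colnames(P),
                       A = c("a1", "a1", "a2", "a2"),
                       B = c("b1", "b2", "b1", "b2"))
  list(table = community_table(P, design),
       d = dist_equidistant(rownames(P), sqrt(2)))
}

# Same construction but both factors shift along the SAME direction u, so
# the A-level cloud lies inside the subspace spanned by the B levels and the
# orthogonal-complement projection of version 2 removes it entirely.
fixture_collinear <- function(eps = 0.1) {
  p0 <- rep(0.25, 4)
  u <- c(1, -1, 0, 0) * eps
  alpha <- c(1, -1); beta <- c(0.5, -0.5)
  cols <- sapply(1:2, function(i) sapply(1:2, function(j) p0 + (alpha[i] + beta[j]) * u))
  P <- matrix(cols, nrow = 4)
  colnames(P) <- c("c11", "c12", "c21", "c22")
  rownames(P) <- paste0("s", 1:4)
  design <- data.frame(community = colnames(P),
                       A = c("a1", "a1", "a2", "a2"),
                       B = c("b1", "b2", "b1", "b2"))
  list(table = community_table(P, design),
       d = dist_equidistant(rownames(P), sqrt(2)))
}

# Directly coded non-symmetrical correspondence analysis of a species x
# community proportion table: SVD of the column-centred profile matrix under
# the column weights, no species weighting, no dissimilarity input.
nsca_oracle <- function(P, cweights = rep(1 / ncol(P), ncol(P))) {
  pbar <- as.vector(P %*% cweights)
  Z <- P - pbar
  Mw <- t(Z) * sqrt(cweights)  # n x S
  sv <- svd(Mw)
  keep <- which(sv$d^2 > 1e-10 * max(sv$d^2))
  list(eig = sv$d[keep]^2,
       col_scores = (sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))) /
         sqrt(cweights))
}

# align the signs of each column of `got` to `ref` before comparison
align_signs <- function(got, ref) {
  for (a in seq_len(ncol(got))) {
    if (sum(got[, a] * ref[, a]) < 0) got[, a] <- -got[, a]
  }
  got
}

# one random balanced dataset (tree + table) for the property suites
random_dataset <- function(seed) {
  set.seed(seed)
  S <- sample(8:24, 1)
  r <- sample(2:4, 1)
  m <- sample(2:4, 1)
  n <- if (seed %% 4 == 0) 1000 else Inf
  sim <- suppressWarnings(simulate_table(
    S = S, r = r, m = m,
    effect_A = runif(1, 0, 2), effect_B = runif(1, 0, 2),
    effect_AB = runif(1, 0, 1),
    n_individuals = n,
    clade_assignment = "overlapping",
    seed = seed))
  d <- dist_sqrt_branch(sim$tree)
  list(table = sim$table, d = d[rownames(sim$table$props), rownames(sim$table$props)])
}
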