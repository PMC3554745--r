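test_that("the two-species space is solved exactly", {
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sp <- dpcoa_space(d, w = c(0.5, 0.5))
  expect_equal(length(sp$eig), 1L)
  expect_equal(sp$eig, 1)
  expect_equal(sort(as.vector(sp$coords)), c(-1, 1))
  expect_equal(abs(sp$coords[1, 1] - sp$coords[2, 1]), 2)
})

test_that("the equilateral triangle has two equal axes summing to 1/3", {
  d <- dist_equidistant(letters[1:3], 1)
  sp <- dpcoa_space(d)
  expect_equal(length(sp$eig), 2L)
  expect_equal(sp$eig[1], sp$eig[2], tolerance = 1e-12)
  expect_equal(sum(sp$eig), 1 / 3)
  expect_equal(sum(sp$eig), quadratic_entropy(rep(1 / 3, 3), d^2 / 2))
})

test_that("space invariants hold on random weighted problems", {
  for (s in 1:20) {
    set.seed(100 + s)
    S <- sample(5:20, 1)
    tr <- random_tree(S, seed = 100 + s)
    d <- dist_sqrt_branch(tr)
    w <- rexp(S); w <- w / sum(w)
    sp <- dpcoa_space(d, w)
    X <- sp$coords
    # weighted orthogonality: X' diag(w) X diagonal with the eigenvalues
    G <- crossprod(X, X * w)
    expect_equal(G, diag(sp$eig, length(sp$eig)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # weighted centering
    expect_lt(max(abs(w %*% X)), 1e-10)
    # distance reproduction
    expect_lt(max(abs(as.matrix(stats::dist(X)) - d[rownames(X), rownames(X)])),
              1e-8)
    # inertia = QE of the weights on the half-squared scale
    expect_equal(sum(sp$eig), quadratic_entropy(w, d^2 / 2), tolerance = 1e-10)
  }
})

test_that("non-Euclidean input and invalid weights are hard errors", {
  bad <- matrix(c(0, 1, 1, 1, 0, 2.5, 1, 2.5, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(dpcoa_space(bad), "Euclidean")
  d <- dist_equidistant(letters[1:3], 1)
  expect_error(dpcoa_space(d, w = c(0.5, 0.5, 0)), "positive")
})

test_that("profiles place points at weighted centroids", {
  ds <- random_dataset(12)
  x <- ds$table
  agg <- aggregate_proportions(x)
  sp <- dpcoa_space(ds$d, agg$p_global)
  S <- nrow(x$props)

  # a unit profile sits on the species point
  P1 <- matrix(0, S, 1, dimnames = list(rownames(x$props), "one"))
  P1[3, 1] <- 1
  cl <- place_points(sp, P1)
  expect_equal(as.vector(cl$coords), unname(sp$coords[3, ]))

  # the global profile sits at the origin
  Pg <- matrix(agg$p_global, S, 1, dimnames = list(rownames(x$props), "g"))
  expect_lt(max(abs(place_points(sp, Pg)$coords)), 1e-10)

  # a factor level is the weighted centroid of its communities' points
  comm_cloud <- place_points(sp, x$props, x$community_weights)
  lev_cloud <- place_points(sp, agg$P_A, x$levelA_weights)
  i <- x$levelsA[1]
  sel <- x$design$A == i
  cw <- x$community_weights[sel] / sum(x$community_weights[sel])
  expect_equal(as.vector(cw %*% comm_cloud$coords[sel, , drop = FALSE]),
               unname(lev_cloud$coords[1, ]), tolerance = 1e-10)
})

test_that("cloud inertias reproduce the quadratic-entropy components", {
  ds <- random_dataset(17)
  x <- ds$table
  agg <- aggregate_proportions(x)
  sp <- dpcoa_space(ds$d, agg$p_global)
  part <- anoqe(x, ds$d)
  expect_equal(inertia(sp), part[["SST"]], tolerance = 1e-8)
  expect_equal(inertia(place_points(sp, x$props, x$community_weights)),
               part[["SSC"]], tolerance = 1e-8)
  expect_equal(inertia(place_points(sp, agg$P_A, x$levelA_weights)),
               part[["SSA"]], tolerance = 1e-8)
  expect_equal(inertia(place_points(sp, agg$P_B, x$levelB_weights)),
               part[["SSB"]], tolerance = 1e-8)
  expect_equal(inertia(interaction_points(sp, x)), part[["SSAB"]],
               tolerance = 1e-8)
})

test_that("interaction points vanish without interaction and carry SSAB otherwise", {
  pa <- fixture_2x2("pureA")
  agg <- aggregate_proportions(pa$table)
  sp <- dpcoa_space(pa$d, agg$p_global)
  expect_lt(max(abs(interaction_points(sp, pa$table)$coords)), 1e-12)

  pi_ <- fixture_2x2("pureI")
  agg2 <- aggregate_proportions(pi_$table)
  sp2 <- dpcoa_space(pi_$d, agg2$p_global)
  cli <- interaction_points(sp2, pi_$table)
  expect_equal(inertia(cli), 0.5, tolerance = 1e-12)
  # equals the community-cloud inertia: the pattern is pure interaction
  expect_equal(inertia(cli),
               inertia(place_points(sp2, pi_$table$props,
                                    pi_$table$community_weights)),
               tolerance = 1e-12)
})

test_that("community distances embed Rao's cross-entropy (the double of DPCoA)", {
  ds <- random_dataset(23)
  x <- ds$table
  agg <- aggregate_proportions(x)
  sp <- dpcoa_space(ds$d, agg$p_global)
  D <- ds$d^2 / 2
  cl <- place_points(sp, x$props, x$community_weights)
  n <- ncol(x$props)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    expect_equal(0.5 * sum((cl$coords[i, ] - cl$coords[j, ])^2),
                 cross_entropy(x$props[, i], x$props[, j], D),
                 tolerance = 1e-8)
  }
  # same identity for the level points
  clA <- place_points(sp, agg$P_A, x$levelA_weights)
  expect_equal(0.5 * sum((clA$coords[1, ] - clA$coords[2, ])^2),
               cross_entropy(agg$P_A[, 1], agg$P_A[, 2], D), tolerance = 1e-8)
})

test_that("inertia asserts centring unless told otherwise", {
  sp <- dpcoa_space(dist_equidistant(letters[1:3], 1))
  raw <- place_points(sp, diag(3)[, 1, drop = FALSE])
  expect_error(inertia(raw), "not centred")
  expect_gt(inertia(raw, centred = FALSE), 0)
})
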