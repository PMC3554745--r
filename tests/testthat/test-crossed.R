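test_that("the main-effect analysis recovers the factor's SS component", {
  # pure-B fixture: relabel the pure-A pattern so the effect sits on B
  e1 <- c(1, 0); e2 <- c(0, 1)
  cols <- cbind(e1, e2, e1, e2)
  dimnames(cols) <- list(c("s1", "s2"), c("c11", "c12", "c21", "c22"))
  design <- data.frame(community = colnames(cols),
                       A = c("a1", "a1", "a2", "a2"),
                       B = c("b1", "b2", "b1", "b2"))
  x <- community_table(cols, design)
  d <- dist_equidistant(c("s1", "s2"), sqrt(2))
  part <- anoqe(x, d)
  fit <- main_effect_dpcoa(x, factor = "B", dist = d)
  expect_equal(sum(fit$eig), part[["SSB"]], tolerance = 1e-10)
  expect_equal(sum(fit$eig), 0.5, tolerance = 1e-12)

  # and on random data, for both factors
  ds <- random_dataset(41)
  part <- anoqe(ds$table, ds$d)
  for (f in c("A", "B")) {
    fit <- main_effect_dpcoa(ds$table, factor = f, dist = ds$d)
    expect_equal(sum(fit$eig), part[[paste0("SS", f)]], tolerance = 1e-8)
  }
})

test_that("a factor with identical level profiles yields no axes", {
  P <- matrix(c(0.7, 0.3, 0.7, 0.3, 0.2, 0.8, 0.2, 0.8), nrow = 2,
              dimnames = list(c("s1", "s2"), paste0("c", 1:4)))
  design <- data.frame(community = paste0("c", 1:4),
                       A = c("a1", "a1", "a2", "a2"),
                       B = c("b1", "b2", "b1", "b2"))
  x <- community_table(P, design)  # B has no effect: columns repeat over B
  d <- dist_equidistant(c("s1", "s2"), sqrt(2))
  expect_warning(fit <- main_effect_dpcoa(x, factor = "B", dist = d),
                 "degenerate")
  expect_equal(length(fit$eig), 0L)
  expect_equal(ncol(fit$scores$species), 0L)
})

test_that("version 1 keeps the target level positions and their inertia", {
  pa <- fixture_2x2("pureA")
  part <- anoqe(pa$table, pa$d)
  fit <- crossed_dpcoa(pa$table, dist = pa$d, factor = "A", version = "v1")
  expect_equal(length(fit$eig), 1L)
  expect_equal(fit$eig, part[["SSA"]], tolerance = 1e-12)
  expect_equal(sort(as.vector(fit$scores$levelsA)), c(-1, 1) / sqrt(2),
               tolerance = 1e-10)
  # communities coincide with their A level
  expect_equal(unname(fit$scores$communities[c("c11", "c12"), 1]),
               rep(fit$scores$levelsA["a1", 1], 2), tolerance = 1e-10)
  # co-factor levels are at the origin after re-centring
  expect_lt(max(abs(fit$scores$levelsB)), 1e-12)

  # random data: eigenvalue sum = SS(A); re-centred community inertia
  # = SS(A) + SS(A,B), both in the full space
  for (s in c(51, 52, 53)) {
    ds <- random_dataset(s)
    part <- anoqe(ds$table, ds$d)
    fit <- crossed_dpcoa(ds$table, dist = ds$d, factor = "A", version = "v1")
    expect_equal(fit$inertia_report$level_cloud_inertia, part[["SSA"]],
                 tolerance = 1e-8)
    expect_equal(sum(fit$eig), part[["SSA"]], tolerance = 1e-8)
    expect_equal(fit$inertia_report$community_cloud_inertia,
                 part[["SSA"]] + part[["SSAB"]], tolerance = 1e-8)
  }
})

test_that("version 2 projects onto the complement of the co-factor subspace", {
  for (s in c(61, 62)) {
    ds <- random_dataset(s)
    part <- anoqe(ds$table, ds$d)
    fit <- crossed_dpcoa(ds$table, dist = ds$d, factor = "A", version = "v2")
    # inertia can only shrink
    expect_lte(fit$inertia_report$level_cloud_inertia, part[["SSA"]] + 1e-10)
    expect_lte(fit$inertia_report$community_cloud_inertia,
               part[["SSA"]] + part[["SSAB"]] + 1e-10)
    # the co-factor's projected level points vanish
    expect_lt(max(abs(fit$scores$levelsB)), 1e-8)
    # v2 eigenvalue sum never exceeds v1's
    fit1 <- crossed_dpcoa(ds$table, dist = ds$d, factor = "A", version = "v1")
    expect_lte(sum(fit$eig), sum(fit1$eig) + 1e-10)
    # axis eigenvalues decrease and are positive
    expect_true(all(diff(fit$eig) <= 1e-12))
    expect_true(all(fit$eig > 0))
  }
})

test_that("without a co-factor effect version 2 reduces to version 1", {
  pa <- fixture_2x2("pureA")  # B cloud at the origin
  f1 <- crossed_dpcoa(pa$table, dist = pa$d, factor = "A", version = "v1")
  f2 <- crossed_dpcoa(pa$table, dist = pa$d, factor = "A", version = "v2")
  expect_equal(f2$eig, f1$eig, tolerance = 1e-12)
  expect_equal(abs(f2$scores$levelsA), abs(f1$scores$levelsA), tolerance = 1e-12)
  expect_equal(f2$inertia_report$dim_GB, 0)
})

test_that("orthogonal factors: versions 1 and 2 agree up to sign", {
  fx <- fixture_orthogonal()
  f1 <- crossed_dpcoa(fx$table, dist = fx$d, factor = "A", version = "v1")
  f2 <- crossed_dpcoa(fx$table, dist = fx$d, factor = "A", version = "v2")
  expect_equal(f2$eig, f1$eig, tolerance = 1e-10)
  expect_equal(f2$inertia_report$level_cloud_inertia,
               f1$inertia_report$level_cloud_inertia, tolerance = 1e-10)
  for (sc in c("species", "communities", "levelsA")) {
    expect_equal(align_signs(f2$scores[[sc]], f1$scores[[sc]]),
                 f1$scores[[sc]], tolerance = 1e-8)
  }
})

test_that("collinear factors: version 2 removes the shared structure", {
  fx <- fixture_collinear()
  f1 <- crossed_dpcoa(fx$table, dist = fx$d, factor = "A", version = "v1")
  # the projection removes the A structure entirely, so no axes survive
  expect_warning(
    f2 <- crossed_dpcoa(fx$table, dist = fx$d, factor = "A", version = "v2"),
    "degenerate")
  expect_gt(f1$inertia_report$level_cloud_inertia, 0)
  expect_lt(f2$inertia_report$level_cloud_inertia,
            1e-10 * f1$inertia_report$level_cloud_inertia)
})

test_that("version 2 errors when the co-factor spans the whole species space", {
  # 2 species -> 1 species axis; a B effect spans it entirely
  e1 <- c(1, 0); e2 <- c(0, 1)
  cols <- cbind(e1, e2, e1, e2)
  dimnames(cols) <- list(c("s1", "s2"), c("c11", "c12", "c21", "c22"))
  design <- data.frame(community = colnames(cols),
                       A = c("a1", "a1", "a2", "a2"),
                       B = c("b1", "b2", "b1", "b2"))
  x <- community_table(cols, design)
  d <- dist_equidistant(c("s1", "s2"), sqrt(2))
  expect_error(crossed_dpcoa(x, dist = d, factor = "A", version = "v2"),
               "dim G_X must be greater than dim G_B")
})

test_that("the orthogonal-complement projector is idempotent and symmetric", {
  ds <- random_dataset(71)
  x <- ds$table
  agg <- aggregate_proportions(x)
  sp <- dpcoa_space(ds$d, agg$p_global)
  Y_B <- crossprod(agg$P_B, sp$coords)
  ax <- crossdpcoa:::cloud_axes(Y_B, x$levelB_weights, 1e-9)
  U <- ax$vectors
  Q <- diag(ncol(sp$coords)) - U %*% t(U)
  expect_equal(Q, t(Q), tolerance = 1e-12)
  expect_equal(Q %*% Q, Q, tolerance = 1e-10)
})

test_that("fit objects print, summarise, score and plot", {
  ds <- random_dataset(81)
  fit <- crossed_dpcoa(ds$table, dist = ds$d, factor = "A", version = "v1")
  expect_output(print(fit), "version 1")
  expect_output(print(summary(fit)), "ANOQE")
  sc <- scores(fit, display = "communities")
  expect_equal(nrow(sc), ncol(ds$table$props))
  expect_identical(scores(fit, display = "sites"), sc)
  expect_equal(nrow(scores(fit, display = "levelsA")),
               length(ds$table$levelsA))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("percentages are reported against both bases", {
  ds <- random_dataset(91)
  fit <- crossed_dpcoa(ds$table, dist = ds$d, factor = "A", version = "v1")
  expect_equal(sum(fit$percent), 100, tolerance = 1e-8)
  part <- anoqe(ds$table, ds$d)
  expect_equal(fit$percent_ss, 100 * fit$eig / part[["SSA"]], tolerance = 1e-8)
})
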