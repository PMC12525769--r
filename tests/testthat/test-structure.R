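test_that("mass centers are mass-weighted means", {
  s <- site_from_xyz(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(mass_center(s)), c(1, 0, 0))
  s1 <- site_from_xyz(c(5, 5, 5))
  expect_equal(unname(mass_center(s1)), c(5, 5, 5))
  s2 <- chromophore_site("w", atoms = data.frame(
    element = c("C", "C"), x = c(0, 3), y = 0, z = 0, mass = c(12, 24)))
  expect_equal(unname(mass_center(s2))[1], 2)
  expect_error(chromophore_site("z", atoms = data.frame(
    element = "X", x = 0, y = 0, z = 0, mass = 0)), "mass")
})

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  sites <- point_sites(rbind(c(0, 0, 0), c(30, 0, 0)))
  D <- pairwise_distances(sites)
  expect_equal(D[1, 2], 30)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), c(0, 0))
  expect_equal(dim(pairwise_distances(point_sites(c(1, 2, 3)))), c(1, 1))
  tri <- point_sites(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  Dt <- pairwise_distances(tri)
  expect_setequal(round(Dt[upper.tri(Dt)], 10), c(3, 4, 5))
})

test_that("distance matrices satisfy the triangle inequality on random sets", {
  set.seed(11)
  for (rep in 1:5) {
    sites <- point_sites(matrix(runif(30, 0, 100), ncol = 3))
    D <- pairwise_distances(sites)
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("EET graph edges respect the inclusive cutoff and grow monotonically", {
  sites <- point_sites(rbind(c(0, 0, 0), c(30, 0, 0), c(70, 0, 0)))
  g <- build_eet_graph(sites, cutoff_A = 35)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$distance_A, 30)
  # inclusive boundary
  g35 <- build_eet_graph(point_sites(rbind(c(0, 0, 0), c(35, 0, 0))), 35)
  expect_equal(nrow(g35$edges), 1)
  expect_equal(nrow(build_eet_graph(sites, cutoff_A = 0)$edges), 0)
  full <- build_eet_graph(sites, cutoff_A = 1e6)
  expect_equal(nrow(full$edges), 3 * 2 / 2)

  set.seed(7)
  pts <- point_sites(matrix(runif(60, 0, 60), ncol = 3))
  cuts <- seq(0, 120, by = 5)
  ne <- vapply(cuts, function(co) nrow(build_eet_graph(pts, co)$edges), 0)
  expect_true(all(diff(ne) >= 0))
})

test_that("min intergroup distance matches brute force and breaks ties lexicographically", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    grp <- sample(c("core", "rod"), n, replace = TRUE)
    if (length(unique(grp)) < 2) grp[1:2] <- c("core", "rod")
    centers <- matrix(runif(3 * n, 0, 80), ncol = 3)
    sites <- point_sites(centers, groups = grp)
    res <- min_intergroup_distance(sites, "core", "rod")
    D <- pairwise_distances(sites)
    brute <- min(D[grp == "core", grp == "rod"])
    expect_equal(res$distance_A, brute, tolerance = 1e-12)
  }
  # planted minimum with exact ties: lexicographically smallest pair wins
  sites <- point_sites(rbind(c(0, 0, 0), c(0, 0, 33), c(0, 0, -33)),
                       groups = c("a", "b", "b"), ids = c("p1", "q2", "q1"))
  res <- min_intergroup_distance(sites, "a", "b")
  expect_equal(res$distance_A, 33)
  expect_equal(res$site_b, "q1")
  expect_error(min_intergroup_distance(sites, "a", "a"), "differ")
  expect_error(min_intergroup_distance(sites, "a", "zz"), "zz")
})

test_that("rigid motions leave distances and out-of-plane magnitudes unchanged", {
  set.seed(5)
  th <- 0.7; rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(12, -7, 30)
  xyz <- matrix(rnorm(60, sd = 5), ncol = 3)
  ring_defs <- list(A = 1:5, B = 6:10, C = 11:15, D = 16:20)
  s0 <- site_from_xyz(xyz)
  s1 <- site_from_xyz(xyz %*% t(rot) + matrix(shift, 20, 3, byrow = TRUE))
  g0 <- coplanarity(s0, ring_defs); g1 <- coplanarity(s1, ring_defs)
  expect_equal(abs(g1$out_of_plane), abs(g0$out_of_plane), tolerance = 1e-9)

  centers <- matrix(runif(30, 0, 50), ncol = 3)
  sites0 <- point_sites(centers)
  sites1 <- point_sites(centers %*% t(rot) + matrix(shift, 10, 3, byrow = TRUE))
  expect_equal(pairwise_distances(sites1), pairwise_distances(sites0),
               tolerance = 1e-9)
})

test_that("coplanarity reports signed ring displacements from the B-C plane", {
  # four coplanar rings -> zero out-of-plane
  ring <- function(cx, cz = 0) cbind(cx + 1.1 * cos(2 * pi * (0:4) / 5),
                                     1.1 * sin(2 * pi * (0:4) / 5), cz)
  flat <- rbind(ring(-4.5), ring(-1.5), ring(1.5), ring(4.5))
  defs <- list(A = 1:5, B = 6:10, C = 11:15, D = 16:20)
  g <- coplanarity(site_from_xyz(flat), defs)
  expect_equal(unname(g$out_of_plane), c(0, 0), tolerance = 1e-9)
  expect_equal(sum(g$normal^2), 1)

  # displace ring A by +2 and ring D by -1 along the plane normal (z)
  bent <- flat
  bent[1:5, 3] <- bent[1:5, 3] + 2
  bent[16:20, 3] <- bent[16:20, 3] - 1
  gb <- coplanarity(site_from_xyz(bent), defs)
  expect_equal(unname(abs(gb$out_of_plane["A"])), 2, tolerance = 1e-9)
  # sign convention: A displacement nonnegative, D opposite side here
  expect_gte(gb$out_of_plane[["A"]], 0)
  expect_equal(unname(gb$out_of_plane["D"]), -1, tolerance = 1e-9)

  collinear <- flat
  collinear[6:15, 2:3] <- 0  # B and C atoms on a line
  expect_error(coplanarity(site_from_xyz(collinear), defs), "collinear|degenerate")
  expect_error(coplanarity(site_from_xyz(flat),
                           list(A = 1:5, B = 6:7, C = 11:15, D = 16:20)))
})

test_that("toy structures round-trip through harvest with groups and types", {
  lay <- data.frame(group = c("core", "core", "rod"), bilin_type = "PCB",
                    x = c(0, 20, 40), y = c(0, 5, 0), z = 0)
  path <- withr::local_tempfile(fileext = ".pdb")
  info <- make_toy_structure(lay, path, seed = 3)
  sites <- harvest_chromophores(path, info$ligand_map, info$group_map)
  expect_length(sites, 3)
  expect_setequal(vapply(sites, `[[`, "", "group"), c("core", "rod"))
  D <- pairwise_distances(sites)
  # PDB stores 3 decimals; mass centers recovered to format precision
  expect_equal(sort(D[upper.tri(D)]),
               sort(c(dist(lay[, c("x", "y", "z")]))), tolerance = 1e-3)
  # every harvested pseudo-bilin supports a plane fit
  g <- coplanarity(sites[[1]], toy_ring_defs())
  expect_lt(max(abs(g$out_of_plane)), 1e-2)

  # no matching residues -> empty with warning
  expect_warning(none <- harvest_chromophores(path, c(ZZZ = "PCB")), "no residues")
  expect_length(none, 0)
  expect_error(harvest_chromophores(path, c(BLN = "PCB")[0]), "named")
  expect_error(harvest_chromophores("not-a-file.pdb", c(BLN = "PCB")), "file")
})

test_that("a planted 33-angstrom rod-core contact is found as the minimum", {
  lay <- data.frame(
    group = c(rep("core", 3), rep("rod", 3)),
    bilin_type = "PCB",
    x = c(0, 10, 20, 53, 70, 80),
    y = 0, z = 0)
  path <- withr::local_tempfile(fileext = ".pdb")
  info <- make_toy_structure(lay, path, seed = 9)
  sites <- harvest_chromophores(path, info$ligand_map, info$group_map)
  res <- min_intergroup_distance(sites, "core", "rod")
  expect_equal(res$distance_A, 33, tolerance = 1e-3)  # planted 53 - 20
  g <- build_eet_graph(sites, cutoff_A = 35)
  expect_true(all(g$edges$distance_A <= 35))
})

test_that("determinism and jitter behave as documented for toy structures", {
  lay <- data.frame(group = "g", bilin_type = "PCB", x = c(0, 30), y = 0, z = 0)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_structure(lay, p1, seed = 4)
  make_toy_structure(lay, p2, seed = 4)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(make_toy_structure(lay[0, ], p1), "at least one")
})
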