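cfg <- descriptor_config()

test_that("closed-form descriptor examples hold", {
  # two C-alpha-only residues 2 A apart: WCN = 1/4 each
  st2 <- random_bead_structure(2, seed = 1)
  st2$residues[, c("x", "y", "z")] <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3,
                                             byrow = TRUE)
  st2$atoms[, c("x", "y", "z")] <- st2$residues[, c("x", "y", "z")]
  expect_equal(weighted_contact_number(st2), c(0.25, 0.25))
  # centroid at the midpoint: CM = 1 for both
  expect_equal(centroid_distance(st2), c(1, 1))
  # CN with radius 6.4: 1 each at 5 A, 0 each at 7 A
  expect_equal(contact_number(st2, cfg), c(1L, 1L))
  st7 <- st2
  st7$residues$x <- c(0, 7); st7$atoms$x <- c(0, 7)
  expect_equal(contact_number(st7, cfg), c(0L, 0L))

  # equilateral triangle side s: all CM equal s / sqrt(3)
  s <- 5
  tri <- random_bead_structure(3, seed = 2)
  xyz <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  tri$residues[, c("x", "y", "z")] <- xyz
  tri$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(centroid_distance(tri), rep(s / sqrt(3), 3))

  # 3-node path graph (unit hops): centre 1.0, ends 0.75
  path3 <- tri
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  path3$residues[, c("x", "y", "z")] <- xyz
  path3$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(closeness_centrality(path3, cfg), c(0.75, 1.0, 0.75))
  # isolated residue has closeness 0
  iso <- tri
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(40, 0, 0))
  iso$residues[, c("x", "y", "z")] <- xyz
  iso$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(closeness_centrality(iso, cfg)[3], 0)
})

test_that("WCN scales as the inverse square of a coordinate scaling", {
  st <- random_bead_structure(20, seed = 3)
  w1 <- weighted_contact_number(st)
  st$residues[, c("x", "y", "z")] <- st$residues[, c("x", "y", "z")] * 2
  st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] * 2
  expect_equal(weighted_contact_number(st), w1 / 4, tolerance = 1e-12)
})

test_that("hydrogen bond rule counts N/O pairs within 3.5 A", {
  st <- random_bead_structure(2, seed = 4)
  st$atoms <- data.frame(
    seq_position = c(1L, 2L), elety = c("N", "O"), elesy = c("N", "O"),
    x = c(0, 2.9), y = 0, z = 0, o = 1, b = 10)
  # N-O at 2.9 A between non-adjacent... residues 1,2 are adjacent backbone
  # N/O -> excluded; use side-chain-like names
  st$atoms$elety <- c("ND2", "OD1")
  expect_equal(hydrogen_bond_count(st, cfg), c(1L, 1L))
  st$atoms$x[2] <- 4.0
  expect_equal(hydrogen_bond_count(st, cfg), c(0L, 0L))
  # backbone i,i+1 N-O contact is not counted
  st$atoms$elety <- c("N", "O"); st$atoms$x[2] <- 2.9
  expect_equal(hydrogen_bond_count(st, cfg), c(0L, 0L))
})

test_that("core sets follow the RSA threshold and class table", {
  st <- random_bead_structure(4, seed = 5, sequence = "LDGA")
  rsa <- c(5, 50, 9, 12)
  expect_equal(core_set(st, "B", rsa = rsa)$members, c(1L, 3L))
  expect_equal(core_set(st, "H")$members, c(1L, 4L))  # Leu, Ala hydrophobic
  expect_equal(core_set(st, "BnH", rsa = rsa)$members, 1L)
  expect_equal(core_set(st, "BuH", rsa = rsa)$members, c(1L, 3L, 4L))
  expect_error(core_set(st, "B", rsa = c(50, 50, 50, 50)), "empty")
})

test_that("DIS and farness closed forms hold", {
  st <- random_bead_structure(3, seed = 6)
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(30, 0, 0))
  st$residues[, c("x", "y", "z")] <- xyz
  st$atoms[, c("x", "y", "z")] <- xyz
  core1 <- list(kind = "B", members = 2L)
  # single core member at 2 A: DIS = 2, F = 1/(2^-3) = 8 at q = 2
  expect_equal(mean_core_distance(st, core1)[1], 2)
  expect_equal(farness(st, core1, q = 2)[1], 8)
  # core containing only the residue itself: undefined sentinel
  expect_true(is.na(mean_core_distance(st, core1)[2]))
  # members at 1 A and 3 A: DIS = 2; both at 1 A: F = 1/(1+1) = 0.5
  st4 <- random_bead_structure(4, seed = 7)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(0, 1, 0))
  st4$residues[, c("x", "y", "z")] <- xyz
  st4$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(mean_core_distance(st4, list(kind = "B",
                                            members = c(2L, 3L)))[1], 2)
  expect_equal(farness(st4, list(kind = "B", members = c(2L, 4L)),
                       q = 2)[1], 0.5)
})

test_that("farness scales as s^(q+1) under coordinate scaling", {
  st <- random_bead_structure(15, seed = 8)
  core <- list(kind = "H", members = c(2L, 5L, 9L))
  f1 <- farness(st, core, q = 2)
  st$residues[, c("x", "y", "z")] <- st$residues[, c("x", "y", "z")] * 3
  st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] * 3
  expect_equal(farness(st, core, q = 2), f1 * 3^3, tolerance = 1e-9)
  # q = 0 reduces to the unnormalised harmonic-mean form
  st2 <- random_bead_structure(10, seed = 9)
  f0 <- farness(st2, core, q = 0)
  ca <- as.matrix(st2$residues[, c("x", "y", "z")])
  manual <- 1 / sum(1 / sqrt(colSums((t(ca[core$members, ]) - ca[1, ])^2)))
  expect_equal(f0[1], manual, tolerance = 1e-12)
})

test_that("GNM Kirchhoff rows sum to zero and symmetric chains give symmetric profiles", {
  st <- random_bead_structure(3, seed = 10)
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  st$residues[, c("x", "y", "z")] <- xyz
  st$atoms[, c("x", "y", "z")] <- xyz
  f <- gnm_fluctuation(st, cfg)
  expect_equal(f[1], f[3], tolerance = 1e-10)   # symmetric ends
  expect_gt(f[1], f[2])                          # ends more flexible
  expect_true(all(f > 0))
  # disconnected network errors
  far <- st
  far$residues$x[3] <- 100; far$atoms$x[3] <- 100
  expect_error(gnm_fluctuation(far, cfg), "disconnected")
})

test_that("SASA behaves physically and matches a high-resolution oracle", {
  # a single isolated residue is essentially fully exposed
  st <- random_bead_structure(2, seed = 11, sequence = "GG")
  st$residues[, c("x", "y", "z")] <- rbind(c(0, 0, 0), c(50, 0, 0))
  st$atoms[, c("x", "y", "z")] <- st$residues[, c("x", "y", "z")]
  res <- sasa_rsa(st, cfg)
  expect_true(all(res$rsa >= 95))

  # caging an atom strictly reduces its SASA
  n_cage <- 26
  ang <- seq(0, 2 * pi, length.out = n_cage + 1)[-1]
  cage_xyz <- rbind(c(0, 0, 0),
                    cbind(4 * cos(ang), 4 * sin(ang), 0),
                    c(0, 0, 4), c(0, 0, -4))
  nn <- nrow(cage_xyz)
  caged <- random_bead_structure(nn, seed = 12)
  caged$residues[, c("x", "y", "z")] <- cage_xyz
  caged$atoms[, c("x", "y", "z")] <- cage_xyz
  caged_sasa <- sasa_rsa(caged, cfg)
  expect_lt(caged_sasa$residue_sasa[1], res$residue_sasa[1])

  # per-atom sums vs an independent random-point oracle at 10,000 points
  st3 <- build_polypeptide(synthetic_spec(
    blocks = list(c("helix", "8"), c("loop", "4")), seed = 13))
  mine <- sasa_rsa(st3, cfg, n_points = 10000)$residue_sasa
  oracle_atoms <- bf_sasa(st3, cfg$sasa_probe, 40000)
  oracle <- as.numeric(tapply(oracle_atoms, st3$atoms$seq_position, sum))
  expect_true(all(abs(mine - oracle) / oracle < 0.02))
  # the default 960-point shell stays within 2% of its high-resolution value
  coarse <- sasa_rsa(st3, cfg)$residue_sasa
  expect_true(all(abs(coarse - mine) / mine < 0.02))
})

test_that("residue depth separates the centre of a cluster from its shell", {
  # dense cluster: centre bead buried deeper than the shell beads
  set.seed(14)
  shell <- matrix(rnorm(3 * 60), 60, 3)
  shell <- shell / sqrt(rowSums(shell^2)) * 4.5
  xyz <- rbind(c(0, 0, 0), shell)
  st <- random_bead_structure(61, seed = 14)
  st$residues[, c("x", "y", "z")] <- xyz
  st$atoms[, c("x", "y", "z")] <- xyz
  d <- residue_depth(st, cfg)
  expect_gt(d[1], max(d[-1]))
  # fully exposed dipeptide: depth 0 for both
  st2 <- read_structure(fixture_pdb_3res(), chain_id = "A")
  expect_equal(residue_depth(st2, cfg), c(0, 0, 0))
})

test_that("descriptors match independent brute-force oracles on random structures", {
  for (seed in c(21, 22, 23, 24)) {
    n <- sample(20:40, 1)
    st <- random_bead_structure(n, seed = seed)
    expect_equal(contact_number(st, cfg), bf_contact_number(st, 6.4))
    expect_equal(weighted_contact_number(st), bf_wcn(st), tolerance = 1e-9)
    expect_equal(closeness_centrality(st, cfg), bf_closeness(st, 8.0))
    expect_equal(hydrogen_bond_count(st, cfg), bf_hbond(st, 3.5))
    core <- list(kind = "H", members = sort(sample(n, 6)))
    expect_equal(mean_core_distance(st, core), bf_dis(st, core$members),
                 tolerance = 1e-9)
    expect_equal(farness(st, core, 2), bf_farness(st, core$members, 2),
                 tolerance = 1e-9)
    gn <- tryCatch(gnm_fluctuation(st, cfg), error = function(e) NULL)
    if (!is.null(gn)) expect_equal(gn, bf_gnm(st, 10.0), tolerance = 1e-8)
  }
})

test_that("descriptors are invariant under rigid-body motion", {
  st <- random_bead_structure(25, seed = 30)
  moved <- rigid_transform(st, seed = 31)
  core <- list(kind = "H", members = c(3L, 8L, 12L))
  expect_equal(contact_number(moved, cfg), contact_number(st, cfg))
  expect_equal(weighted_contact_number(moved), weighted_contact_number(st),
               tolerance = 1e-6)
  expect_equal(closeness_centrality(moved, cfg),
               closeness_centrality(st, cfg))
  expect_equal(gnm_fluctuation(moved, cfg), gnm_fluctuation(st, cfg),
               tolerance = 1e-6)
  expect_equal(farness(moved, core, 2), farness(st, core, 2),
               tolerance = 1e-6)
  expect_equal(centroid_distance(moved), centroid_distance(st),
               tolerance = 1e-6)
  # translation leaves depth unchanged
  shifted <- st
  shifted$residues[, c("x", "y", "z")] <-
    sweep(as.matrix(st$residues[, c("x", "y", "z")]), 2, c(5, -3, 7), "+")
  shifted$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(st$atoms[, c("x", "y", "z")]), 2, c(5, -3, 7), "+")
  expect_equal(residue_depth(shifted, cfg), residue_depth(st, cfg),
               tolerance = 1e-6)
})

test_that("moving a residue away from the core raises F and DIS, lowers WCN", {
  st <- random_bead_structure(12, seed = 40, box = 10)
  core <- list(kind = "H", members = 2:6)
  centre <- colMeans(as.matrix(st$residues[core$members, c("x", "y", "z")]))
  dir <- as.numeric(st$residues[1, c("x", "y", "z")]) - centre
  dir <- dir / sqrt(sum(dir^2))
  prev <- NULL
  for (step in c(0, 5, 10)) {
    moved <- st
    newpos <- as.numeric(st$residues[1, c("x", "y", "z")]) + step * dir
    moved$residues[1, c("x", "y", "z")] <- as.list(newpos)
    moved$atoms[1, c("x", "y", "z")] <- as.list(newpos)
    cur <- c(F = farness(moved, core, 2)[1],
             DIS = mean_core_distance(moved, core)[1],
             WCN = weighted_contact_number(moved)[1])
    if (!is.null(prev)) {
      expect_gt(cur["F"], prev["F"])
      expect_gt(cur["DIS"], prev["DIS"])
      expect_lt(cur["WCN"], prev["WCN"])
    }
    prev <- cur
  }
})

test_that("the assembled feature matrix is complete and deterministic", {
  set.seed(50)
  xyz <- matrix(rnorm(3 * 30, sd = 4), 30, 3)   # compact cluster
  st <- random_bead_structure(30, seed = 50)
  st$residues[, c("x", "y", "z")] <- xyz
  st$atoms[, c("x", "y", "z")] <- xyz
  fm1 <- suppressWarnings(compute_feature_matrix(st, cfg))
  fm2 <- suppressWarnings(compute_feature_matrix(st, cfg))
  expect_identical(fm1, fm2)  # seedless recomputation is bit-identical
  expect_true(all(tertiary_feature_names() %in% names(fm1)))
  expect_equal(nrow(fm1), 30L)
  # a compact cluster has buried residues, so the core columns are defined
  expect_false(anyNA(fm1$DIS_hpho))
  expect_false(anyNA(fm1$WCN))
})
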