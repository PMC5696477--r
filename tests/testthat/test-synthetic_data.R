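test_that("ensemble generation is deterministic and sized by its layout", {
  spec <- synthetic_spec(n_folded = 1,
                         group_layout = c("g+/+" = 4, "g+/-" = 3,
                                          "g-/+" = 6, "g-/-" = 7),
                         seed = 7)
  ens <- generate_ensemble(spec)
  expect_equal(nrow(ens$energies), 21L)
  expect_equal(nrow(ens$truth), 5L)              # 4 families + 1 folded
  expect_identical(generate_ensemble(spec), ens)
  expect_equal(min(ens$energies$e_rel), 0)
  expect_equal(nrow(ens$barriers), choose(21, 2))
})

test_that("an empty specification yields empty outputs", {
  ens <- generate_ensemble(synthetic_spec(n_folded = 0,
                                          group_layout = integer()))
  expect_equal(nrow(ens$energies), 0L)
  expect_equal(nrow(ens$truth), 0L)
  expect_length(ens$types, 0L)
})

test_that("generated barriers respect their class intervals", {
  spec <- synthetic_spec(seed = 3)
  ens <- generate_ensemble(spec)
  cls <- vapply(ens$barriers$dg_barrier, classify_barrier, "")
  # within-family pairs are low, all pairs involving the fold are high
  ids <- ens$energies$id
  fam <- lapply(ens$truth$members[ens$truth$n_members > 1], identity)
  for (k in seq_len(nrow(ens$barriers))) {
    p <- c(ens$barriers$from[k], ens$barriers$to[k])
    same_fam <- any(vapply(fam, function(m) all(p %in% m), TRUE))
    if (same_fam) expect_identical(cls[k], "low")
  }
  folded <- setdiff(ids, unlist(fam))
  inv <- ens$barriers$from %in% folded | ens$barriers$to %in% folded
  expect_true(all(cls[inv] == "high"))
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_spec(barrier_draws = list(low = c(0, 3),
                                                   medium = c(2.5, 7.5),
                                                   high = c(8.5, 14))),
               "boundaries")
  expect_error(synthetic_spec(group_layout = c(4, 3)), "named")
  expect_error(synthetic_spec(energy_scale = -1))
})

test_that("pooling the generated ensemble recovers the ground truth", {
  for (seed in c(7, 23, 101)) {
    spec <- synthetic_spec(n_folded = 2,
                           group_layout = c("g+/+" = 4, "g+/-" = 3,
                                            "g-/+" = 5, "g-/-" = 4),
                           seed = seed)
    ens <- generate_ensemble(spec)
    g <- build_conversion_graph(ens$energies$id, barriers = ens$barriers)
    pops <- boltzmann_populations(free_energies(ens$energies, 450), 450)
    gref <- free_energies(ens$energies, 10)
    b <- pool_populations(g, pops, g_ref = gref)
    expect_setequal(b$sink, ens$truth$sink)
    m <- match(b$sink, ens$truth$sink)
    expect_equal(b$pooled, ens$truth$pooled[m], tolerance = 1e-12)
    expect_identical(lapply(b$members, sort),
                     lapply(ens$truth$members[m], sort))
  }
})

test_that("trial-dihedral enumeration is the full lexicographic product", {
  grid3 <- list(b1 = c(-60, 60, 180), b2 = c(-60, 60, 180),
                b3 = c(-60, 60, 180))
  combos <- enumerate_trial_dihedrals(grid3)
  expect_equal(nrow(combos), 27L)
  expect_equal(combos$b1, rep(c(-60, 60, 180), each = 9))   # slowest first
  expect_equal(combos$b3[1:3], c(-60, 60, 180))             # fastest last
  expect_equal(nrow(enumerate_trial_dihedrals(list(b = 0))), 1L)
  grid8 <- setNames(rep(list(c(0, 120, 240)), 8), paste0("r", 1:8))
  expect_equal(nrow(enumerate_trial_dihedrals(grid8)), 6561L)
  expect_error(enumerate_trial_dihedrals(list(a = 1, b = numeric())), "b")
})

test_that("the geometry builder realises requested dihedrals exactly", {
  g <- build_dipeptide_geometry(phi2 = -84, psi2 = 68, chi1 = 175,
                                orientation = -60, amino_swing = 45)
  d <- typing_dihedrals(g)
  expect_equal(d$phi2, -84, tolerance = 1e-3)
  expect_equal(d$psi2, 68, tolerance = 1e-3)
  expect_equal(d$chi1, 175, tolerance = 1e-3)
  expect_equal(d$orient, -60, tolerance = 1e-3)
  expect_equal(d$amino_swing, 45, tolerance = 1e-3)
  # mirroring flips every dihedral sign
  dm <- typing_dihedrals(mirror_geometry(g))
  expect_equal(dm$phi2, 84, tolerance = 1e-3)
  expect_equal(dm$chi1, -175, tolerance = 1e-3)
})

test_that("the packaged YG table is intact and matches its checksum", {
  path <- system.file("extdata", "yg_table1.csv", package = "jetcool")
  expect_identical(unname(tools::md5sum(path)),
                   "39958c5eaeae8ef1db1e35598c7159ef")
  fx <- table1_fixture()
  expect_equal(unname(fx$energies$e_rel[fx$energies$id == "yg1"]), 0)
  expect_identical(unname(fx$types["yg1"]), "A1-γ_D(F)-g+/+")
  expect_equal(unname(fx$distributions["yg1", "T450"]), 3.05)
  expect_equal(unname(fx$distributions["yg14", "T450"]), 8.65)
  expect_true(is.na(fx$distributions["yg2", "T450"]))
  expect_equal(nrow(fx$energies), 37L)
  # every packaged type label parses under the label grammar
  expect_silent(lapply(fx$types, parse_type_label))
})
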