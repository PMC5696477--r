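test_that("multi-XYZ files round-trip with ids, frame order and atom order", {
  g1 <- geometry(c("N", "C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0),
                                         c(2.0, 1.1, 0)), label = "yg1")
  g2 <- geometry(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)),
                 label = "yg14")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_ensemble(list(g1, g2), path)
  back <- read_xyz_ensemble(path)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, "", "label"), c("yg1", "yg14"))
  expect_identical(back[[1]]$element, g1$element)
  expect_equal(back[[1]]$coords, g1$coords, tolerance = 1e-9)
  expect_equal(back[[2]]$coords, g2$coords, tolerance = 1e-9)
})

test_that("empty XYZ file gives an empty ensemble", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(), path)
  expect_length(read_xyz_ensemble(path), 0L)
})

test_that("malformed XYZ frames are rejected with the frame named", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "broken", "C 0 0 0", "C 1 0 0", "C 2 0 0", "C 3 0 0"),
             path)
  expect_error(read_xyz_ensemble(path), "frame 1")
  writeLines(c("x", "bad count"), path)
  expect_error(read_xyz_ensemble(path), "malformed atom-count")
  writeLines(c("1", "a", "C 0 0 0", "1", "a", "C 1 0 0"), path)
  expect_error(read_xyz_ensemble(path), "duplicate")
})

test_that("blank XYZ comment lines auto-assign 1-based conformer ids", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0 0 0", "1", "", "C 1 0 0"), path)
  back <- read_xyz_ensemble(path)
  expect_identical(vapply(back, `[[`, "", "label"), c("conf_1", "conf_2"))
})

test_that("energy tables parse with delimiter detection and g_corr headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,e_rel,g_corr@298,g_corr@450",
               "a,0.0,0.1,0.2", "b,1.5,-0.2,-0.4"), path)
  tab <- read_energy_table(path)
  expect_s3_class(tab, "energy_table")
  expect_identical(tab$id, c("a", "b"))
  expect_equal(tab$gcorr_450, c(0.2, -0.4))
  # tab-separated variant parses identically
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\te_rel\tg_corr@298\tg_corr@450",
               "a\t0.0\t0.1\t0.2", "b\t1.5\t-0.2\t-0.4"), path2)
  expect_equal(read_energy_table(path2)$gcorr_298, tab$gcorr_298)
})

test_that("energy tables enforce a unique zero-energy reference", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,e_rel", "a,1.0", "b,2.0"), path)
  expect_error(read_energy_table(path), "reference")
  expect_equal(nrow(read_energy_table(path, reference_check = FALSE)), 2L)
  writeLines(c("id,e_rel", "a,0"), path)
  expect_equal(nrow(read_energy_table(path)), 1L)
  writeLines(c("id,e_rel", "a,0", "b,oops"), path)
  expect_error(read_energy_table(path), "non-numeric")
})

test_that("hartree input is converted to kcal/mol and re-referenced", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,e_rel", "a,-520.001", "b,-520.000"), path)
  tab <- read_energy_table(path, hartree = TRUE)
  expect_equal(tab$e_rel[1], 0)
  expect_equal(tab$e_rel[2], 0.001 * 627.5094740631, tolerance = 1e-9)
})

test_that("the packaged YG table loads 37 validated records", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$energies), 37L)
  expect_equal(sum(abs(fx$energies$e_rel) < 1e-12), 1L)
  expect_identical(fx$energies$id[which.min(fx$energies$e_rel)], "yg1")
})

test_that("energy tables round-trip at full float precision", {
  tab <- toy_energy_table(c(0, 1 / 3, pi),
                          gcorr = list(gcorr_450 = c(0, -exp(1) / 7, 0.25)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_energy_table(tab, path)
  back <- read_energy_table(path)
  expect_identical(back$e_rel, tab$e_rel)
  expect_identical(back$gcorr_450, tab$gcorr_450)
})

test_that("basin reports round-trip bit-stably and reject empty input", {
  fx <- table1_fixture()
  grp <- yg_cooling_groups()
  pops <- fx$distributions[, "T450"]
  pops[is.na(pops)] <- 0
  basins <- pool_populations(yg_fixture_graph(fx, grp), pops,
                             sinks = grp$sinks)
  path <- withr::local_tempfile(fileext = ".txt")
  write_report(basins, path, threshold = 8)
  back <- read_report(path)
  expect_identical(back$sink, basins$sink)
  expect_identical(back$pooled, basins$pooled)
  expect_identical(back$observable, basins$observable)
  expect_identical(lapply(back$members, sort), lapply(basins$members, sort))
  # pooled sum over the yg14 basin appears at full precision
  expect_equal(back$pooled[back$sink == "yg14"], 14.01, tolerance = 1e-12)
  # bit stability: a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_report(basins, path2, threshold = 8)
  expect_identical(readLines(path), readLines(path2))
  empty <- basins[0, ]
  expect_error(write_report(empty, path), "empty")
})

test_that("a singleton basin at 100% reports one observable basin", {
  g <- build_conversion_graph("only")
  basins <- pool_populations(g, c(only = 100))
  expect_equal(nrow(basins), 1L)
  expect_true(basins$observable)
  path <- withr::local_tempfile(fileext = ".txt")
  write_report(basins, path)
  expect_identical(read_report(path)$sink, "only")
})

test_that("barrier and frequency tables validate their columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("from,to,dg_barrier", "a,b,1.5", "a,c,9"), path)
  bt <- read_barrier_table(path)
  expect_equal(bt$dg_barrier, c(1.5, 9))
  writeLines(c("from,to,dg_barrier", "a,a,1.5"), path)
  expect_error(read_barrier_table(path), "distinct")
  writeLines(c("mode_label,frequency,intensity", "NH,3400,10"), path)
  ft <- read_frequency_table(path)
  expect_equal(ft$frequency, 3400)
  writeLines(c("mode_label,frequency", "NH,-1"), path)
  expect_error(read_frequency_table(path), "positive")
})
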