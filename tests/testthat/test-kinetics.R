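test_that("barrier classes respect the inclusive boundaries", {
  expect_identical(classify_barrier(1.5), "low")
  expect_identical(classify_barrier(2.5), "medium")
  expect_identical(classify_barrier(2.0), "low")       # boundary inclusive
  expect_identical(classify_barrier(8.0), "high")      # boundary inclusive
  expect_identical(classify_barrier(2.0 + 1e-9), "medium")
  expect_identical(classify_barrier(8.0 - 1e-9), "medium")
  expect_identical(classify_barrier(0), "low")
  expect_error(classify_barrier(-0.1), "non-negative")
  # boundaries are configurable
  expect_identical(classify_barrier(2.5, low_max = 3), "low")
})

test_that("type-based barrier prediction encodes the empirical rules", {
  expect_identical(
    predict_barrier_class("A1-γ_L(F)-g+/+", "A1-γ_D(F)-g+/+"), "high")
  expect_identical(
    predict_barrier_class("A1-β(E)-g+/+", "A1-γ_D(F)-g+/+"), "high")
  expect_identical(
    predict_barrier_class("A1-ε_D(E)-g+/+", "A1-ε_D(E)-g-/+"), "medium")
  expect_identical(
    predict_barrier_class("A1-β(E)-g+/+", "A1-ε_D(E)-g+/+"), "low")
  expect_identical(
    predict_barrier_class("A1-β(E)-g+/+", "A2-β(E)-g+/+"), "low")
  expect_identical(
    predict_barrier_class("A1-γ_D(F)-g+/+", "A2-γ_D(F)-g+/+"), "low")
  expect_identical(
    predict_barrier_class("A1-γ_D(F)-g+/+", "A1-γ_D(F)-g-/+"), "medium")
  expect_error(predict_barrier_class("U-β(E)-g+/+", "A1-β(E)-g+/+"),
               "untyped")
})

test_that("conversion graphs connect only low-barrier pairs", {
  types <- c(a = "A1-β(E)-g+/+", b = "A1-ε_D(E)-g+/+",
             c = "A1-ε_L(E)-g+/+", d = "A2-β(E)-g+/+",
             f = "A1-γ_D(F)-g+/+")
  g <- build_conversion_graph(names(types), types = types)
  comp <- igraph::components(g)$membership
  expect_equal(max(comp), 2L)                    # one family + isolated fold
  expect_equal(sum(comp == comp[["f"]]), 1L)
  empty <- build_conversion_graph(character())
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("explicit barriers override type predictions", {
  types <- c(a = "A1-β(E)-g+/+", b = "A1-ε_D(E)-g+/+")
  barriers <- data.frame(from = "a", to = "b", dg_barrier = 5)
  g <- build_conversion_graph(names(types), barriers = barriers,
                              types = types)
  expect_equal(igraph::ecount(g), 0L)            # predicted low, measured medium
  barriers2 <- data.frame(from = "a", to = "b", dg_barrier = 0.4)
  types2 <- c(a = "A1-β(E)-g+/+", b = "A1-γ_D(F)-g+/+")
  g2 <- build_conversion_graph(names(types2), barriers = barriers2,
                               types = types2)
  expect_equal(igraph::ecount(g2), 1L)           # predicted high, measured low
  expect_error(build_conversion_graph("a", barriers = barriers),
               "unknown conformer")
})

test_that("pooling collapses each basin onto its reference-T sink", {
  g <- build_conversion_graph(
    c("x", "y", "z"),
    barriers = data.frame(from = c("x", "y"), to = c("y", "z"),
                          dg_barrier = c(0.5, 1)))
  pops <- c(x = 20, y = 50, z = 30)
  gref <- c(x = 0.3, y = 0.1, z = 0.9)
  b <- pool_populations(g, pops, g_ref = gref)
  expect_identical(b$sink, "y")
  expect_equal(b$pooled, 100)
  # ties on g_ref break by e_rel, then id
  gref2 <- c(x = 0.1, y = 0.1, z = 0.1)
  b2 <- pool_populations(g, pops, g_ref = gref2,
                         e_rel = c(x = 2, y = 1, z = 1))
  expect_identical(b2$sink, "y")
  b3 <- pool_populations(g, pops, g_ref = gref2)
  expect_identical(b3$sink, "x")
  expect_error(pool_populations(g, pops[-1], g_ref = gref), "x")
  expect_error(pool_populations(g, pops), "no designated sink")
})

test_that("pooled mass is conserved and order/labels are immaterial", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    ids <- sprintf("n%02d", seq_len(n))
    npairs <- sample(0:(n * (n - 1) / 2), 1)
    pairs <- if (npairs) t(utils::combn(ids, 2))[
      sample(n * (n - 1) / 2, npairs), , drop = FALSE] else
        matrix(character(), 0, 2)
    barriers <- data.frame(from = pairs[, 1], to = pairs[, 2],
                           dg_barrier = runif(nrow(pairs), 0, 4))
    pops <- setNames(runif(n), ids)
    pops <- 100 * pops / sum(pops)
    gref <- setNames(runif(n), ids)
    g <- build_conversion_graph(ids, barriers = barriers)
    b <- pool_populations(g, pops, g_ref = gref)
    expect_equal(sum(b$pooled), 100, tolerance = 1e-9)
    # brute-force transitive-closure oracle gives the same partition
    low <- barriers[barriers$dg_barrier <= 2, c("from", "to"), drop = FALSE]
    oracle <- oracle_components(ids, as.matrix(low))
    expect_setequal(lapply(b$members, sort),
                    lapply(unname(oracle), sort))
    # relabel and permute: same basins up to renaming
    map <- setNames(sprintf("m%02d", sample(n)), ids)
    perm <- sample(n)
    barriers2 <- data.frame(from = unname(map[barriers$from]),
                            to = unname(map[barriers$to]),
                            dg_barrier = barriers$dg_barrier)
    g2 <- build_conversion_graph(unname(map[ids][perm]),
                                 barriers = barriers2)
    b2 <- pool_populations(g2, setNames(pops, map[ids]),
                           g_ref = setNames(gref, map[ids]))
    expect_identical(sort(unname(map[b$sink])), sort(b2$sink))
    expect_equal(sort(b2$pooled), sort(b$pooled), tolerance = 1e-12)
  }
})

test_that("raising one barrier out of the low class never merges basins", {
  set.seed(33)
  ids <- sprintf("c%d", 1:8)
  pairs <- t(utils::combn(ids, 2))
  barriers <- data.frame(from = pairs[, 1], to = pairs[, 2],
                         dg_barrier = runif(nrow(pairs), 0, 6))
  pops <- setNames(rep(100 / 8, 8), ids)
  gref <- setNames(runif(8), ids)
  base <- pool_populations(build_conversion_graph(ids, barriers = barriers),
                           pops, g_ref = gref)
  low_idx <- which(barriers$dg_barrier <= 2)
  for (k in low_idx) {
    mod <- barriers
    mod$dg_barrier[k] <- 5
    b <- pool_populations(build_conversion_graph(ids, barriers = mod),
                          pops, g_ref = gref)
    expect_gte(nrow(b), nrow(base))
  }
})

test_that("observability thresholding is exclusive and sorted", {
  g <- build_conversion_graph(c("p", "q", "r"))
  b <- pool_populations(g, c(p = 8, q = 80, r = 12))
  obs <- observable_conformers(b)
  expect_identical(obs$sink, c("q", "r"))        # 8% exactly is not observable
  expect_equal(nrow(observable_conformers(b, threshold = 0)), 3L)
  b5 <- pool_populations(g, c(p = 5, q = 5, r = 90 - 85))
  expect_equal(nrow(observable_conformers(b5)), 0L)
})
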