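test_that("per-edge weights match hand substitution", {
  expect_equal(edge_weight("SRR", 3, 2), 2 / sqrt(6))   # ~0.8165
  expect_equal(edge_weight("SD", 2, 2), 2)
  expect_equal(edge_weight("HM", 3, 2), 25)
  expect_equal(edge_weight("F", 3, 2), 13)
  # hyper-Zagreb = forgotten + 2 * second Zagreb, edge by edge
  grid <- expand.grid(a = 1:4, b = 1:4)
  expect_equal(edge_weight("HM", grid$a, grid$b),
               edge_weight("F", grid$a, grid$b) +
                 2 * edge_weight("M2", grid$a, grid$b))
  # symmetry in the two degrees
  expect_equal(edge_weight("SRR", 1, 4), edge_weight("SRR", 4, 1))
  expect_error(edge_weight("M1", 0, 2), class = "topoqspr_invalid_structure")
  expect_error(edge_weight("nope", 1, 2))
})

test_that("K2 takes the closed-form values for every index", {
  k2 <- mol_graph_from_edges(cbind("a", "b"), "K2")
  v <- compute_indices(k2)
  expect_equal(unclass(v)[topo_indices()],
               c(M1 = 2, M2 = 1, mM2 = 1, H = 1, F = 2, HM = 4, SD = 2,
                 FRR = 1 / 3, SRR = 1),
               ignore_attr = TRUE)
  expect_equal(index_brute_force(k2, "H"), 1)
  v2 <- compute_indices(k2, frr_variant = "as_tabulated")
  expect_equal(v2[["FRR"]], 1 / sqrt(6))
})

test_that("the naphazoline partition reproduces the reference values", {
  part <- as_edge_partition(data.frame(low = c(2, 2, 3), high = c(2, 3, 3),
                                       count = c(8, 8, 2)))
  expect_identical(index_from_partition(part, "M1"), 84)
  expect_identical(index_from_partition(part, "M2"), 98)
  expect_identical(index_from_partition(part, "F"), 204)
  expect_identical(index_from_partition(part, "HM"), 400)
  expect_equal(index_from_partition(part, "mM2"), 32 / 9)       # 3.5556
  expect_equal(index_from_partition(part, "H"), 8 * 0.5 + 8 * 0.4 + 2 / 3)
  expect_equal(index_from_partition(part, "SD"), 112 / 3)       # 37.333
  expect_equal(index_from_partition(part, "SRR"),
               8 * 0.5 + 8 * 2 / sqrt(6) + 2 / 3, tolerance = 1e-12)
  # FRR, definition as written: 8/8 + 8/11 + 2/15
  expect_equal(index_from_partition(part, "FRR"), 1 + 8 / 11 + 2 / 15)
})

test_that("foscarnet takes the reference descriptor vector", {
  g <- mol_graph_from_edges(foscarnet_edges(), "Foscarnet")
  expect_equal(partition_as_counts(edge_partition(g)),
               c("1-3" = 2L, "1-4" = 3L, "3-4" = 1L))
  v <- compute_indices(g)
  expect_equal(v[["M1"]], 30)
  expect_equal(v[["M2"]], 30)
  expect_equal(v[["mM2"]], 1.5)
  expect_equal(v[["H"]], 2.4857, tolerance = 1e-4)
  expect_equal(v[["F"]], 96)
  expect_equal(v[["HM"]], 156)
  expect_equal(v[["SD"]], 21.5)
  expect_equal(v[["SRR"]], 10.0414, tolerance = 1e-4)
})

test_that("path of length two matches hand enumeration", {
  g <- mol_graph_from_edges(rbind(c("a", "b"), c("b", "c")), "path3")
  expect_equal(index_brute_force(g, "M1"), 6)
  expect_equal(index_brute_force(g, "mM2"), 1.0)
  expect_equal(index_brute_force(g, "SRR"), 2 * 2 / sqrt(2), tolerance = 1e-12)
})

test_that("partition path, brute force and the independent oracle agree", {
  set.seed(2)
  for (k in 1:60) {
    pairs <- igraph::as_edgelist(
      random_mol_graph(sample(4:25, 1), extra_edges = sample(0:4, 1),
                       seed = 5000 + k)$graph)
    g <- mol_graph_from_edges(pairs)
    part <- edge_partition(g)
    for (ix in topo_indices()) {
      for (fv in c("as_stated", "as_tabulated")) {
        a <- index_from_partition(part, ix, frr_variant = fv)
        b <- index_brute_force(g, ix, frr_variant = fv)
        o <- oracle_index(pairs, ix, frr_variant = fv)
        expect_equal(a, b, tolerance = 1e-9)
        expect_equal(a, o, tolerance = 1e-9)
      }
    }
  }
})

test_that("regular graphs collapse to the closed forms", {
  # d-regular with m edges: M1 = 2dm, mM2 = m/d^2, H = m/d, SD = 2m, SRR = m/d
  for (g in list(mol_graph_from_edges(cycle_edges(6), "C6"),
                 mol_graph_from_edges(complete_edges(4), "K4"))) {
    d <- unname(degree_map(g)[1])
    m <- n_edges(g)
    expect_true(all(degree_map(g) == d))
    expect_equal(index_brute_force(g, "M1"), 2 * d * m)
    expect_equal(index_brute_force(g, "mM2"), m / d^2)
    expect_equal(index_brute_force(g, "H"), m / d)
    expect_equal(index_brute_force(g, "SD"), 2 * m)
    expect_equal(index_brute_force(g, "SRR"), m / d)
  }
})

test_that("adding an edge strictly increases M1, M2, F and HM", {
  base <- cycle_edges(8)
  with_chord <- rbind(base, c("v1", "v4"))
  for (ix in c("M1", "M2", "F", "HM")) {
    expect_gt(oracle_index(with_chord, ix), oracle_index(base, ix))
    expect_gt(index_brute_force(mol_graph_from_edges(with_chord), ix),
              index_brute_force(mol_graph_from_edges(base), ix))
  }
})

test_that("M1, M2, F, HM are integer-valued and all indices positive", {
  set.seed(3)
  for (k in 1:40) {
    g <- random_mol_graph(sample(3:20, 1), extra_edges = sample(0:3, 1),
                          seed = 7000 + k)
    v <- compute_indices(g)
    expect_true(all(v > 0))
    expect_equal(v[c("M1", "M2", "F", "HM")],
                 round(v[c("M1", "M2", "F", "HM")]))
  }
})

test_that("descriptor tables carry one row per structure in column order", {
  gs <- list(mol_graph_from_edges(cbind("a", "b"), "K2"),
             mol_graph_from_edges(naphazoline_edges(), "Naphazoline"))
  tab <- compute_index_table(gs)
  expect_equal(dim(tab), c(2L, 10L))
  expect_equal(names(tab), c("name", topo_indices()))
  expect_equal(tab$M1, c(2, 84))
})
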