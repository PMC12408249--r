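test_that("small molecules parse to the expected graph shapes", {
  g_me <- smiles_to_graph("C")
  expect_equal(g_me$n_atoms, 1L)
  expect_equal(g_me$n_bond_edges, 0L)
  expect_equal(nrow(g_me$edges), 1L)          # just the self-loop
  expect_equal(g_me$edges[1, ], c(0L, 0L))

  g_et <- smiles_to_graph("CCO")
  expect_equal(g_et$n_atoms, 3L)
  expect_equal(g_et$n_bond_edges, 4L)          # 2 bonds x 2 directions

  g_bz <- smiles_to_graph("C1=CC=CC=C1")
  expect_equal(g_bz$n_atoms, 6L)
  expect_equal(g_bz$n_bond_edges, 12L)         # 6 ring bonds x 2
  expect_true(all(g_bz$atoms$aromatic))
  expect_true(all(g_bz$atoms$in_ring))
})

test_that("parsing errors name the offending SMILES", {
  expect_error(smiles_to_graph(""), "empty SMILES")
  expect_error(smiles_to_graph("not_a_smiles"), "not_a_smiles")
})

test_that("graphs are deterministic, bidirected, with one self-loop per node", {
  fixture <- smiles_fixture()
  for (s in fixture$smiles[seq(1, 50, by = 7)]) {
    g1 <- smiles_to_graph(s)
    g2 <- smiles_to_graph(s)
    expect_identical(g1$node_features, g2$node_features)
    expect_identical(g1$edges, g2$edges)

    loops <- g1$edges[g1$edges[, 1] == g1$edges[, 2], , drop = FALSE]
    expect_equal(sort(loops[, 1]), 0:(g1$n_atoms - 1L))

    bonds <- g1$edges[g1$edges[, 1] != g1$edges[, 2], , drop = FALSE]
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_equal(key(bonds), key(bonds[, 2:1, drop = FALSE]))
    expect_true(all(g1$edges >= 0 & g1$edges < g1$n_atoms))
  }
})

test_that("atom counts agree with an independent parser on 50 molecules", {
  fixture <- smiles_fixture()
  got <- vapply(fixture$smiles, function(s) smiles_to_graph(s)$n_atoms,
                integer(1))
  expect_equal(unname(got), fixture$n_heavy)
  got_edges <- vapply(fixture$smiles,
                      function(s) smiles_to_graph(s)$n_bond_edges,
                      integer(1))
  expect_equal(unname(got_edges), 2L * fixture$n_bonds)
})

test_that("atom feature vectors follow the one-hot contract", {
  cfg <- atom_featurizer_config()
  base <- list(element = "C", degree = 2L, formal_charge = 0,
               hybridization = "sp3", aromatic = FALSE, in_ring = FALSE,
               n_h = 2L)
  v1 <- atom_feature_vector(base, cfg)
  v2 <- atom_feature_vector(base, cfg)
  expect_identical(v1, v2)
  expect_length(v1, cfg$d_atom)

  vN <- atom_feature_vector(modifyList(base, list(element = "N")), cfg)
  el_block <- seq_len(length(cfg$elements) + 1L)
  expect_false(identical(v1[el_block], vN[el_block]))
  expect_identical(v1[-el_block], vN[-el_block])

  v_other <- atom_feature_vector(modifyList(base, list(element = "Se")), cfg)
  expect_equal(v_other[length(cfg$elements) + 1L], 1)
  expect_equal(sum(v_other[seq_along(cfg$elements)]), 0)
})

test_that("d_atom is identical across a dataset of graphs", {
  widths <- vapply(smiles_fixture()$smiles[1:10], function(s) {
    ncol(smiles_to_graph(s)$node_features)
  }, integer(1))
  expect_length(unique(widths), 1L)
})

test_that("graph JSON serialization round-trips", {
  g <- smiles_to_graph("CCOC(=O)C", drug_id = "sm1")
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  g2 <- read_graph_json(path)
  expect_equal(g2$node_features, unname(g$node_features))
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$drug_id, "sm1")
})

test_that("circular fingerprints are deterministic and structure-sensitive", {
  f1 <- morgan_fingerprint(smiles_to_graph("CCO"))
  f2 <- morgan_fingerprint(smiles_to_graph("CCO"))
  expect_identical(f1, f2)
  f3 <- morgan_fingerprint(smiles_to_graph("c1ccccc1"))
  expect_true(length(setdiff(f1, f3)) > 0)
  expect_true(all(f1 >= 0 & f1 < 2048))
})
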