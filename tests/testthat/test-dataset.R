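make_fm <- function(vals, ids,
                    cols = sprintf("k%02d",
                                   seq_len(length(vals) / length(ids)))) {
  feature_matrix(matrix(vals, length(ids), length(cols), byrow = TRUE,
                        dimnames = list(ids, cols)))
}

test_that("pathway aggregation sums member compound rows", {
  fm <- featurize_compounds(list(methane_graph(), water_graph()), 2L)
  ann1 <- annotation_table("methane", "P1")
  agg1 <- aggregate_pathway_features(fm, ann1)
  expect_equal(unname(agg1$values["P1", ]), unname(fm$values["methane", ]))

  ann2 <- annotation_table(c("methane", "water"), c("P1", "P1"))
  agg2 <- aggregate_pathway_features(fm, ann2)
  expect_equal(unname(agg2$values["P1", ]), c(1, 1))
})

test_that("aggregation matches a brute-force sum oracle on random corpora", {
  set.seed(5)
  corpus <- synth_corpus(20L, seed = 81L)
  fm <- featurize_compounds(corpus, 1L)
  ids <- entity_ids(fm)
  for (rep in 1:3) {
    cp <- sample(ids, 30L, replace = TRUE)
    pw <- sample(sprintf("P%d", 1:6), 30L, replace = TRUE)
    ann <- annotation_table(cp, pw)
    agg <- aggregate_pathway_features(fm, ann)
    for (p in entity_ids(agg)) {
      members <- ann$compound_id[ann$pathway_id == p]
      oracle <- colSums(fm$values[members, , drop = FALSE])
      expect_equal(agg$values[p, ], oracle)
    }
  }
})

test_that("aggregation drops structureless pairs and errors when nothing remains", {
  fm <- featurize_compounds(list(methane_graph()), 1L)
  ann <- annotation_table(c("methane", "ghost"), c("P1", "P2"))
  expect_message(agg <- aggregate_pathway_features(fm, ann), "dropped 1")
  expect_equal(entity_ids(agg), "P1")
  expect_error(
    suppressMessages(
      aggregate_pathway_features(fm, annotation_table("ghost", "P9"))),
    "no pathway")
})

test_that("pathway_size sums member compound sizes and skips empty pathways", {
  sizes <- c(a = 5L, b = 1L, c = 12L)
  ann <- annotation_table(c("a", "b", "c", "zz"),
                          c("P1", "P2", "P2", "P3"))
  ps <- pathway_size(ann, sizes)
  expect_equal(ps[["P1"]], 5L)
  expect_equal(ps[["P2"]], 13L)
  expect_false("P3" %in% names(ps))   # only member has no structure
})

test_that("deduplicate keeps the smallest ID and merges annotations", {
  fm <- make_fm(c(1, 0,
                  1, 0,
                  0, 2), c("b", "a", "c"))
  ann <- annotation_table(c("b", "a", "c"), c("P1", "P2", "P3"))
  dd <- deduplicate(fm, ann, role = "compound")
  expect_setequal(entity_ids(dd$matrix), c("a", "c"))
  expect_equal(unname(dd$map[["b"]]), "a")
  merged <- dd$annotations[dd$annotations$compound_id == "a", ]
  expect_setequal(merged$pathway_id, c("P1", "P2"))
})

test_that("deduplicate is the identity on distinct rows and idempotent", {
  set.seed(9)
  for (rep in 1:5) {
    vals <- matrix(rpois(8L * 4L, 1), 8L, 4L,
                   dimnames = list(sprintf("e%d", 1:8), sprintf("k%d", 1:4)))
    fm <- feature_matrix(vals)
    ann <- annotation_table(sample(rownames(vals), 10L, replace = TRUE),
                            sample(sprintf("P%d", 1:3), 10L, replace = TRUE))
    d1 <- deduplicate(fm, ann, role = "compound")
    d2 <- deduplicate(d1$matrix, d1$annotations, role = "compound")
    expect_identical(d2$matrix$values, d1$matrix$values)
    expect_identical(d2$annotations, d1$annotations)
  }
  distinct <- make_fm(c(1, 0, 0, 1), c("x", "y"))
  dd <- deduplicate(distinct, annotation_table("x", "P1"))
  expect_identical(dd$matrix$values, distinct$values)
})

test_that("normalization scales columns to [0, 1] by their maxima", {
  fm <- make_fm(c(0, 2, 4), c("a", "b", "c"), "k1")
  nm <- normalize_features(fm)
  expect_equal(unname(nm$values[, 1L]), c(0, 0.5, 1))

  already <- make_fm(c(0, 1, 1, 0), c("a", "b"))
  expect_equal(normalize_features(already)$values, already$values)

  set.seed(13)
  rand <- feature_matrix(matrix(rpois(60L, 4), 10L, 6L,
                                dimnames = list(sprintf("e%d", 1:10),
                                                sprintf("k%d", 1:6))))
  nr <- normalize_features(rand)$values
  expect_true(all(nr >= 0 & nr <= 1))
  nonzero <- colSums(rand$values) > 0
  expect_true(all(apply(nr[, nonzero, drop = FALSE], 2L, max) == 1))
})

test_that("cross_join enumerates all pairs with annotation-driven labels", {
  cfm <- make_fm(c(1, 0, 0, 1), c("c1", "c2"))
  pfm <- make_fm(c(1, 0, 0, 1, 1, 1), c("p1", "p2", "p3"))
  ann <- annotation_table(c("c1", "c2"), c("p2", "p3"))
  ds <- cross_join(cfm, pfm, ann)
  expect_equal(ds$n_entries, 6)
  expect_equal(sum(ds$labels), 2L)
  # oracle: nested loops over the pair grid
  oracle <- logical(0)
  for (ci in c("c1", "c2")) for (pj in c("p1", "p2", "p3")) {
    oracle <- c(oracle,
                any(ann$compound_id == ci & ann$pathway_id == pj))
  }
  expect_identical(ds$labels, oracle)

  one <- cross_join(make_fm(1, "c"), make_fm(1, "p"),
                    annotation_table("c", "p"))
  expect_equal(one$n_entries, 1)
  expect_true(one$labels)
  expect_error(cross_join(cfm, feature_matrix(matrix(numeric(0), 0L, 0L)),
                          ann), "empty")
})

test_that("entry features concatenate the compound and pathway rows", {
  cfm <- make_fm(c(1, 2, 3, 4), c("c1", "c2"))
  pfm <- make_fm(c(5, 6, 7, 8, 9, 10), c("p1", "p2", "p3"))
  ds <- cross_join(cfm, pfm, annotation_table("c1", "p1"))
  X <- entry_features(ds)
  expect_equal(dim(X), c(6L, 4L))
  # entry 5 = compound 2, pathway 2 (compound-major order)
  expect_equal(unname(X[5L, ]), c(3, 4, 7, 8))
})

test_that("assign_levels follows minimum root distance, with igraph as oracle", {
  h <- pathway_hierarchy(c("A", "A", "C", "B"), c("B", "C", "D", "D"))
  lm <- assign_levels(h)
  expect_equal(unname(lm$level[c("A", "B", "C", "D")]), c(1L, 2L, 2L, 3L))

  skip_if_not_installed("igraph")
  set.seed(17)
  for (rep in 1:5) {
    gh <- gen_hierarchy(synth_config(n_compounds = 5L, n_pathways = 30L,
                                     hierarchy_depth = 6L,
                                     seed = 100L + rep))
    lm <- gh$levels
    g <- igraph::graph_from_data_frame(gh$hierarchy$edges)
    nodes <- igraph::V(g)$name
    roots <- nodes[igraph::degree(g, mode = "in") == 0L]
    d <- igraph::distances(g, v = roots, to = nodes, mode = "out")
    oracle <- apply(d, 2L, min) + 1L
    expect_equal(unname(lm$level[nodes]), unname(oracle[nodes]))
  }
})

test_that("levels 6 and deeper display as L6+, and chains reach it", {
  chain <- pathway_hierarchy(sprintf("N%d", 1:8), sprintf("N%d", 2:9))
  lm <- assign_levels(chain)
  expect_equal(unname(lm$level[["N9"]]), 9L)
  expect_equal(unname(lm$display[["N9"]]), "L6+")
  expect_equal(unname(lm$display[["N5"]]), "L5")
  expect_message(assign_levels(chain, ids = c("N1", "ORPHAN")), "absent")
})

test_that("subset_by_level is the identity at 1 and nests at higher levels", {
  td <- tiny_dataset(seed = 19L, n_compounds = 12L, n_pathways = 8L)
  ds <- td$pd$dataset
  lv <- td$pd$levels
  s1 <- subset_by_level(ds, lv, 1L)
  expect_identical(s1$labels, ds$labels)
  expect_identical(entity_ids(s1$pathways), entity_ids(ds$pathways))
  s2 <- subset_by_level(ds, lv, 2L)
  expect_true(all(entity_ids(s2$pathways) %in% entity_ids(ds$pathways)))
  expect_equal(s2$n_entries, s2$n_compounds * s2$n_pathways)
  # positives equal annotation pairs restricted to retained pathways
  keep <- td$pd$dataset$annotations$pathway_id %in% entity_ids(s2$pathways)
  expect_equal(sum(s2$labels), sum(keep))
})

test_that("level subsetting matches the nested-loop count on a known layout", {
  cfm <- make_fm(rep(1, 4L), sprintf("c%d", 1:4), "k1")
  pfm <- make_fm(seq_len(5L), sprintf("p%d", 1:5), "k1")
  ds <- cross_join(normalize_features(cfm), normalize_features(pfm),
                   annotation_table("c1", "p1"))
  h <- pathway_hierarchy(c("p1", "p1", "p2"), c("p3", "p4", "p5"))
  lv <- suppressMessages(assign_levels(h, ids = sprintf("p%d", 1:5)))
  s2 <- subset_by_level(ds, lv, 2L)   # p3, p4, p5 at level 2
  expect_equal(s2$n_entries, 4 * 3)
})

test_that("the built pipeline dataset keeps cardinality and label conservation", {
  td <- tiny_dataset(seed = 23L, n_compounds = 15L, n_pathways = 5L)
  ds <- td$pd$dataset
  expect_equal(ds$n_entries, ds$n_compounds * ds$n_pathways)
  expect_equal(sum(ds$labels), nrow(ds$annotations))
  expect_equal(length(ds$labels), ds$n_entries)
})
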