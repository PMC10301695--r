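obo_text <- function(stanzas) {
  c("format-version: 1.2", "", unlist(stanzas))
}

stanza <- function(id, name = id, is_a = character(0), extra = character(0)) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("is_a: ", is_a), extra, "")
}

test_that("parse_obo transcribes terms and is_a edges and drops other relations", {
  f <- tempfile(fileext = ".obo")
  writeLines(obo_text(list(
    stanza("A"),
    stanza("B", is_a = "A ! rootward"),
    stanza("C", is_a = "A"),
    stanza("D", is_a = c("B", "C"), extra = "relationship: part_of A")
  )), f)
  g <- parse_obo(f)
  expect_setequal(g$terms, c("A", "B", "C", "D"))
  expect_equal(nrow(g$edges), 4L)
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]),
                  c("A B", "A C", "B D", "C D"))
})

test_that("parse_obo honours namespace filter and drops obsolete terms", {
  f <- tempfile(fileext = ".obo")
  writeLines(obo_text(list(
    stanza("A", extra = "namespace: biological_process"),
    stanza("B", is_a = "A", extra = "namespace: biological_process"),
    stanza("X", is_a = "A", extra = "namespace: molecular_function"),
    stanza("Z", is_a = "A",
           extra = c("namespace: biological_process", "is_obsolete: true"))
  )), f)
  g <- parse_obo(f, namespace = "biological_process")
  expect_setequal(g$terms, c("A", "B"))
  expect_equal(nrow(g$edges), 1L)
})

test_that("parse_obo rejects cyclic is_a structure naming a member", {
  f <- tempfile(fileext = ".obo")
  writeLines(obo_text(list(
    stanza("X", is_a = "Y"),
    stanza("Y", is_a = "X")
  )), f)
  expect_error(parse_obo(f), "cycle")
  expect_error(parse_obo(tempfile()), "cannot read")
})

test_that("parse_annotations deduplicates TSV pairs and rejects empty files", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("T1\tg1", "T1\tg1", "T2\tg2"), f)
  ann <- parse_annotations(f)
  expect_equal(ann, list(T1 = "g1", T2 = "g2"))
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(parse_annotations(empty), "zero parsable rows")
})

test_that("parse_annotations excludes GAF rows with NOT qualifier", {
  gaf_row <- function(gene, term, qual = "") {
    paste(c("DB", gene, gene, qual, term, "REF", "IEA", "", "P",
            "", "", "protein", "taxon:9606", "20210101", "DB", "", ""),
          collapse = "\t")
  }
  f <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               gaf_row("g1", "T1"),
               gaf_row("g2", "T1", qual = "NOT"),
               gaf_row("g3", "T2", qual = "NOT|contributes_to"),
               gaf_row("g4", "T2")), f)
  ann <- parse_annotations(f)
  # hand count: rows 1 and 4 retained
  expect_equal(ann, list(T1 = "g1", T2 = "g4"))
})

test_that("descendant gene sets cover reachable annotations", {
  g <- toy_graph()
  expect_equal(descendant_genes(g, "A"), c("g1", "g2", "g3", "g4", "g5"))
  expect_equal(descendant_genes(g, "B"), c("g2", "g3", "g5"))
  expect_equal(descendant_genes(g, "D"), "g5")
  expect_error(descendant_genes(g, "nope"), "unknown term")
})

test_that("trimming removes out-of-range terms and contracts edges", {
  g <- toy_graph()
  # descendant counts: A=5, B=3, C=3, D=1; thresholds [2,4] keep B and C
  onto <- trim_ontology(g, bottom = 2, top = 4)
  expect_setequal(onto$terms, c("B", "C"))
  expect_equal(unname(onto$depth[c("B", "C")]), c(0L, 0L))
  expect_equal(onto$genes, c("g2", "g3", "g4"))
  expect_equal(nrow(onto$edges), 0L)
})

test_that("no-op thresholds keep the whole graph with the root at depth 0", {
  g <- toy_graph()
  onto <- trim_ontology(g, bottom = 0, top = Inf)
  expect_setequal(onto$terms, g$terms)
  expect_equal(sum(onto$depth == 0), 1L)
  expect_equal(unname(onto$depth["A"]), 0L)
  expect_equal(unname(onto$depth["D"]), 2L)
})

test_that("chain trimming keeps the middle term at depth 0", {
  edges <- rbind(c("R", "S"), c("S", "T"))
  colnames(edges) <- c("parent", "child")
  g <- pathvae:::new_ontology_graph(
    c("R", "S", "T"), edges,
    list(R = sprintf("r%d", 1:5), S = sprintf("s%d", 1:2),
         T = sprintf("t%d", 1:3)))
  # descendant counts: R=10, S=5, T=3; thresholds [4,8] keep only S
  expect_equal(length(descendant_genes(g, "R")), 10L)
  onto <- trim_ontology(g, bottom = 4, top = 8)
  expect_equal(onto$terms, "S")
  expect_equal(unname(onto$depth), 0L)
})

test_that("every kept term's original descendant count lies inside the thresholds", {
  for (s in 1:10) {
    g <- random_dag(25, seed = s)
    counts <- lengths(pathvae:::all_descendant_genes(g))
    bottom <- sample(1:3, 1)
    top <- sample(6:20, 1)
    onto <- tryCatch(trim_ontology(g, bottom, top), error = function(e) NULL)
    if (is.null(onto)) next
    expect_true(all(onto$trim_counts >= bottom & onto$trim_counts <= top))
    expect_true(all(counts[onto$terms] >= bottom & counts[onto$terms] <= top))
    expect_true(all(unlist(onto$annotations) %in% onto$genes))
  }
})

test_that("contraction preserves reachability among kept terms", {
  for (s in 1:8) {
    g <- random_dag(20, seed = 100 + s)
    R0 <- oracle_transitive_closure(g$terms, g$edges)
    onto <- tryCatch(trim_ontology(g, 2, 15), error = function(e) NULL)
    if (is.null(onto) || length(onto$terms) < 2) next
    R1 <- oracle_transitive_closure(onto$terms, onto$edges)
    for (u in onto$terms) for (v in onto$terms) {
      expect_identical(R1[u, v], R0[u, v])
    }
    # every contracted edge increases depth
    if (nrow(onto$edges)) {
      expect_true(all(onto$depth[onto$edges[, 1]] < onto$depth[onto$edges[, 2]]))
    }
  }
})

test_that("longest-path depths match the diamond example and the DFS oracle", {
  edges <- rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D"), c("A", "D"))
  colnames(edges) <- c("parent", "child")
  d <- compute_depths(edges, c("A", "B", "C", "D"))
  expect_equal(unname(d[c("A", "D")]), c(0L, 2L))
  g <- random_dag(50, p_edge = 0.2, seed = 42)
  expect_equal(compute_depths(g$edges, g$terms),
               oracle_longest_path(g$terms, g$edges))
})

test_that("masks transcribe the toy annotation pattern", {
  g <- toy_graph()
  onto <- trim_ontology(g, bottom = 2, top = 4)   # B, C both depth 0
  masks <- build_masks(onto, k = 3)
  expect_length(masks$decoder, 0L)
  R <- masks$reconstruction
  expect_equal(dim(R), c(3L, 6L))       # genes g2..g4 x (2 terms * 3)
  # columns 1:3 belong to B (annot g2,g3), 4:6 to C (annot g3,g4)
  expect_equal(unname(R["g2", ]), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(R["g3", ]), c(1, 1, 1, 1, 1, 1))
  expect_equal(unname(R["g4", ]), c(0, 0, 0, 1, 1, 1))
})

test_that("chain masks at k = 1 are the identity-like hand pattern", {
  onto <- chain_ontology()
  masks <- build_masks(onto, k = 1)
  expect_equal(masks$decoder[[1]], matrix(1))
  expect_equal(unname(masks$reconstruction), rbind(c(0, 1), c(1, 0)))
  # rows are genes (gC, gP sorted), columns (P, C): gC links C, gP links P
  expect_equal(rownames(masks$reconstruction), c("gC", "gP"))
})

test_that("mask nonzero pattern equals the brute-force adjacency expansion", {
  for (s in 1:6) {
    g <- random_dag(18, seed = 200 + s)
    onto <- trim_ontology(g, 1, 100)
    k <- sample(1:3, 1)
    masks <- build_masks(onto, k)
    A <- oracle_full_adjacency(onto, k)
    for (d in seq_along(masks$decoder)) {
      rows <- onto$terms[onto$depth == d]
      ri <- range(match(rows, onto$terms))
      sl <- ((ri[1] - 1) * k + 1):(ri[2] * k)
      expect_equal(masks$decoder[[d]],
                   A[sl, seq_len(min(sl) - 1), drop = FALSE])
    }
    expect_equal(sum(unlist(lapply(masks$decoder, sum))),
                 k^2 * nrow(onto$edges))
    expect_equal(sum(masks$reconstruction),
                 k * sum(lengths(onto$annotations)))
  }
})

test_that("mask construction is deterministic given identical inputs", {
  g <- random_dag(15, seed = 9)
  onto <- trim_ontology(g, 1, 100)
  expect_identical(build_masks(onto, 2), build_masks(onto, 2))
  expect_identical(trim_ontology(g, 1, 100)$terms, onto$terms)
})

test_that("trimming with nothing surviving reports the count distribution", {
  g <- toy_graph()
  expect_error(trim_ontology(g, 100, 200), "no terms survive")
})
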