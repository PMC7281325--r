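toy_marker_frame <- function() {
  data.frame(site_key = c("P1_109_S_1", "P2_50_T_1"),
             gene_symbol = c("YAP1L", "NEK9L"),
             residue = c("S", "T"), position = c(109L, 50L),
             multiplicity = 1L,
             fc_A_T1 = c(-3, 2.2), fc_A_T2 = c(-2.8, NA),
             fc_A_T3 = c(-3.1, 2.5),
             consensus_direction = c("down", "up"),
             consensus_fc = c(-3, 2.3),
             tier = c("three_of_three", "two_of_three"),
             stringsAsFactors = FALSE)
}

toy_gene_frame <- function() {
  data.frame(gene = c("TEAD2L", "YAP1L"),
             direction = c("up", "down"),
             fc_baseline = c(2.3, -2.1), q_baseline = c(0.01, 0.02),
             fc_treated = c(2.2, -2.4), q_treated = c(0.01, 0.03),
             stringsAsFactors = FALSE)
}

test_that("network merges phospho and mRNA layers by symbol", {
  net <- build_network(toy_marker_frame(), toy_gene_frame(),
                       kinases = "NEK9L")
  expect_equal(igraph::vcount(net), 3)
  v <- igraph::vertex_attr(net)
  i <- match(c("YAP1L", "NEK9L", "TEAD2L"), v$name)
  expect_equal(v$node_kind[i], c("both", "phosphoprotein", "mRNA"))
  expect_equal(v$fc_T1[i], c(-3, 2.2, NA))
  expect_equal(v$fc_T2[i], c(-2.8, NA, NA))
  expect_equal(v$mrna_fc[i], c(-2.25, NA, 2.25))
  expect_equal(v$is_kinase[i], c(FALSE, TRUE, FALSE))
  expect_equal(v$sites[i], c("S109", "T50", ""))
  expect_equal(igraph::ecount(net), 0)
})

test_that("edges referencing absent symbols are dropped with a warning", {
  edges <- data.frame(symbol_a = c("YAP1L", "YAP1L"),
                      symbol_b = c("TEAD2L", "GHOST"),
                      score = c(0.9, 0.5), source_db = "toy")
  expect_warning(
    net <- build_network(toy_marker_frame(), toy_gene_frame(), edges),
    "absent symbols")
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$score, 0.9)
})

test_that("several marker sites on one protein fold into one node", {
  m <- toy_marker_frame()
  m <- rbind(m, m[1, ])
  m$site_key[3] <- "P1_127_S_1"
  m$position[3] <- 127L
  m$consensus_fc[3] <- -1.8
  m$fc_A_T1[3] <- -1.8
  net <- build_network(m, NULL)
  expect_equal(igraph::vcount(net), 2)
  v <- igraph::vertex_attr(net)
  i <- match("YAP1L", v$name)
  expect_equal(v$sites[i], "S109;S127")
  expect_equal(v$fc_T1[i], -3)  # strongest site carries the node
})

test_that("hypergeometric p matches the exact enumeration example", {
  universe <- sprintf("U%02d", 1:20)
  selected <- universe[1:6]
  sets <- list(TERM = c(universe[c(1, 2, 3, 10, 11)]))  # K=5, k=3
  res <- hypergeometric_enrichment(selected, universe, sets)
  expect_equal(res$k, 3)
  expect_equal(res$p, 5090 / 38760)
  expect_equal(res$p, oracle_hypergeom(20, 5, 6, 3))
})

test_that("degenerate enrichment cases behave as certain events", {
  universe <- sprintf("U%02d", 1:12)
  sets <- list(ALL = universe[1:4], NONE = c("X1", "X2"),
               MISS = universe[10:12])
  res <- hypergeometric_enrichment(universe, universe, sets)
  expect_equal(res$p[res$term == "ALL"], 1)   # selected = universe
  expect_false("NONE" %in% res$term)          # K = 0 skipped
  res2 <- hypergeometric_enrichment(universe[1:3], universe,
                                    list(MISS = universe[10:12]))
  expect_equal(res2$k, 0)
  expect_equal(res2$p, 1)                     # P(X >= 0) = 1
  expect_error(hypergeometric_enrichment(c("Z9"), universe, sets),
               "subset")
})

test_that("BH over terms preserves the p-value ranking", {
  withr::with_seed(3, {
    universe <- sprintf("U%03d", 1:60)
    selected <- sample(universe, 15)
    sets <- lapply(1:20, function(i) sample(universe, sample(3:20, 1)))
    names(sets) <- paste0("T", 1:20)
    res <- hypergeometric_enrichment(selected, universe, sets)
    expect_true(all(diff(res$p) >= 0))
    expect_true(all(diff(res$q) >= -1e-15))
    expect_true(all(res$q >= res$p))
    expect_equal(res$q, bh_adjust(res$p))
  })
})

test_that("GraphML and Cytoscape JSON round-trip the network", {
  net <- suppressWarnings(build_network(
    toy_marker_frame(), toy_gene_frame(),
    edges = data.frame(symbol_a = "YAP1L", symbol_b = "TEAD2L",
                       score = 0.7, source_db = "toy"),
    kinases = "NEK9L"))
  for (fmt in c("graphml", "cyjs")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(net, f, fmt)
    back <- import_graph(f, fmt)
    expect_equal(igraph::vcount(back), igraph::vcount(net))
    expect_equal(igraph::ecount(back), igraph::ecount(net))
    o1 <- order(igraph::V(net)$name)
    o2 <- order(igraph::V(back)$name)
    for (a in names(igraph::vertex_attr(net))) {
      v1 <- igraph::vertex_attr(net, a)[o1]
      v2 <- igraph::vertex_attr(back, a)[o2]
      # missing quantifications must come back as explicit missing values
      expect_equal(is.na(v1), is.na(v2), info = paste(fmt, a))
      expect_equal(v1[!is.na(v1)], v2[!is.na(v2)], info = paste(fmt, a),
                   tolerance = 1e-9)
    }
    expect_equal(igraph::E(back)$score, igraph::E(net)$score)
  }
})

test_that("empty networks and unknown formats are handled", {
  empty <- build_network(toy_marker_frame()[0, ], NULL)
  expect_equal(igraph::vcount(empty), 0)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, f, "graphml")
  expect_equal(igraph::vcount(import_graph(f, "graphml")), 0)
  expect_error(export_graph(empty, f, "gexf"))
})

test_that("edge TSV export writes endpoint symbols and attributes", {
  net <- suppressWarnings(build_network(
    toy_marker_frame(), toy_gene_frame(),
    edges = data.frame(symbol_a = "YAP1L", symbol_b = "TEAD2L",
                       score = 0.7, source_db = "toy")))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_graph(net, f, "edge_tsv")
  e <- read.delim(f)
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$symbol_a, e$symbol_b), c("YAP1L", "TEAD2L"))
  expect_equal(e$score, 0.7)
})

test_that("GMT collections parse names, descriptions and members", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst\tG1\tG2\tG3",
               "SET_B\tsecond\tG2\tG4"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("SET_A", "SET_B"))
  expect_equal(sets$SET_B, c("G2", "G4"))
  expect_equal(attr(sets, "descriptions"), c("first", "second"))
  writeLines("BROKEN\tonly-description", f)
  expect_error(read_gmt(f), "GMT")
})
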