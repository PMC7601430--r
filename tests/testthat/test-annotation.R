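tw <- load_trait_windows()

test_that("the packaged window table carries the printed structure", {
  expect_s3_class(tw, "trait_window_table")
  gc <- gene_counts(tw)
  expect_equal(gc$windows_by_trait,
               c(BT = 6L, CW = 11L, EMA = 7L, MS = 5L, YW = 13L))
  expect_equal(gc$entries_by_trait,
               c(BT = 100L, CW = 136L, EMA = 72L, MS = 50L, YW = 128L))
  expect_equal(gc$per_window_total, 371L)
  # every share clears the 1% selection rule at 2-dp printing precision
  expect_true(all(tw$gv_percent > 1.0 - 0.005))
  # the lone lowercase miRNA is typed as such; MIR gene loci stay genes
  expect_equal(tw$symbol[which(tw$node_type == "miRNA")], "bta-mir-2379")
  expect_equal(tw$node_type[!is.na(tw$symbol) & tw$symbol == "MIR124A-2"],
               rep("gene", 2))
  # one window has no annotated gene
  expect_equal(sum(is.na(tw$symbol)), 1)
  expect_equal(unique(tw$trait[is.na(tw$symbol)]), "EMA")
})

test_that("pleiotropy summary separates shared and trait-specific windows", {
  ps <- pleiotropy_summary(tw)
  expect_equal(ps$n_windows_distinct, 33)
  expect_equal(ps$n_pleiotropic, 7)
  expect_equal(ps$n_trait_specific, 26)
  # toy checks
  toy <- data.frame(trait = c("A", "B", "C"), chrom = "1", start_mb = 1,
                    end_mb = 2, gv_percent = 1.5,
                    symbol = "g1", node_type = "gene")
  ps2 <- pleiotropy_summary(toy)
  expect_equal(ps2$n_windows_distinct, 1)
  expect_equal(ps2$n_pleiotropic, 1)
  toy$start_mb <- 1:3
  ps3 <- pleiotropy_summary(toy)
  expect_equal(ps3$n_pleiotropic, 0)
  expect_equal(ps3$n_trait_specific, 3)
})

test_that("trait overlaps reproduce the shared-gene counts", {
  expect_length(trait_overlap(tw, c("CW", "YW")), 88)
  expect_length(trait_overlap(tw, c("BT", "EMA")), 2)
  # the three-way CW/EMA/YW overlap contains the symbols of the two windows
  # shared by all three traits
  three <- trait_overlap(tw, c("CW", "EMA", "YW"))
  expect_true(all(c("PLAG1", "XKR4", "ATP6V1H", "RGS20") %in% three))
  # exclusive mode drops genes annotated to any other trait
  expect_true(length(trait_overlap(tw, c("CW", "YW"), exclusive = TRUE)) <=
                length(trait_overlap(tw, c("CW", "YW"))))
  # a single trait returns its full unique gene set
  expect_length(trait_overlap(tw, "BT"), length(unique(
    tw$symbol[tw$trait == "BT" & !is.na(tw$symbol)])))
  expect_error(trait_overlap(tw, "XX"), "unknown trait")
})

test_that("gene-trait network has one edge per distinct trait-gene pair", {
  g <- build_gene_trait_network(tw)
  expect_equal(sum(igraph::V(g)$type == "trait"), 5)
  deg <- igraph::degree(g)
  # edges at the YW node = its distinct annotated symbols
  yw_unique <- length(unique(tw$symbol[tw$trait == "YW" & !is.na(tw$symbol)]))
  expect_equal(unname(deg["YW"]), yw_unique)
  # bipartite: no edge joins two traits or two genes
  ends <- igraph::as_data_frame(g, what = "edges")
  tset <- igraph::V(g)$name[igraph::V(g)$type == "trait"]
  expect_true(all(xor(ends$from %in% tset, ends$to %in% tset)))
  # shuffling the rows yields the same degree sequence
  g2 <- build_gene_trait_network(tw[sample(nrow(tw)), ])
  expect_equal(unname(sort(igraph::degree(g2))), unname(sort(deg)))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  # empty input
  g0 <- build_gene_trait_network(tw[0, ])
  expect_equal(igraph::vcount(g0), 0)
})

test_that("miRNA-gene network counts targets and finds hubs", {
  mt <- load_mirna_targets()
  expect_length(unique(mt$gene), 42)
  expect_equal(mt$gene[mt$note == "not_in_table2"], "PPM1L")
  g <- build_mirna_gene_network(mt)
  expect_equal(sum(igraph::V(g)$type == "miRNA"), 3)
  # star interaction graph: the centre is the hub
  inter <- data.frame(gene1 = "HUB", gene2 = paste0("g", 1:5))
  targ <- data.frame(mirna = "mir-x", gene = "g1")
  gs <- build_mirna_gene_network(targ, inter)
  expect_equal(gs$hub, "HUB")
  expect_error(build_mirna_gene_network(targ,
                                        data.frame(gene1 = "a", gene2 = "a")),
               "self-loops")
  g0 <- build_mirna_gene_network(data.frame(mirna = character(0),
                                            gene = character(0)))
  expect_equal(igraph::vcount(g0), 0)
})

test_that("window-to-gene assignment follows the interval rule", {
  win <- data.frame(chrom = "1", start_bp = 1000, end_bp = 2000,
                    gv_percent = 1.5)
  genes <- data.frame(
    symbol = c("inside", "straddle", "outside", "wrong_chrom"),
    chrom = c("1", "1", "1", "2"),
    start_bp = c(1200, 900, 2500, 1200), end_bp = c(1400, 1100, 2600, 1400))
  hit <- map_windows_to_genes(win, genes)
  expect_setequal(hit$symbol, c("inside", "straddle"))
  # strict containment drops the straddler
  hit2 <- map_windows_to_genes(win, genes, mode = "within")
  expect_setequal(hit2$symbol, "inside")
  # no gene on the window: NA placeholder row
  far <- data.frame(symbol = "far", chrom = "1", start_bp = 9e6, end_bp = 1e7)
  expect_true(is.na(map_windows_to_genes(win, far)$symbol))
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  bg <- paste0("g", 1:10)
  sets <- list(term = bg[1:5])
  res <- hypergeometric_enrichment(bg[2:5], bg, sets)
  expect_equal(res$p, 5 / 210)  # C(5,4) C(5,0) / C(10,4)
  expect_equal(res$p, enumerate_hyper_p(bg, sets$term, 4, 4))
  # random configurations against the enumeration oracle
  set.seed(101)
  for (rep in 1:5) {
    bg2 <- paste0("h", 1:12)
    term <- sample(bg2, sample(3:6, 1))
    lst <- sample(bg2, 5)
    ov <- length(intersect(term, lst))
    p_pkg <- hypergeometric_enrichment(lst, bg2,
                                       list(t = term))$p
    expect_equal(p_pkg, enumerate_hyper_p(bg2, term, 5, ov))
  }
  # empty term and zero overlap give p = 1; single term: p_adj = p
  res0 <- hypergeometric_enrichment(bg[1:2], bg,
                                    list(none = character(0),
                                         disjoint = bg[9:10]))
  expect_equal(res0$p, c(1, 1))
  res1 <- hypergeometric_enrichment(bg[1:3], bg, list(t = bg[1:4]))
  expect_equal(res1$p_adj, res1$p)
  expect_true(all(res1$p_adj >= res1$p))
  expect_error(hypergeometric_enrichment("zzz", bg, list(t = bg[1:2])),
               "outside the background")
  expect_error(hypergeometric_enrichment("a", character(0), list()),
               "empty background")
})
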