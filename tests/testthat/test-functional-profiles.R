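make_ann <- function(gene_id, cog_family, category)
  cog_annotation(data.frame(gene_id = gene_id, cog_family = cog_family,
                            category = category, stringsAsFactors = FALSE))

test_that("the COG matrix counts annotated genes per genome and family", {
  set.seed(51)
  g1 <- make_gene_set("g1", setNames(replicate(5, rand_dna(80)),
                                     paste0("a", 1:5)))
  g2 <- make_gene_set("g2", setNames(replicate(3, rand_dna(80)),
                                     paste0("b", 1:3)))
  ann <- make_ann(c("a1", "a2", "a3", "a4", "b1", "b2"),
                  c("COG1", "COG1", "COG1", "COG2", "COG3", "COG3"),
                  c("J", "J", "J", "K", "L", "L"))
  m <- build_cog_matrix(list(g1, g2), ann)
  expect_equal(m["g1", "COG1"], 3L)
  expect_equal(m["g1", "COG2"], 1L)
  expect_equal(m["g1", "COG3"], 0L)
  expect_equal(m["g2", "COG3"], 2L)
  # block-diagonal for disjoint families; zero rows retained
  g3 <- make_gene_set("g3", c(c1 = rand_dna(80)))
  m2 <- build_cog_matrix(list(g1, g2, g3), ann)
  expect_true(all(m2["g3", ] == 0))
})

test_that("the low-abundance column filter is strict at the 10% boundary", {
  m <- matrix(0L, 10, 3, dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  m[1, "A"] <- 1L          # sum 1 = 10% of 10 genomes -> kept
  m[, "B"] <- 0L           # sum 0 -> removed
  m[1:5, "C"] <- 1L        # sum 5 -> kept
  f <- filter_low_abundance_columns(m)
  expect_setequal(colnames(f), c("A", "C"))
  # 20 genomes: a sum of 1 falls below 2 and is removed
  m20 <- matrix(0L, 20, 2, dimnames = list(paste0("g", 1:20), c("A", "C")))
  m20[1, "A"] <- 1L
  m20[1:2, "C"] <- 1L
  f20 <- filter_low_abundance_columns(m20)
  expect_setequal(colnames(f20), "C")
  expect_equal(filter_low_abundance_columns(f20), f20)  # idempotent
  expect_error(filter_low_abundance_columns(m[, "B", drop = FALSE]),
               "every COG")
})

test_that("functional trees reproduce average-linkage Manhattan heights", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 1), r3 = c(10, 10))
  colnames(m) <- c("C1", "C2")
  tr <- functional_tree(m)
  d <- leaf_path_distances(tr)
  # first merge joins r1, r2 at L1 = 1; r3 joins at mean(20, 19) = 19.5
  expect_equal(unname(d["r1", "r2"]), 1)
  expect_equal(unname(d["r1", "r3"]), 19.5)
  expect_equal(unname(d["r2", "r3"]), 19.5)
  # identical rows merge at height zero
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(8, 9))
  expect_equal(unname(leaf_path_distances(functional_tree(m2))["a", "b"]), 0)
  # row order does not change the tree
  set.seed(52)
  m3 <- matrix(rpois(7 * 4, 3), 7, 4,
               dimnames = list(paste0("g", 1:7), paste0("C", 1:4)))
  t1 <- functional_tree(m3)
  t2 <- functional_tree(m3[sample.int(7), ])
  expect_equal(leaf_path_distances(t1), leaf_path_distances(t2))
  expect_error(functional_tree(m3[1:2, ]), "at least 3")
})

test_that("family category assignment follows the at-least-half rule", {
  ann <- make_ann(c("x1", "x2", "x3", "y1", "y2", "z1", "z2"),
                  paste0("COG", 1:7),
                  c("J", "J", "J", "J", "K", "KT", "KT"))
  expect_equal(assign_family_category(c("x1", "x2", "x3", "x4"), ann), "J")
  # 2 J vs 2 K in a family of 4: tie at exactly one half
  ann2 <- make_ann(c("p1", "p2", "p3", "p4"), paste0("COG", 1:4),
                   c("J", "J", "K", "K"))
  expect_warning(out <- assign_family_category(paste0("p", 1:4), ann2), "tie")
  expect_true(is.na(out))
  # fully unannotated family
  expect_true(is.na(assign_family_category(c("q1", "q2"), ann)))
  # multi-letter codes split fractionally: two KT genes give K = T = 0.5
  expect_warning(out2 <- assign_family_category(c("z1", "z2"), ann), "tie")
  expect_true(is.na(out2))
  # below half: one J among four members
  expect_true(is.na(assign_family_category(c("x1", "q1", "q2", "q3"), ann)))
})

test_that("hypergeometric enrichment matches closed forms and brute force", {
  bg <- make_ann(paste0("b", 1:10), paste0("COG", 1:10),
                 c(rep("J", 5), rep("K", 5)))
  core <- paste0("b", 1:3)  # 3 core genes, all J
  res <- category_enrichment(core, bg)
  pJ <- res$p_value[res$category == "J"]
  expect_equal(pJ, choose(5, 3) / choose(10, 3), tolerance = 1e-12)
  expect_false(res$enriched[res$category == "J"])  # 1/12 > 0.05
  # k = 0 has upper-tail probability 1
  expect_equal(res$p_value[res$category == "K"], 1)
  # brute-force combinatorial sum at N=100, K=10, n=10, k=8
  N <- 100; K <- 10; n <- 10; k <- 8
  brute <- sum(vapply(k:n, function(j)
    choose(K, j) * choose(N - K, n - j), 0)) / choose(N, n)
  set.seed(53)
  bg2 <- make_ann(paste0("g", 1:N), paste0("COG", 1:N),
                  c(rep("J", K), rep("S", N - K)))
  core2 <- paste0("g", c(1:8, 50, 51))  # 8 of the 10 J genes among 10 draws
  res2 <- category_enrichment(core2, bg2)
  expect_equal(res2$p_value[res2$category == "J"], brute, tolerance = 1e-12)
  expect_true(res2$enriched[res2$category == "J"])
  # monotone decreasing in k for fixed margins
  ps <- vapply(0:10, function(kk)
    phyper(kk - 1, K, N - K, n, lower.tail = FALSE), 0)
  expect_true(all(diff(ps) <= 0))
  # empty draw set
  expect_equal(nrow(category_enrichment(character(0), bg)), 0L)
  # a BH-adjusted variant is available
  res_bh <- category_enrichment(core2, bg2, adjust = "BH")
  expect_true(all(res_bh$p_value >= res2$p_value - 1e-15))
})

test_that("each core family is assigned at most one category overall", {
  set.seed(54)
  fams <- split(paste0("m", 1:20), rep(1:5, each = 4))
  ann <- make_ann(paste0("m", 1:20), paste0("COG", rep(1:5, each = 4)),
                  sample(c("J", "K", "L", "S"), 20, TRUE))
  cats <- vapply(fams, assign_family_category, "", ann = ann)
  expect_lte(sum(!is.na(cats)), length(fams))
})

test_that("annotation and matrix files round-trip", {
  ann <- make_ann(c("a1", "a2"), c("COG1", "COG2"), c("J", "KT"))
  tf <- tempfile()
  write_cog_annotation(ann, tf)
  expect_equal(read_cog_annotation(tf)$category, c("J", "KT"))
  expect_error(make_ann("a1", "COG1", "j7"), "invalid category")
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("C1", "C2")))
  tm <- tempfile()
  write_cog_matrix_tsv(m, tm)
  expect_equal(dim(utils::read.delim(tm)), c(2L, 3L))
})
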