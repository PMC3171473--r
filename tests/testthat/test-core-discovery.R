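test_that("leaf families are connected components of within-genome homology", {
  set.seed(21)
  # five mutually unrelated genes -> five singleton families
  gs <- make_gene_set("g1", setNames(replicate(5, rand_dna(300)),
                                     paste0("x", 1:5)))
  lc <- leaf_cores(gs)
  expect_length(lc$families, 5L)
  expect_true(all(vapply(lc$families, function(f) length(f$members), 1L) == 1))

  # an exact duplicate pair joins one family
  dup <- rand_dna(300)
  gs2 <- make_gene_set("g1", c(x1 = dup, x2 = dup, y1 = rand_dna(300),
                               y2 = rand_dna(300), y3 = rand_dna(300)))
  lc2 <- leaf_cores(gs2)
  expect_length(lc2$families, 4L)
  sizes <- sort(unname(vapply(lc2$families, function(f) length(f$members), 1L)))
  expect_equal(sizes, c(1L, 1L, 1L, 2L))
})

test_that("leaf families close transitively: x1~x2, x2~x3 but x1 !~ x3", {
  set.seed(22)
  x2 <- rand_dna(600)
  x1 <- substr(x2, 1, 300)      # overlaps x2 only
  x3 <- substr(x2, 301, 600)    # overlaps x2 only, disjoint from x1
  gs <- make_gene_set("g1", c(x1 = x1, x2 = x2, x3 = x3))
  lc <- leaf_cores(gs)
  expect_length(lc$families, 1L)
  expect_setequal(lc$families[[1]]$members, c("x1", "x2", "x3"))
  # the brute-force hit graph confirms the same single component
  gt <- data.frame(gene_id = c("x1", "x2", "x3"), genome_id = "g1",
                   seq = c(x1, x2, x3), stringsAsFactors = FALSE)
  pairs <- oracle_hit_pairs(gt)
  comp <- oracle_components(gt$gene_id, pairs)
  expect_length(unique(comp), 1L)
})

test_that("clade cores require a family from every direct child", {
  set.seed(23)
  a <- rand_dna(400)
  b <- rand_dna(400)
  sets <- list(
    make_gene_set("g1", c(a1 = a, b1 = b)),
    make_gene_set("g2", c(a2 = a, b2 = b)),
    make_gene_set("g3", c(a3 = a, b3 = rand_dna(400))))
  gt <- coregenes:::as_gene_table(sets)
  children <- lapply(sets, leaf_cores)
  cc <- clade_cores("clade", children, gt)
  # only the a-family is ubiquitous; b lacks a homolog in g3
  expect_length(cc$families, 1L)
  expect_setequal(cc$families[[1]]$members, c("a1", "a2", "a3"))
})

test_that("a coreless child empties the clade without a search", {
  set.seed(24)
  sets <- list(
    structure(list(clade_id = "c1", families = list(), n_genomes = 1L),
              class = "clade_core_set"),
    leaf_cores(make_gene_set("g2", c(x = rand_dna(300)))))
  cc <- clade_cores("clade", sets, data.frame(gene_id = character(),
                                              genome_id = character(),
                                              seq = character()))
  expect_length(cc$families, 0L)
  expect_true(attr(cc, "stopped"))
})

test_that("paralogs are captured into the clade family per genome", {
  set.seed(25)
  a <- rand_dna(400)
  g1 <- make_gene_set("g1", c(a1 = a, a1p = mutate_dna(a, 0.05),
                              z1 = rand_dna(300)))
  g2 <- make_gene_set("g2", c(a2 = mutate_dna(a, 0.02), z2 = rand_dna(300)))
  gt <- coregenes:::as_gene_table(list(g1, g2))
  cc <- clade_cores("clade", list(leaf_cores(g1), leaf_cores(g2)), gt)
  expect_length(cc$families, 1L)
  fam <- cc$families[[1]]
  expect_setequal(fam$members, c("a1", "a1p", "a2"))
  expect_setequal(fam$per_genome$g1, c("a1", "a1p"))
  expect_equal(fam$per_genome$g2, "a2")
})

test_that("a single genome run reduces to its leaf families", {
  set.seed(26)
  tax <- lineage_taxonomy("g1\tR\tS")
  gs <- make_gene_set("g1", c(x = rand_dna(300), y = rand_dna(300)))
  res <- run_core_discovery(tax, list(g1 = gs))
  expect_equal(sum(res$clade_summary$status == "leaf"), 1L)
  # families pass through the singleton chain and surface at the top clade
  expect_setequal(unique(res$catalog$clade_id), "R")
  expect_length(res$families, 2L)
})

test_that("zero-divergence planted cores surface with the planted counts", {
  tax <- lineage_taxonomy(c("g1\tR\tA", "g2\tR\tA", "g3\tR\tB", "g4\tR\tB"))
  cfg <- sim_config(tax, n_core_per_clade = c(R = 3, "R/A" = 2, "R/B" = 1),
                    n_accessory_per_genome = 0, branch_sub_rate = 0,
                    paralog_dup_prob = 0, decoy_16s_trna = FALSE,
                    plasmid_fraction = 0, gene_len_range = c(300, 400),
                    seed = 101)
  sim <- simulate_pangenome(cfg)
  res <- run_core_discovery(sim$taxonomy, sim$genomes)
  s <- res$clade_summary
  # at-clade counts: every planted family above a clade is also core there
  expect_equal(s$n_core[s$clade_id == "R"], 3L)
  expect_equal(s$n_core[s$clade_id == "R/A"], 5L)  # 3 from R + 2 planted
  expect_equal(s$n_core[s$clade_id == "R/B"], 4L)
  # terminal counts match the planting
  expect_equal(s$n_terminal[s$clade_id == "R"], 3L)
  expect_equal(s$n_terminal[s$clade_id == "R/A"], 2L)
  expect_equal(s$n_terminal[s$clade_id == "R/B"], 1L)
  ev <- truth_eval(res, sim)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("the stop rule propagates corelessness to all ancestors", {
  set.seed(27)
  tax <- lineage_taxonomy(c("g1\tR\tA", "g2\tR\tA", "g3\tR\tB", "g4\tR\tB"))
  # plant only under A: B's genomes share nothing, so R/B has no core and
  # R stops without searching
  cfg <- sim_config(tax, n_core_per_clade = c("R/A" = 2),
                    n_accessory_per_genome = 3, branch_sub_rate = 0.01,
                    paralog_dup_prob = 0, decoy_16s_trna = FALSE,
                    plasmid_fraction = 0, gene_len_range = c(300, 400),
                    seed = 102)
  sim <- simulate_pangenome(cfg)
  res <- run_core_discovery(sim$taxonomy, sim$genomes)
  s <- res$clade_summary
  expect_equal(s$n_core[s$clade_id == "R/B"], 0L)
  expect_equal(s$n_core[s$clade_id == "R"], 0L)
  expect_equal(s$status[s$clade_id == "R"], "stopped")
  expect_true("R" %in% res$stop_log$clade_id)
})

test_that("representatives prefer the variant closest to single-member orthologs", {
  set.seed(28)
  a <- rand_dna(400)
  fam <- list(per_genome = list(
    g1 = c("p", "pp"), g2 = "o2", g3 = "o3"))
  gt <- data.frame(
    gene_id = c("p", "pp", "o2", "o3"),
    seq = c(a, mutate_dna(a, 0.05), mutate_dna(a, 0.005), mutate_dna(a, 0.005)),
    stringsAsFactors = FALSE)
  out <- select_representative(fam, gt)
  expect_equal(unname(out$representative[c("g2", "g3")]), c("o2", "o3"))
  expect_equal(unname(out$representative["g1"]), "p")
  # all-multi fallback: medoid by mean intra-family score
  fam2 <- list(per_genome = list(g1 = c("p", "pp"), g2 = c("q", "qq")))
  gt2 <- data.frame(
    gene_id = c("p", "pp", "q", "qq"),
    seq = c(a, mutate_dna(a, 0.2), mutate_dna(a, 0.02), mutate_dna(a, 0.25)),
    stringsAsFactors = FALSE)
  out2 <- select_representative(fam2, gt2)
  expect_equal(unname(out2$representative["g1"]), "p")
  expect_equal(unname(out2$representative["g2"]), "q")
  expect_error(select_representative(list(per_genome = list(g1 = character())),
                                     gt),
               "no members")
})

test_that("global exclusivity and ubiquity hold on a mixed scenario", {
  tax <- lineage_taxonomy(c("g1\tR\tA", "g2\tR\tA", "g3\tR\tA",
                            "g4\tR\tB", "g5\tR\tB"))
  cfg <- sim_config(tax, n_core_per_clade = c(R = 2, "R/A" = 2, "R/B" = 2),
                    n_accessory_per_genome = 3, branch_sub_rate = 0.02,
                    paralog_dup_prob = 0.3, decoy_16s_trna = TRUE,
                    gene_len_range = c(300, 500), seed = 103)
  sim <- simulate_pangenome(cfg)
  kept <- filter_genomes(sim$genomes, input_filter_config(min_genes = 0))$kept
  res <- run_core_discovery(sim$taxonomy, kept)
  # every gene in at most one catalog family
  expect_false(anyDuplicated(res$catalog$gene_id) > 0)
  expect_setequal(res$consumed, res$catalog$gene_id)
  # ubiquity: each family covers exactly the genomes under its clade
  for (fid in names(res$families)) {
    f <- res$families[[fid]]
    covered <- names(f$per_genome)
    under <- if (f$clade_id %in% sim$taxonomy$nodes$taxon_id)
      genomes_under(sim$taxonomy, f$clade_id) else f$clade_id
    expect_setequal(covered, under)
  }
})

test_that("at-clade family counts are monotone up the hierarchy", {
  tax <- lineage_taxonomy(c("g1\tR\tA", "g2\tR\tA", "g3\tR\tB", "g4\tR\tB"))
  cfg <- sim_config(tax, n_core_per_clade = c(R = 2, "R/A" = 3),
                    n_accessory_per_genome = 4, branch_sub_rate = 0.03,
                    paralog_dup_prob = 0.2, gene_len_range = c(300, 500),
                    seed = 104)
  sim <- simulate_pangenome(cfg)
  kept <- filter_genomes(sim$genomes, input_filter_config(min_genes = 0))$kept
  res <- run_core_discovery(sim$taxonomy, kept)
  s <- setNames(res$clade_summary$n_core, res$clade_summary$clade_id)
  for (cl in names(res$clade_children)) {
    kids <- res$clade_children[[cl]]
    expect_lte(s[[cl]], min(s[kids]))
  }
})

test_that("results do not depend on sibling order in the taxonomy", {
  cfgmk <- function(tax) sim_config(
    tax, n_core_per_clade = setNames(c(2, 1), c(tax$root,
                                                tax$nodes$taxon_id[2])),
    n_accessory_per_genome = 2, branch_sub_rate = 0.02,
    paralog_dup_prob = 0, decoy_16s_trna = FALSE,
    gene_len_range = c(300, 400), seed = 105)
  tax1 <- lineage_taxonomy(c("g1\tR\tA", "g2\tR\tA", "g3\tR\tB", "g4\tR\tB"))
  sim <- simulate_pangenome(cfgmk(tax1))
  tax2 <- lineage_taxonomy(c("g4\tR\tB", "g3\tR\tB", "g2\tR\tA", "g1\tR\tA"))
  res1 <- run_core_discovery(tax1, sim$genomes)
  res2 <- run_core_discovery(tax2, sim$genomes)
  key <- function(res) sort(vapply(res$families,
                                   function(f) paste(sort(f$members),
                                                     collapse = "|"), ""))
  expect_equal(key(res1), key(res2))
})

test_that("catalog exports round-trip", {
  set.seed(29)
  tax <- lineage_taxonomy(c("g1\tR\tA", "g2\tR\tA"))
  a <- rand_dna(300)
  res <- run_core_discovery(tax, list(
    g1 = make_gene_set("g1", c(a1 = a, z1 = rand_dna(300))),
    g2 = make_gene_set("g2", c(a2 = a, z2 = rand_dna(300)))))
  tf <- tempfile(); write_core_tsv(res, tf)
  expect_equal(nrow(utils::read.delim(tf)), nrow(res$catalog))
  tj <- tempfile(); write_core_summary_json(res, tj)
  expect_named(jsonlite::read_json(tj), res$clade_summary$clade_id,
               ignore.order = TRUE)
  ff <- tempfile(); export_representatives_fasta(res, ff)
  expect_equal(length(Biostrings::readDNAStringSet(ff)),
               sum(res$catalog$is_representative))
})
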