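test_that("FASTA records parse in order with header split at first whitespace", {
  tf <- tempfile(fileext = ".ffn")
  write_fasta_lines(tf,
    c("g1 DNA polymerase III", "g2", "g7 tRNA-Ala"),
    c("acgtacgt", "AACCGGTT", "ACGRYACGn"))
  gs <- read_gene_fasta(tf, "gen1")
  expect_s3_class(gs, "gene_set")
  expect_equal(gs$genes$gene_id, c("g1", "g2", "g7"))
  expect_equal(gs$genes$product, c("DNA polymerase III", "", "tRNA-Ala"))
  # lowercase uppercased, non-ACGT IUPAC letters mapped to N
  expect_equal(gs$genes$seq, c("ACGTACGT", "AACCGGTT", "ACGNNACGN"))
})

test_that("empty FASTA yields an empty gene set; malformed input names a line", {
  tf <- tempfile(); writeLines(character(0), tf)
  expect_equal(length(read_gene_fasta(tf, "gen1")), 0L)
  bad <- tempfile()
  writeLines(c(">g1", "ACGT", "not a sequence line !!"), bad)
  expect_error(read_gene_fasta(bad, "gen1"), "line 3")
  nohdr <- tempfile()
  writeLines(c("ACGT"), nohdr)
  expect_error(read_gene_fasta(nohdr, "gen1"), "line 1")
})

test_that("duplicate gene ids within a file are rejected", {
  tf <- tempfile()
  write_fasta_lines(tf, c("g1 a", "g1 b"), c("ACGT", "ACGT"))
  expect_error(read_gene_fasta(tf, "gen1"), "duplicate gene_id")
})

test_that("replicon is inferred from the header token and sidecar overrides win", {
  tf <- tempfile()
  write_fasta_lines(tf, c("g1 replication protein [plasmid pXY]", "g2 gyrase"),
                    c("ACGTACGT", "ACGTACGT"))
  gs <- read_gene_fasta(tf, "gen1")
  expect_equal(gs$genes$replicon, c("plasmid", "chromosome"))
  side <- tempfile()
  writeLines(c("gene_id\treplicon", "g2\tplasmid"), side)
  gs2 <- read_gene_fasta(tf, "gen1", replicon_tsv = side)
  expect_equal(gs2$genes$replicon, c("plasmid", "plasmid"))
})

test_that("concatenation merges files in order and renames collisions", {
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta_lines(f1, c("a1 x", "a2 y"), c("ACGT", "ACGT"))
  write_fasta_lines(f2, c("b1 x", "b2 y", "b3 z"), c("ACGT", "ACGT", "ACGT"))
  gs <- concatenate_genome_files(c(f1, f2), "gen1")
  expect_equal(length(gs), 5L)
  expect_equal(gs$genes$gene_id, c("a1", "a2", "b1", "b2", "b3"))
  # one file is the same as a plain read
  expect_equal(concatenate_genome_files(f1, "gen1"), read_gene_fasta(f1, "gen1"))
  # same file twice: collisions suffixed, warning raised
  expect_warning(gs2 <- concatenate_genome_files(c(f1, f1), "gen1"),
                 "colliding")
  expect_equal(length(gs2), 4L)
  expect_equal(sum(grepl("\\.2$", gs2$genes$gene_id)), 2L)
  expect_error(concatenate_genome_files(character(0), "gen1"), "no input")
})

test_that("genomes below the minimum gene count are rejected", {
  gs <- make_gene_set("small", setNames(replicate(399, rand_dna(80)),
                                        paste0("s", 1:399)))
  expect_true(is_rejected(apply_input_filters(gs, input_filter_config())))
  gs2 <- make_gene_set("ok", setNames(replicate(400, rand_dna(80)),
                                      paste0("s", 1:400)))
  expect_false(is_rejected(apply_input_filters(gs2, input_filter_config())))
})

test_that("16S and tRNA annotations are excluded case-insensitively", {
  set.seed(1)
  prods <- c(rep("hypothetical protein", 458),
             rep("16S ribosomal RNA", 2), paste0("tRNA-", month.abb[1:10]),
             rep("tRNA-Ala", 30))
  gs <- make_gene_set("gen1", setNames(replicate(500, rand_dna(80)),
                                       paste0("x", 1:500)), products = prods)
  out <- apply_input_filters(gs, input_filter_config())
  expect_equal(length(out), 458L)
  expect_false(any(grepl("tRNA|16S", out$genes$product)))
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["n_pattern_removed"]), 42)
})

test_that("plasmid genes are removed before the minimum-count rule applies", {
  repl <- c(rep("plasmid", 60), rep("chromosome", 390))
  gs <- make_gene_set("gen1", setNames(replicate(450, rand_dna(80)),
                                       paste0("x", 1:450)), replicon = repl)
  expect_true(is_rejected(apply_input_filters(gs, input_filter_config())))
  # without plasmid removal the same genome passes
  keep_cfg <- input_filter_config(drop_plasmid_only = FALSE)
  expect_false(is_rejected(apply_input_filters(gs, keep_cfg)))
})

test_that("filtering is idempotent and independent of record order", {
  set.seed(42)
  prods <- sample(c("hypothetical protein", "tRNA-Gly", "16S rRNA gene"),
                  60, TRUE, prob = c(0.7, 0.2, 0.1))
  repl <- sample(c("chromosome", "plasmid"), 60, TRUE, prob = c(0.8, 0.2))
  gs <- make_gene_set("gen1", setNames(replicate(60, rand_dna(80)),
                                       paste0("x", 1:60)),
                      products = prods, replicon = repl)
  cfg <- input_filter_config(min_genes = 0)
  once <- apply_input_filters(gs, cfg)
  twice <- apply_input_filters(once, cfg)
  expect_equal(once$genes, twice$genes)
  perm <- gene_set("gen1", gs$genes[sample.int(60), ])
  out_perm <- apply_input_filters(perm, cfg)
  expect_setequal(out_perm$genes$gene_id, once$genes$gene_id)
})

test_that("gene sets round-trip through FASTA with plasmid tags", {
  gs <- make_gene_set("gen1", c(a = rand_dna(90), b = rand_dna(90)),
                      products = c("thing one", "thing two"),
                      replicon = c("plasmid", "chromosome"))
  tf <- tempfile(fileext = ".fasta")
  write_gene_fasta(gs, tf)
  back <- read_gene_fasta(tf, "gen1")
  expect_equal(back$genes$gene_id, gs$genes$gene_id)
  expect_equal(back$genes$seq, gs$genes$seq)
  expect_equal(back$genes$replicon, gs$genes$replicon)
})

test_that("filter_genomes reports per-genome counts and status", {
  g1 <- make_gene_set("gen1", setNames(replicate(5, rand_dna(80)),
                                       paste0("a", 1:5)))
  g2 <- make_gene_set("gen2", setNames(replicate(3, rand_dna(80)),
                                       paste0("b", 1:3)))
  res <- filter_genomes(list(g1, g2), input_filter_config(min_genes = 4))
  expect_equal(res$report$status, c("kept", "rejected"))
  expect_named(res$kept, "gen1")
  tf <- tempfile()
  write_filter_report(res$report, tf)
  expect_equal(nrow(utils::read.delim(tf)), 2L)
})
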