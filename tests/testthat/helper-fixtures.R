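# fixtures and independent oracles used across the suite; the oracles
# deliberately avoid the package's search path (no seeding, own e-value)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_dna <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# mutate exactly k distinct sites
mutate_dna_exact <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  for (i in sample(length(chars), k))
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

revcomp_chr <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

make_gene_set <- function(genome_id, seqs, products = NULL,
                          replicon = "chromosome") {
  if (is.null(names(seqs))) names(seqs) <- paste0(genome_id, "_g", seq_along(seqs))
  if (is.null(products)) products <- rep("hypothetical protein", length(seqs))
  gene_set(genome_id,
           data.frame(gene_id = names(seqs), product = products,
                      replicon = rep_len(replicon, length(seqs)),
                      seq = unname(seqs), stringsAsFactors = FALSE))
}

write_fasta_lines <- function(path, headers, seqs) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
}

lineage_taxonomy <- function(rows) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(rows, tf)
  load_taxonomy(tf)
}

# ---- brute-force homology oracle ------------------------------------------
# All unordered pairs, both strands, full Smith-Waterman via Biostrings with
# the same scoring scheme; its own Karlin-Altschul e-value (lambda re-derived
# here, db length = total nt of the gene table).

oracle_lambda <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- uniroot(function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1,
                      c(1e-6, 5), tol = 1e-12)$root
    val
  }
})

oracle_submat <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                       baseOnly = FALSE)
    val
  }
})

oracle_align <- function(a_vec, b_vec) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a_vec), Biostrings::DNAStringSet(b_vec),
    type = "local", substitutionMatrix = oracle_submat(),
    gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(al),
       aln_len = nchar(as.character(Biostrings::alignedPattern(al))))
}

# qualifying unordered gene pairs under the thresholds; returns two-column
# matrix of gene ids
oracle_hit_pairs <- function(gene_table, min_aln_len = 75, evalue_max = 1e-3,
                             both_strands = TRUE) {
  n <- nrow(gene_table)
  if (n < 2) return(matrix(character(0), ncol = 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- gene_table$seq[idx[, 1]]
  b <- gene_table$seq[idx[, 2]]
  fw <- oracle_align(a, b)
  score <- fw$score; alen <- fw$aln_len
  if (both_strands) {
    rv <- oracle_align(a, vapply(b, revcomp_chr, ""))
    better <- rv$score > score
    score[better] <- rv$score[better]
    alen[better] <- rv$aln_len[better]
  }
  db_len <- sum(nchar(gene_table$seq))
  m <- nchar(a)
  evalue <- m * db_len * 0.46 * exp(-oracle_lambda() * score)
  ok <- score > 0 & alen >= min_aln_len & evalue <= evalue_max
  cbind(gene_table$gene_id[idx[ok, 1]], gene_table$gene_id[idx[ok, 2]])
}

oracle_components <- function(ids, pairs) {
  # simple union-find keyed by gene id
  parent <- setNames(ids, ids)
  findp <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- findp(pairs[k, 1]); rb <- findp(pairs[k, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(ids, findp, "")
}

# top-down oracle partitions: for each canonical clade (root first), the
# connected components of not-yet-consumed genes under the clade that touch
# every genome; returns list clade_id -> list of sorted member sets
oracle_partitions <- function(sim, kept_genomes, min_aln_len = 75,
                              evalue_max = 1e-3) {
  tax <- sim$taxonomy
  gt <- do.call(rbind, lapply(kept_genomes, function(g)
    data.frame(gene_id = g$genes$gene_id, genome_id = g$genome_id,
               seq = g$genes$seq, stringsAsFactors = FALSE)))
  pairs <- oracle_hit_pairs(gt, min_aln_len, evalue_max)
  genome_of <- setNames(gt$genome_id, gt$gene_id)

  canon <- coregenes:::canonical_clades(tax)
  clade_ids <- unique(canon[tax$nodes$taxon_id])
  # order root-down: by number of genomes, descending
  sz <- vapply(clade_ids, function(cl) length(genomes_under(tax, cl)), 0L)
  clade_ids <- clade_ids[order(-sz)]
  # genome pseudo-clades last
  g_pseudo <- setdiff(unique(unname(canon)), clade_ids)

  consumed <- character(0)
  out <- list()
  for (cl in c(clade_ids, g_pseudo)) {
    gset <- if (cl %in% tax$nodes$taxon_id) genomes_under(tax, cl) else cl
    genes <- gt$gene_id[gt$genome_id %in% gset]
    genes <- setdiff(genes, consumed)
    if (!length(genes)) { out[[cl]] <- list(); next }
    sub <- pairs[pairs[, 1] %in% genes & pairs[, 2] %in% genes, , drop = FALSE]
    comp <- oracle_components(genes, sub)
    fams <- split(genes, comp[genes])
    keep <- vapply(fams, function(m)
      setequal(unique(genome_of[m]), gset), TRUE)
    fams <- unname(lapply(fams[keep], sort))
    out[[cl]] <- fams
    consumed <- c(consumed, unlist(fams))
  }
  out
}

# package-side partitions in the same shape: terminal families by canonical
# clade with full member sets
package_partitions <- function(result, sim) {
  canon <- coregenes:::canonical_clades(sim$taxonomy)
  out <- list()
  for (fid in names(result$families)) {
    f <- result$families[[fid]]
    cl <- if (f$clade_id %in% names(canon)) canon[[f$clade_id]] else f$clade_id
    out[[cl]] <- c(out[[cl]], list(sort(f$members)))
  }
  out
}

partition_key <- function(fams)
  sort(vapply(fams, paste, "", collapse = "|"))

# compare oracle and package partitions over all clades present in either
expect_partitions_equal <- function(result, sim, kept) {
  po <- oracle_partitions(sim, kept)
  pp <- package_partitions(result, sim)
  clades <- union(names(po)[vapply(po, length, 1L) > 0],
                  names(pp)[vapply(pp, length, 1L) > 0])
  for (cl in clades) {
    expect_equal(partition_key(pp[[cl]] %||0% list()),
                 partition_key(po[[cl]] %||0% list()),
                 info = paste("clade", cl))
  }
  invisible(TRUE)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# random small scenario for oracle-equivalence checks
random_scenario <- function(seed) {
  set.seed(seed)
  shapes <- list(
    c("gA1\troot\tA", "gA2\troot\tA", "gB1\troot\tB", "gB2\troot\tB"),
    c("gA1\troot\tA", "gA2\troot\tA", "gA3\troot\tA",
      "gB1\troot\tB", "gB2\troot\tB"),
    c("g1\troot\tA\tX", "g2\troot\tA\tX", "g3\troot\tA\tY",
      "g4\troot\tB", "g5\troot\tB"),
    c("g1\troot\tA", "g2\troot\tA", "g3\troot\tB", "g4\troot\tB",
      "g5\troot\tC", "g6\troot\tC"))
  tax <- lineage_taxonomy(shapes[[sample.int(length(shapes), 1)]])
  plantable <- tax$nodes$taxon_id
  n_plant <- sample(2:3, 1)
  clades <- sample(plantable, min(n_plant, length(plantable)))
  counts <- setNames(sample(1:2, length(clades), TRUE), clades)
  cfg <- sim_config(tax, n_core_per_clade = counts,
                    n_accessory_per_genome = sample(1:3, 1),
                    gene_len_range = c(200L, 400L),
                    branch_sub_rate = runif(1, 0, 0.04),
                    paralog_dup_prob = runif(1, 0, 0.25),
                    decoy_16s_trna = sample(c(TRUE, FALSE), 1),
                    plasmid_fraction = 0.1,
                    seed = seed + 1000L)
  sim <- simulate_pangenome(cfg)
  kept <- filter_genomes(sim$genomes, input_filter_config(min_genes = 0))$kept
  list(sim = sim, kept = kept)
}
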