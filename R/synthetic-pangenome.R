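#' Simulation configuration for a synthetic pangenome
#'
#' Describes how gene repertoires evolve down a guide taxonomy: core
#' families planted at chosen clades (one ortholog per descendant genome),
#' per-genome accessory genes drawn fresh (so cross-genome accessory
#' homology is negligible at these lengths), within-genome paralog
#' duplication, decoy 16S/tRNA records, plasmid-tagged genes, and
#' point-substitution divergence per taxonomy branch.
#'
#' @param taxonomy A [guide_taxonomy()].
#' @param n_core_per_clade Named integer vector: clade id to number of core
#'   families planted there (every genome under the clade receives one
#'   ortholog of each).
#' @param n_accessory_per_genome Accessory genes drawn fresh per genome.
#' @param gene_len_range Gene length range in nt (uniform; default
#'   300-1500).
#' @param branch_sub_rate Expected fraction of sites substituted along each
#'   taxonomy branch, in `[0, 1)`.
#' @param paralog_dup_prob Probability that a genome carries an extra
#'   diverged duplicate of a core ortholog.
#' @param decoy_16s_trna Add one decoy "16S ribosomal RNA" record and two
#'   short "tRNA-Xxx" records per genome.
#' @param plasmid_fraction Fraction of accessory genes tagged as
#'   plasmid-borne.
#' @param indel_rate Per-branch probability of a short indel per gene
#'   (geometric length); 0 disables, keeping substitutions only.
#' @param core_category_probs,accessory_category_probs Named probability
#'   vectors over COG category letters for planted and accessory genes.
#' @param n_accessory_cogs Size of the shared accessory COG-family pool.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(taxonomy, n_core_per_clade,
                       n_accessory_per_genome = 10L,
                       gene_len_range = c(300L, 1500L),
                       branch_sub_rate = 0.02,
                       paralog_dup_prob = 0.1,
                       decoy_16s_trna = TRUE,
                       plasmid_fraction = 0.05,
                       indel_rate = 0,
                       core_category_probs = c(J = 0.20, K = 0.15, L = 0.15,
                                               O = 0.10, S = 0.15, C = 0.05,
                                               E = 0.05, G = 0.05, M = 0.05,
                                               P = 0.05),
                       accessory_category_probs = NULL,
                       n_accessory_cogs = 50L,
                       seed) {
  stopifnot(inherits(taxonomy, "guide_taxonomy"))
  if (missing(seed)) stop("a seed is required")
  if (length(n_core_per_clade)) {
    stopifnot(!is.null(names(n_core_per_clade)))
    bad <- setdiff(names(n_core_per_clade), taxonomy$nodes$taxon_id)
    if (length(bad)) stop("unknown clade id(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(branch_sub_rate >= 0, branch_sub_rate < 1,
            paralog_dup_prob >= 0, paralog_dup_prob <= 1,
            plasmid_fraction >= 0, plasmid_fraction <= 1,
            indel_rate >= 0, indel_rate < 1,
            gene_len_range[1] >= 75L, gene_len_range[2] >= gene_len_range[1])
  if (is.null(accessory_category_probs)) {
    letters20 <- c("C","D","E","F","G","H","I","J","K","L","M","N","O","P",
                   "Q","R","S","T","U","V")
    accessory_category_probs <- stats::setNames(
      rep(1 / length(letters20), length(letters20)), letters20)
  }
  structure(list(taxonomy = taxonomy,
                 n_core_per_clade = n_core_per_clade,
                 n_accessory_per_genome = as.integer(n_accessory_per_genome),
                 gene_len_range = as.integer(gene_len_range),
                 branch_sub_rate = branch_sub_rate,
                 paralog_dup_prob = paralog_dup_prob,
                 decoy_16s_trna = decoy_16s_trna,
                 plasmid_fraction = plasmid_fraction,
                 indel_rate = indel_rate,
                 core_category_probs = core_category_probs /
                   sum(core_category_probs),
                 accessory_category_probs = accessory_category_probs /
                   sum(accessory_category_probs),
                 n_accessory_cogs = as.integer(n_accessory_cogs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# uniform integer in [lo, hi]; safe when lo == hi (base sample() would
# treat the single value as a range)
sample_len <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

mutate_seq <- function(seq, rate, indel_rate = 0) {
  if (rate > 0) {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit)) {
      alt <- c("A", "C", "G", "T")
      for (i in hit)
        chars[i] <- sample(setdiff(alt, chars[i]), 1L)
    }
    seq <- paste(chars, collapse = "")
  }
  if (indel_rate > 0 && stats::runif(1) < indel_rate) {
    L <- nchar(seq)
    len <- min(stats::rgeom(1, 0.3) + 1L, max(1L, L %/% 10L))
    pos <- sample.int(L, 1L)
    if (stats::runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1, pos), random_dna(len),
                    substr(seq, pos + 1L, L))
    } else {
      seq <- paste0(substr(seq, 1, max(0L, pos - 1L)),
                    substr(seq, pos + len, L))
    }
  }
  seq
}

# evolve an ancestral sequence down the taxonomy from `clade_id`: one
# mutation round per taxonomy branch, with mutations shared along shared
# lineage, plus one genome-private branch (each genome is its own terminal
# unit, so genomes sharing a terminal taxon still diverge)
evolve_down <- function(tax, clade_id, anc, rate, indel_rate = 0) {
  out <- list()
  recurse <- function(node, seq) {
    for (gid in tax$genomes$genome_id[tax$genomes$taxon_id == node])
      out[[gid]] <<- mutate_seq(seq, rate, indel_rate)
    for (ch in children_of(tax, node))
      recurse(ch, mutate_seq(seq, rate, indel_rate))
  }
  recurse(clade_id, anc)
  out
}

#' Simulate a synthetic pangenome
#'
#' Ancestral sequences are drawn uniformly at random per planted family and
#' mutated independently down each lineage at the per-branch substitution
#' rate; accessory genes are unrelated random sequences; paralogs are
#' within-genome duplicates with one extra branch of divergence; decoy
#' 16S/tRNA records and plasmid tags exercise the input filters. COG
#' families are assigned per planted family and per accessory pool member.
#' Fully reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_pangenome`: `genomes` (named list of
#'   [gene_set()]), `truth` (`planted`: clade_id/family_id;
#'   `genes`: gene_id, family_id or `"ACCESSORY"`/`"DECOY"`, is_paralog),
#'   `cog` (a [cog_annotation()]), `marker_16s` (clade-informative rRNA-like
#'   marker per genome, evolved down the taxonomy), `taxonomy`, `config`.
#' @export
simulate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tax <- cfg$taxonomy
  with_seed(cfg$seed, {
    genome_ids <- tax$genomes$genome_id
    genes <- stats::setNames(vector("list", length(genome_ids)), genome_ids)
    truth_rows <- list()
    cog_rows <- list()
    planted_rows <- list()
    fam_counter <- 0L

    add_gene <- function(gid, gene_id, product, replicon, seq,
                         family, paralog, cog_fam, cog_cat) {
      genes[[gid]][[length(genes[[gid]]) + 1L]] <<-
        data.frame(gene_id = gene_id, product = product, replicon = replicon,
                   seq = seq, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <<-
        data.frame(gene_id = gene_id, family_id = family,
                   is_paralog = paralog, stringsAsFactors = FALSE)
      if (!is.na(cog_fam))
        cog_rows[[length(cog_rows) + 1L]] <<-
          data.frame(gene_id = gene_id, cog_family = cog_fam,
                     category = cog_cat, stringsAsFactors = FALSE)
    }

    # planted core families, clade by clade in postorder for determinism
    clade_order <- intersect(postorder_clades(tax), names(cfg$n_core_per_clade))
    for (clade in clade_order) {
      k <- cfg$n_core_per_clade[[clade]]
      if (k < 1L) next
      under <- genomes_under(tax, clade)
      for (j in seq_len(k)) {
        fam_counter <- fam_counter + 1L
        fam_id <- sprintf("fam%04d", fam_counter)
        planted_rows[[length(planted_rows) + 1L]] <-
          data.frame(clade_id = clade, family_id = fam_id,
                     stringsAsFactors = FALSE)
        len <- sample_len(cfg$gene_len_range[1], cfg$gene_len_range[2])
        anc <- random_dna(len)
        cog_fam <- sprintf("COG%04d", fam_counter)
        cog_cat <- sample(names(cfg$core_category_probs), 1L,
                          prob = cfg$core_category_probs)
        evolved <- evolve_down(tax, clade, anc, cfg$branch_sub_rate,
                               cfg$indel_rate)
        for (gid in under) {
          seq <- evolved[[gid]]
          gene_id <- paste0(gid, "_", fam_id)
          add_gene(gid, gene_id, paste("core protein", fam_id), "chromosome",
                   seq, fam_id, FALSE, cog_fam, cog_cat)
          if (stats::runif(1) < cfg$paralog_dup_prob) {
            dup <- mutate_seq(seq, cfg$branch_sub_rate, cfg$indel_rate)
            add_gene(gid, paste0(gene_id, "_p"),
                     paste("core protein", fam_id, "paralog"), "chromosome",
                     dup, fam_id, TRUE, cog_fam, cog_cat)
          }
        }
      }
    }

    # accessory, decoys, plasmid tags per genome
    acc_pool <- sprintf("ACOG%04d", seq_len(cfg$n_accessory_cogs))
    for (gid in genome_ids) {
      for (j in seq_len(cfg$n_accessory_per_genome)) {
        len <- sample_len(cfg$gene_len_range[1], cfg$gene_len_range[2])
        plasmid <- stats::runif(1) < cfg$plasmid_fraction
        cogf <- sample(acc_pool, 1L)
        cat <- sample(names(cfg$accessory_category_probs), 1L,
                      prob = cfg$accessory_category_probs)
        add_gene(gid, sprintf("%s_acc%03d", gid, j),
                 paste0("hypothetical protein",
                        if (plasmid) " [plasmid]" else ""),
                 if (plasmid) "plasmid" else "chromosome",
                 random_dna(len), "ACCESSORY", FALSE, cogf, cat)
      }
      if (isTRUE(cfg$decoy_16s_trna)) {
        add_gene(gid, paste0(gid, "_rrs"), "16S ribosomal RNA", "chromosome",
                 random_dna(1500L), "DECOY", FALSE, NA, NA)
        add_gene(gid, paste0(gid, "_trna1"), "tRNA-Ala", "chromosome",
                 random_dna(76L), "DECOY", FALSE, NA, NA)
        add_gene(gid, paste0(gid, "_trna2"), "tRNA-Gly", "chromosome",
                 random_dna(76L), "DECOY", FALSE, NA, NA)
      }
    }

    # clade-informative 16S-like marker per genome: one ancestral rRNA
    # evolved down the taxonomy (kept apart from the decoy 16S records,
    # which are random and exist to exercise the input filters)
    anc16 <- random_dna(1200L)
    ev16 <- evolve_down(tax, tax$root, anc16, cfg$branch_sub_rate, 0)
    marker_16s <- vapply(genome_ids, function(gid) ev16[[gid]], "")

    genome_sets <- lapply(genome_ids, function(gid) {
      tab <- do.call(rbind, genes[[gid]])
      gene_set(gid, tab,
               taxon_id = tax$genomes$taxon_id[tax$genomes$genome_id == gid])
    })
    names(genome_sets) <- genome_ids
    structure(list(
      genomes = genome_sets,
      truth = list(planted = if (length(planted_rows))
                     do.call(rbind, planted_rows)
                   else data.frame(clade_id = character(),
                                   family_id = character()),
                   genes = do.call(rbind, truth_rows)),
      cog = cog_annotation(do.call(rbind, cog_rows)),
      marker_16s = marker_16s,
      taxonomy = tax, config = cfg),
      class = "sim_pangenome")
  })
}

#' @export
print.sim_pangenome <- function(x, ...) {
  cat("<sim_pangenome> ", length(x$genomes), " genomes, ",
      nrow(x$truth$planted), " planted families, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated pangenome to disk
#'
#' Emits one FASTA per genome under `dir/genomes/`, plus a lineage TSV, the
#' COG annotation TSV, the 16S-like marker FASTA and a ground-truth JSON at
#' the top level of `dir`.
#'
#' @param sim A [simulate_pangenome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "genomes"), showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes)
    write_gene_fasta(g, file.path(dir, "genomes",
                                  paste0(g$genome_id, ".fasta")))
  lineages <- vapply(sim$genomes, function(g) {
    path <- rev(ancestors_of(sim$taxonomy, g$taxon_id))
    paste(c(g$genome_id, path), collapse = "\t")
  }, "")
  writeLines(unname(lineages), file.path(dir, "lineages.tsv"))
  write_cog_annotation(sim$cog, file.path(dir, "cog_annotation.tsv"))
  marker <- Biostrings::DNAStringSet(sim$marker_16s)
  Biostrings::writeXStringSet(marker, file.path(dir, "marker_16s.fasta"))
  jsonlite::write_json(list(planted = sim$truth$planted,
                            genes = sim$truth$genes),
                       file.path(dir, "truth.json"))
  invisible(dir)
}

ancestors_of <- function(tax, taxon_id) {
  out <- character(0)
  node <- taxon_id
  while (!is.na(node)) {
    out <- c(out, tax$nodes$name[tax$nodes$taxon_id == node])
    node <- tax$nodes$parent_id[tax$nodes$taxon_id == node]
  }
  out
}

# highest clade whose genome set equals this clade's (canonical clade for
# matching: singleton chains are indistinguishable by ubiquity)
canonical_clades <- function(tax) {
  ids <- tax$nodes$taxon_id
  sets <- lapply(ids, function(id) sort(genomes_under(tax, id)))
  keys <- vapply(sets, paste, "", collapse = "|")
  canon <- character(length(ids))
  names(canon) <- ids
  for (key in unique(keys)) {
    grp <- ids[keys == key]
    # the topmost node of the chain is the one none of whose ancestors share
    # the key; chains are nested so the first in node-table order is topmost
    canon[grp] <- grp[1]
  }
  # genome pseudo-clades: canonical to the topmost taxon with the same set
  gcanon <- stats::setNames(tax$genomes$genome_id, tax$genomes$genome_id)
  for (i in seq_len(nrow(tax$genomes))) {
    gid <- tax$genomes$genome_id[i]
    key <- gid
    match_tax <- ids[vapply(sets, function(s) identical(s, key), TRUE)]
    if (length(match_tax)) gcanon[gid] <- canon[match_tax[1]]
  }
  c(canon, gcanon[setdiff(names(gcanon), names(canon))])
}

#' Evaluate a core-discovery run against the simulation ground truth
#'
#' A recovered family matches a planted one iff the recovered per-genome
#' representatives equal the planted ortholog set (paralogs excluded on
#' both sides; a merged or split family counts as zero matches). Precision
#' and recall are computed per clade over clades spanning at least two
#' genomes (single-genome clades trivially hold every accessory singleton),
#' after canonicalizing singleton-chain clades by their genome sets.
#'
#' @param result A [run_core_discovery()] result.
#' @param sim The [simulate_pangenome()] output the run consumed.
#' @return List with `per_clade` (clade_id, n_planted, n_recovered,
#'   n_matched, precision, recall) and overall `precision` and `recall`
#'   (pooled over clades).
#' @export
truth_eval <- function(result, sim) {
  tax <- sim$taxonomy
  canon <- canonical_clades(tax)
  multi <- names(canon)[vapply(names(canon), function(id) {
    if (id %in% tax$nodes$taxon_id) length(genomes_under(tax, id)) >= 2L
    else FALSE
  }, TRUE)]
  eval_clades <- unique(canon[multi])

  planted_sets <- list()
  tg <- sim$truth$genes
  for (i in seq_len(nrow(sim$truth$planted))) {
    cl <- canon[[sim$truth$planted$clade_id[i]]]
    fam <- sim$truth$planted$family_id[i]
    orth <- sort(tg$gene_id[tg$family_id == fam & !tg$is_paralog])
    planted_sets[[cl]] <- c(planted_sets[[cl]],
                            stats::setNames(list(orth), fam))
  }

  recovered_sets <- list()
  cat_df <- result$catalog[result$catalog$is_representative, , drop = FALSE]
  if (nrow(cat_df)) {
    for (fid in unique(cat_df$family_id)) {
      rows <- cat_df[cat_df$family_id == fid, , drop = FALSE]
      cl <- rows$clade_id[1]
      cl <- if (cl %in% names(canon)) canon[[cl]] else cl
      recovered_sets[[cl]] <- c(recovered_sets[[cl]],
                                stats::setNames(list(sort(rows$gene_id)), fid))
    }
  }

  per <- lapply(eval_clades, function(cl) {
    pl <- planted_sets[[cl]]
    rc <- recovered_sets[[cl]]
    matched <- 0L
    if (length(pl) && length(rc)) {
      pk <- vapply(pl, paste, "", collapse = "|")
      rk <- vapply(rc, paste, "", collapse = "|")
      matched <- length(intersect(pk, rk))
    }
    data.frame(clade_id = cl, n_planted = length(pl),
               n_recovered = length(rc), n_matched = matched,
               precision = if (length(rc)) matched / length(rc) else NA_real_,
               recall = if (length(pl)) matched / length(pl) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  tot_p <- sum(per$n_recovered); tot_t <- sum(per$n_planted)
  list(per_clade = per,
       precision = if (tot_p) sum(per$n_matched) / tot_p else NA_real_,
       recall = if (tot_t) sum(per$n_matched) / tot_t else NA_real_)
}
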