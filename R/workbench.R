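#' Tie-corrected Spearman rank correlation
#'
#' Spearman's rho with the usual tie correction (Pearson correlation of
#' ranks) and a two-sided p-value from the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Bundled clade overview table
#'
#' A packaged table of 32 large prokaryotic clades (phylum to genus, each
#' spanning at least 30 sequenced genomes) with their phylogenetic
#' alpha-diversity, genome counts, core-family counts, and COG category
#' composition of the cores (S count, J/K/L and O percentages with
#' enrichment flags).
#'
#' @return A data frame with one row per clade.
#' @export
clade_overview_table <- function() {
  path <- system.file("extdata", "table1_clades.tsv", package = "coregenes",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = TRUE)
}

#' Diversity versus core-count rank correlation on the bundled clade table
#'
#' Runs [spearman_rho()] on alpha-diversity against the number of core gene
#' families across the bundled clades: the clade diversity check that core
#' counts shrink as clades get more diverse.
#'
#' @return List with `rho`, `abs_rho`, `p_value`, `n`.
#' @export
clade_diversity_correlation <- function() {
  tab <- clade_overview_table()
  r <- spearman_rho(tab$alpha_diversity, tab$n_core_families)
  list(rho = r$rho, abs_rho = abs(r$rho), p_value = r$p_value, n = r$n)
}

#' Run the full pipeline from a configuration
#'
#' Stages: read and filter genomes, prune the guide taxonomy, recursive
#' core discovery with representative selection, optional 16S reference
#' tree with per-clade alpha-diversity, optional functional tree and
#' per-clade enrichment from a COG annotation, and a clade summary table.
#' All stages are logged; every output is deterministic given the seed.
#'
#' @param config A named list, or path to a YAML/JSON file, with fields:
#'   `genomes_dir` (FASTA files named `<genome_id>.fasta`; required),
#'   `taxonomy` (lineage TSV or Newick path; required), `out_dir`
#'   (required), and optional `cog_annotation` (TSV), `sixteen_s`
#'   (FASTA of one 16S sequence per genome, record names = genome ids),
#'   `filters` (min_genes, patterns), `params` (word_size, evalue_max,
#'   min_aln_len), `percentile`, `n_perm`, `seed`.
#' @return Invisibly, a list with the main in-memory results; artifacts are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  for (field in c("genomes_dir", "taxonomy", "out_dir"))
    if (is.null(cfg[[field]])) stop("config is missing field '", field, "'")
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  params <- do.call(search_params, cfg$params %||% list())
  fcfg <- do.call(input_filter_config, cfg$filters %||% list())

  stage <- function(...) message("[coregenes] ", ...)

  stage("reading genomes from ", cfg$genomes_dir)
  files <- sort(list.files(cfg$genomes_dir, pattern = "\\.(fa|fasta|ffn)$",
                           full.names = TRUE))
  if (!length(files)) stop("stage genome_io: no FASTA files in ",
                           cfg$genomes_dir)
  genomes <- lapply(files, function(f)
    read_gene_fasta(f, sub("\\.(fa|fasta|ffn)$", "", basename(f))))
  names(genomes) <- vapply(genomes, function(g) g$genome_id, "")

  stage("filtering ", length(genomes), " genomes")
  filt <- filter_genomes(genomes, fcfg)
  write_filter_report(filt$report, file.path(out, "filter_report.tsv"))
  stage(sum(filt$report$status == "kept"), " genomes kept")
  if (!length(filt$kept)) stop("stage filters: every genome was rejected")

  stage("loading taxonomy from ", cfg$taxonomy)
  tax <- load_taxonomy(cfg$taxonomy)
  tax <- prune_taxonomy(tax, names(filt$kept))
  taxonomy_to_newick(tax, file.path(out, "pruned_taxonomy.nwk"))

  stage("recursive core discovery")
  result <- run_core_discovery(tax, filt$kept, params)
  write_core_tsv(result, file.path(out, "core_families.tsv"))
  write_core_summary_json(result, file.path(out, "core_summary.json"))
  stage(length(result$families), " terminal core families across ",
        nrow(result$clade_summary), " clades")

  ref_tree <- NULL
  alpha <- NULL
  if (!is.null(cfg$sixteen_s)) {
    stage("building 16S reference tree")
    recs <- Biostrings::readDNAStringSet(cfg$sixteen_s)
    names(recs) <- sub("\\s.*$", "", names(recs))
    seqs <- stats::setNames(as.character(recs), names(recs))
    seqs <- seqs[intersect(names(seqs), names(filt$kept))]
    if (length(seqs) >= 3) {
      dm <- pairwise_seq_distances(seqs, params)
      ref_tree <- midpoint_root(build_nj_tree(dm))
      write_newick(ref_tree, file.path(out, "reference_16s.nwk"))
      internal <- tax$nodes$taxon_id
      alpha <- vapply(internal, function(cl) {
        memb <- intersect(genomes_under(tax, cl), ref_tree$tip.label)
        if (length(memb) < 1) return(NA_real_)
        alpha_diversity(ref_tree, memb)
      }, 0)
    }
  }

  ann <- NULL
  enr <- NULL
  func_tree <- NULL
  if (!is.null(cfg$cog_annotation)) {
    stage("functional profiling")
    ann <- read_cog_annotation(cfg$cog_annotation)
    cm <- build_cog_matrix(filt$kept, ann)
    cm <- filter_low_abundance_columns(cm)
    write_cog_matrix_tsv(cm, file.path(out, "cog_matrix.tsv"))
    if (nrow(cm) >= 3) {
      func_tree <- functional_tree(cm)
      write_newick(func_tree, file.path(out, "functional_tree.nwk"))
    }
    enr <- lapply(stats::setNames(nm = unique(result$catalog$clade_id)),
                  function(cl) {
      core_genes <- result$catalog$gene_id[result$catalog$clade_id == cl]
      category_enrichment(core_genes, ann)
    })
    enr_tab <- do.call(rbind, lapply(names(enr), function(cl)
      if (nrow(enr[[cl]])) cbind(clade_id = cl, enr[[cl]])))
    if (!is.null(enr_tab))
      utils::write.table(enr_tab, file.path(out, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(ref_tree) && !is.null(func_tree) &&
      length(intersect(ref_tree$tip.label, func_tree$tip.label)) ==
        length(ref_tree$tip.label)) {
    stage("comparing 16S and functional trees")
    cmp <- permutation_pvalue(ref_tree, func_tree,
                              n_perm = cfg$n_perm %||% 1000L, seed = seed,
                              percentile = cfg$percentile %||% 10)
    jsonlite::write_json(unclass(cmp)[c("distance", "p_value",
                                        "n_permutations", "null_mean",
                                        "null_sd", "seed")],
                         file.path(out, "tree_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  stage("writing clade summary")
  summary <- clade_summary_table(result, tax, alpha, ann)
  utils::write.table(summary, file.path(out, "clade_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("done")
  invisible(list(result = result, taxonomy = tax, summary = summary,
                 ref_tree = ref_tree, functional_tree = func_tree,
                 enrichment = enr, report = filt$report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.(ya?ml)$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the yaml package; use JSON instead")
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stopifnot(is.list(config))
  config
}

#' Per-clade summary rows
#'
#' One row per taxonomy clade: genome count, at-clade and terminal core
#' family counts, alpha-diversity on the reference tree when available,
#' and (with an annotation) the S-category core count plus J/K/L and O
#' percentage and enrichment columns.
#'
#' @param result A [run_core_discovery()] result.
#' @param tax The pruned [guide_taxonomy()] the run used.
#' @param alpha Optional named numeric of per-clade alpha-diversities.
#' @param ann Optional [cog_annotation()].
#' @return A data frame, one row per internal clade.
#' @export
clade_summary_table <- function(result, tax, alpha = NULL, ann = NULL) {
  s <- result$clade_summary
  s <- s[s$clade_id %in% tax$nodes$taxon_id, , drop = FALSE]
  s$rank <- tax$nodes$rank[match(s$clade_id, tax$nodes$taxon_id)]
  s$alpha_diversity <- if (!is.null(alpha)) unname(alpha[s$clade_id])
                       else NA_real_
  if (!is.null(ann)) {
    jkl <- o_pct <- s_count <- numeric(nrow(s))
    for (i in seq_len(nrow(s))) {
      genes <- result$catalog$gene_id[result$catalog$clade_id == s$clade_id[i]]
      e <- category_enrichment(genes, ann)
      pick <- function(cat) if (cat %in% e$category)
        e$core_pct[e$category == cat] else 0
      jkl[i] <- sum(vapply(c("J", "K", "L"), pick, 0))
      o_pct[i] <- pick("O")
      s_count[i] <- if ("S" %in% e$category) e$k[e$category == "S"] else 0
    }
    s$n_S_cogs <- s_count
    s$jkl_pct <- round(jkl, 1)
    s$o_pct <- round(o_pct, 1)
  }
  rownames(s) <- NULL
  s
}
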