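#' Read a COG annotation table
#'
#' Tab-delimited with columns `gene_id`, `cog_family`, `category`; category
#' codes are one or more COG letters (e.g. `"J"`, `"KT"`). Genes absent from
#' the table are unannotated.
#'
#' @param path TSV path.
#' @return A data frame of class `cog_annotation`.
#' @export
read_cog_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  cog_annotation(ann)
}

#' @rdname read_cog_annotation
#' @param ann Data frame with columns `gene_id`, `cog_family`, `category`.
#' @export
cog_annotation <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "cog_family", "category") %in% names(ann)))
  if (anyDuplicated(ann$gene_id))
    stop("gene annotated twice: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  bad <- grepl("[^A-Z]", ann$category)
  if (any(bad)) stop("invalid category code(s): ",
                     paste(unique(ann$category[bad]), collapse = ", "))
  class(ann) <- c("cog_annotation", "data.frame")
  ann
}

#' Write a COG annotation table
#' @param ann A [cog_annotation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cog_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genome x COG-family abundance matrix
#'
#' Each genome is summarized by the number of its genes annotated to each
#' COG family; unannotated genes are ignored, genomes with no annotated
#' gene keep an all-zero row, and the column set is the union of observed
#' families (sorted).
#'
#' @param genomes List of [gene_set()] objects.
#' @param ann A [cog_annotation()].
#' @return Integer matrix, rows = genomes, columns = COG families.
#' @export
build_cog_matrix <- function(genomes, ann) {
  g_ids <- vapply(genomes, function(g) g$genome_id, "")
  fams <- sort(unique(ann$cog_family))
  m <- matrix(0L, nrow = length(genomes), ncol = length(fams),
              dimnames = list(g_ids, fams))
  fam_of <- stats::setNames(ann$cog_family, ann$gene_id)
  for (i in seq_along(genomes)) {
    f <- fam_of[genomes[[i]]$genes$gene_id]
    f <- f[!is.na(f)]
    if (length(f)) {
      tab <- table(f)
      m[i, names(tab)] <- m[i, names(tab)] + as.integer(tab)
    }
  }
  m
}

#' Drop low-abundance COG columns
#'
#' A column is kept iff its total count is at least `fraction` of the
#' number of genomes (strictly-less-than columns are removed, so a sum of
#' exactly 10% of the genomes survives the default filter).
#'
#' @param m Abundance matrix from [build_cog_matrix()].
#' @param fraction Fraction of the genome count (default 0.10).
#' @return The filtered matrix (rows unchanged).
#' @export
filter_low_abundance_columns <- function(m, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 1)
  keep <- colSums(m) >= fraction * nrow(m)
  if (!any(keep)) stop("column filter removed every COG family")
  m[, keep, drop = FALSE]
}

#' Functional phylogeny from COG profiles
#'
#' Genomes are clustered agglomeratively with average linkage on Manhattan
#' (L1) row distances; the dendrogram is converted to a tree whose leaf
#' path distances reproduce the linkage merge heights, then midpoint-rooted
#' like the sequence trees. Rows are ordered lexicographically first so
#' merge tie-breaks are deterministic.
#'
#' @param m Abundance matrix (>= 3 rows).
#' @return A rooted `phylo` tree over the genomes.
#' @export
functional_tree <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 genomes")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "manhattan"),
                      method = "average")
  tr <- ape::as.phylo(hc)
  midpoint_root(ape::unroot(tr))
}

#' Assign a core family to a COG category
#'
#' A family is assigned to the category covering at least half of its
#' members. Multi-letter codes contribute fractionally (a gene annotated
#' "KT" adds 1/2 to K and 1/2 to T); unannotated members count in the
#' denominator. A tie at exactly one half between two categories is
#' unassignable and returns `NA` with a warning.
#'
#' @param gene_ids Member gene ids of the family (orthologs and paralogs).
#' @param ann A [cog_annotation()].
#' @return A single category letter, or `NA_character_` when unassigned.
#' @export
assign_family_category <- function(gene_ids, ann) {
  n <- length(gene_ids)
  if (!n) return(NA_character_)
  codes <- ann$category[match(gene_ids, ann$gene_id)]
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return(NA_character_)
  letters_list <- strsplit(codes, "")
  w <- unlist(lapply(letters_list, function(l) rep(1 / length(l), length(l))))
  frac <- tapply(w, unlist(letters_list), sum) / n
  top <- frac[frac == max(frac)]
  if (max(frac) < 0.5) return(NA_character_)
  if (length(top) > 1L) {
    warning("category tie at ", signif(max(frac), 3), " between ",
            paste(names(top), collapse = ", "), "; family unassigned")
    return(NA_character_)
  }
  names(top)
}

#' Hypergeometric COG-category enrichment of core genes
#'
#' For each category the upper-tail hypergeometric probability
#' P(X >= k) is computed with population N = annotated background genes,
#' K = background genes carrying the category, n = annotated core genes
#' (draws), k = core genes carrying the category. Multi-letter codes count
#' integrally in every category they name. No multiple-testing correction
#' is applied by default; the enrichment flag is raw p < 0.05.
#'
#' @param core_gene_ids Gene ids of the clade's core genes.
#' @param ann A [cog_annotation()] covering the whole run.
#' @param background_gene_ids Gene universe (defaults to every annotated
#'   gene in `ann`).
#' @param alpha Enrichment significance level (default 0.05).
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) matches the raw
#'   threshold.
#' @return Data frame: `category`, `k`, `n`, `K`, `N`, `core_pct`
#'   (100 k / n), `p_value`, `enriched`; empty when no core gene is
#'   annotated.
#' @export
category_enrichment <- function(core_gene_ids, ann,
                                background_gene_ids = ann$gene_id,
                                alpha = 0.05, adjust = "none") {
  ann_bg <- ann[ann$gene_id %in% background_gene_ids, , drop = FALSE]
  ann_core <- ann[ann$gene_id %in% core_gene_ids, , drop = FALSE]
  n <- nrow(ann_core)
  if (n == 0L)
    return(data.frame(category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), core_pct = numeric(),
                      p_value = numeric(), enriched = logical()))
  N <- nrow(ann_bg)
  cats <- sort(unique(unlist(strsplit(ann_bg$category, ""))))
  has_cat <- function(codes, cat) grepl(cat, codes, fixed = TRUE)
  res <- lapply(cats, function(cat) {
    K <- sum(has_cat(ann_bg$category, cat))
    k <- sum(has_cat(ann_core$category, cat))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k = k, n = n, K = K, N = N,
               core_pct = 100 * k / n, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$enriched <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Write an abundance matrix as TSV
#' @param m Matrix with genome rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cog_matrix_tsv <- function(m, path) {
  utils::write.table(cbind(genome_id = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
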