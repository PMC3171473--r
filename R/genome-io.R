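#' Gene set container
#'
#' A `gene_set` holds one genome's annotated nucleotide genes: the unit the
#' recursive core search consumes. Sequences are stored uppercase over the
#' alphabet A, C, G, T, N (any other IUPAC letter is mapped to N on input).
#'
#' @param genome_id Genome identifier (non-empty string).
#' @param genes A data frame with columns `gene_id`, `product`, `replicon`
#'   and `seq`. `gene_id` must be unique; `replicon` is one of
#'   `"chromosome"`, `"plasmid"` or `"unknown"`.
#' @param taxon_id Leaf of the guide taxonomy this genome hangs from
#'   (defaults to `genome_id`).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genome_id, genes, taxon_id = genome_id) {
  stopifnot(is.character(genome_id), nzchar(genome_id))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "product", "replicon", "seq")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols))
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  genes <- genes[, need]
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genome '", genome_id, "': ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (nrow(genes) && any(!nzchar(genes$gene_id)))
    stop("empty gene_id in genome '", genome_id, "'")
  genes$seq <- clean_nucleotides(genes$seq)
  if (nrow(genes) && any(nchar(genes$seq) < 1L))
    stop("zero-length sequence in genome '", genome_id, "'")
  bad <- setdiff(unique(genes$replicon), c("chromosome", "plasmid", "unknown"))
  if (length(bad)) stop("invalid replicon value(s): ", paste(bad, collapse = ", "))
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, taxon_id = taxon_id, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> genome '", x$genome_id, "' (taxon '", x$taxon_id, "'): ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$genes)

# uppercase and map non-ACGT IUPAC letters (incl. U) to N
clean_nucleotides <- function(seq) {
  seq <- toupper(seq)
  gsub("[^ACGT]", "N", seq)
}

#' Read one genome's genes from a nucleotide FASTA file
#'
#' Each record header is `gene_id[ product...]` (split at the first
#' whitespace). Replicon status is inferred from the header: a header
#' containing `plasmid_token` (case-insensitive) marks the gene as
#' plasmid-borne; a sidecar table may override this per gene.
#'
#' @param path FASTA file path.
#' @param genome_id Genome identifier to stamp on every record.
#' @param taxon_id Guide-taxonomy leaf id (defaults to `genome_id`).
#' @param plasmid_token Header substring marking plasmid genes.
#' @param replicon_tsv Optional path to a two-column TSV (`gene_id`,
#'   `replicon`) overriding header-derived replicon calls.
#' @return A [gene_set()], with records in file order.
#' @export
read_gene_fasta <- function(path, genome_id, taxon_id = genome_id,
                            plasmid_token = "plasmid", replicon_tsv = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_fasta_lines(path)
  recs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  headers <- names(recs)
  if (length(recs) == 0L)
    return(gene_set(genome_id,
                    data.frame(gene_id = character(), product = character(),
                               replicon = character(), seq = character(),
                               stringsAsFactors = FALSE),
                    taxon_id))
  gene_id <- sub("\\s.*$", "", headers)
  product <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  replicon <- ifelse(grepl(plasmid_token, headers, ignore.case = TRUE),
                     "plasmid", "chromosome")
  if (!is.null(replicon_tsv)) {
    side <- utils::read.delim(replicon_tsv, header = TRUE,
                              stringsAsFactors = FALSE)
    idx <- match(gene_id, side$gene_id)
    replicon[!is.na(idx)] <- side$replicon[idx[!is.na(idx)]]
  }
  gene_set(genome_id,
           data.frame(gene_id = gene_id, product = product,
                      replicon = replicon, seq = as.character(recs),
                      stringsAsFactors = FALSE),
           taxon_id)
}

# cheap structural scan so parse errors can name the offending line
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) return(invisible(TRUE))
  if (!startsWith(lines[nonempty[1]], ">"))
    stop("malformed FASTA in '", path, "': line ", nonempty[1],
         " is not a header", call. = FALSE)
  in_seq <- FALSE
  for (i in nonempty) {
    ln <- lines[i]
    if (startsWith(ln, ">")) { in_seq <- TRUE; next }
    if (!grepl("^[A-Za-z.*-]+$", trimws(ln)))
      stop("malformed FASTA in '", path, "': line ", i,
           " contains non-sequence characters", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a gene set to FASTA
#'
#' Headers are `gene_id product`, with a ` [plasmid]` suffix appended for
#' plasmid-borne genes so that replicon status round-trips through
#' [read_gene_fasta()].
#'
#' @param genome A [gene_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "gene_set"))
  g <- genome$genes
  hdr <- trimws(paste(g$gene_id, g$product))
  hdr <- ifelse(g$replicon == "plasmid" & !grepl("plasmid", hdr, ignore.case = TRUE),
                paste(hdr, "[plasmid]"), hdr)
  seqs <- Biostrings::DNAStringSet(g$seq)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Concatenate multiple FASTA files into one genome
#'
#' Genomes deposited as several files (one per chromosome/replicon) are
#' merged in file order. Colliding gene ids are suffixed with the file
#' index and a warning is issued.
#'
#' @inheritParams read_gene_fasta
#' @param paths Character vector of FASTA paths (at least one).
#' @return A [gene_set()] with the union of all records.
#' @export
concatenate_genome_files <- function(paths, genome_id, taxon_id = genome_id,
                                     plasmid_token = "plasmid",
                                     replicon_tsv = NULL) {
  if (length(paths) < 1L) stop("concatenate_genome_files: no input files")
  parts <- lapply(paths, read_gene_fasta, genome_id = genome_id,
                  taxon_id = taxon_id, plasmid_token = plasmid_token,
                  replicon_tsv = replicon_tsv)
  genes <- do.call(rbind, lapply(parts, function(p) p$genes))
  dup <- duplicated(genes$gene_id)
  if (any(dup)) {
    file_of <- rep(seq_along(parts), vapply(parts, length, 1L))
    genes$gene_id[dup] <- paste0(genes$gene_id[dup], ".", file_of[dup])
    warning(sum(dup), " colliding gene id(s) renamed with file suffix in genome '",
            genome_id, "'")
  }
  gene_set(genome_id, genes, taxon_id)
}

#' Input filter configuration
#'
#' Houses the three input-preparation rules: plasmid-only gene removal,
#' annotation-pattern exclusion (16S rRNA and tRNA genes, which are either
#' already-established cores or too short to carry phylogenetic signal), and
#' the minimum analyzable gene count below which a genome is excluded.
#'
#' @param min_genes Minimum surviving gene count (default 400); genomes
#'   below it are rejected from all downstream computation.
#' @param exclude_product_patterns Case-insensitive substrings; any gene
#'   whose product annotation matches one is dropped.
#' @param drop_plasmid_only If `TRUE` (default), plasmid-borne genes are
#'   removed before the annotation patterns are applied.
#' @return An object of class `input_filter_config`.
#' @export
input_filter_config <- function(min_genes = 400L,
                                exclude_product_patterns =
                                  c("16S ribosomal RNA", "16S rRNA", "tRNA"),
                                drop_plasmid_only = TRUE) {
  min_genes <- as.integer(min_genes)
  stopifnot(min_genes >= 0L, is.character(exclude_product_patterns),
            all(nzchar(exclude_product_patterns)), is.logical(drop_plasmid_only))
  structure(list(min_genes = min_genes,
                 exclude_product_patterns = exclude_product_patterns,
                 drop_plasmid_only = drop_plasmid_only),
            class = "input_filter_config")
}

#' Apply input filters to one genome
#'
#' Filter order: plasmid-borne genes first, then product-pattern matches;
#' the minimum-gene-count rule is applied to the surviving (analyzable)
#' gene set. A genome falling below `cfg$min_genes` is rejected and takes
#' no part in any downstream computation.
#'
#' @param genome A [gene_set()].
#' @param cfg An [input_filter_config()].
#' @return The filtered [gene_set()] (with a `filter_counts` attribute), or
#'   an object of class `rejected_genome` when the genome is excluded.
#' @export
apply_input_filters <- function(genome, cfg = input_filter_config()) {
  stopifnot(inherits(genome, "gene_set"), inherits(cfg, "input_filter_config"))
  g <- genome$genes
  n_input <- nrow(g)
  n_plasmid <- 0L
  if (isTRUE(cfg$drop_plasmid_only)) {
    keep <- g$replicon != "plasmid"
    n_plasmid <- sum(!keep)
    g <- g[keep, , drop = FALSE]
  }
  pat <- paste(vapply(cfg$exclude_product_patterns,
                      function(p) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), ""),
               collapse = "|")
  hit <- grepl(pat, g$product, ignore.case = TRUE)
  n_pattern <- sum(hit)
  g <- g[!hit, , drop = FALSE]
  counts <- c(n_input = n_input, n_plasmid_removed = n_plasmid,
              n_pattern_removed = n_pattern, n_retained = nrow(g))
  if (nrow(g) < cfg$min_genes) {
    return(structure(list(genome_id = genome$genome_id,
                          taxon_id = genome$taxon_id,
                          counts = counts),
                     class = "rejected_genome"))
  }
  out <- gene_set(genome$genome_id, g, genome$taxon_id)
  attr(out, "filter_counts") <- counts
  out
}

#' @export
print.rejected_genome <- function(x, ...) {
  cat("<rejected_genome> '", x$genome_id, "': ", x$counts[["n_retained"]],
      " genes retained (below threshold)\n", sep = "")
  invisible(x)
}

#' Test whether a filtered genome was rejected
#' @param x Result of [apply_input_filters()].
#' @return `TRUE` for a rejected genome.
#' @export
is_rejected <- function(x) inherits(x, "rejected_genome")

#' Filter a collection of genomes and report
#'
#' @param genomes List of [gene_set()] objects.
#' @param cfg An [input_filter_config()].
#' @return A list with `kept` (named list of surviving gene sets) and
#'   `report` (one row per input genome with filter counts and status).
#' @export
filter_genomes <- function(genomes, cfg = input_filter_config()) {
  res <- lapply(genomes, apply_input_filters, cfg = cfg)
  status <- ifelse(vapply(res, is_rejected, TRUE), "rejected", "kept")
  counts <- do.call(rbind, lapply(res, function(r)
    if (is_rejected(r)) r$counts else attr(r, "filter_counts")))
  report <- data.frame(
    genome_id = vapply(res, function(r) r$genome_id, ""),
    as.data.frame(counts), status = status,
    stringsAsFactors = FALSE, row.names = NULL)
  kept <- res[status == "kept"]
  names(kept) <- report$genome_id[status == "kept"]
  list(kept = kept, report = report)
}

#' Write the per-genome filter report
#' @param report The `report` element of [filter_genomes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
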