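#' Homology search parameters
#'
#' Thresholds for the nucleotide ortholog search: a minimum exact seed word
#' size, an e-value ceiling, and a minimum alignment length (which is what
#' keeps short spurious matches, e.g. between tRNA-sized fragments, out of
#' the hit set). Defaults are word size 10, e-value 0.001, minimum
#' alignment length 75, searching both strands.
#'
#' @param word_size Exact-match seed length (>= 4).
#' @param evalue_max E-value ceiling (> 0).
#' @param min_aln_len Minimum alignment length in nt (>= `word_size`).
#' @param both_strands Also search the reverse complement.
#' @return An object of class `search_params`.
#' @export
search_params <- function(word_size = 10L, evalue_max = 1e-3,
                          min_aln_len = 75L, both_strands = TRUE) {
  word_size <- as.integer(word_size)
  min_aln_len <- as.integer(min_aln_len)
  stopifnot(word_size >= 4L, evalue_max > 0, min_aln_len >= word_size,
            is.logical(both_strands))
  structure(list(word_size = word_size, evalue_max = evalue_max,
                 min_aln_len = min_aln_len, both_strands = both_strands),
            class = "search_params")
}

# scoring scheme shared by search, oracle cross-checks and representative
# selection: blastn-like match/mismatch with affine gaps
CG_MATCH <- 2
CG_MISMATCH <- -3
CG_GAP_OPEN <- 5
CG_GAP_EXTEND <- 2

cg_submat <- function() {
  if (is.null(.cg_cache$submat))
    .cg_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = CG_MATCH, mismatch = CG_MISMATCH, baseOnly = FALSE)
  .cg_cache$submat
}

.cg_cache <- new.env(parent = emptyenv())

# Karlin-Altschul lambda for the match/mismatch scheme under uniform base
# composition: solves sum p_i p_j exp(lambda * s_ij) = 1. K is a fixed
# blastn-like constant; raw scores of qualifying alignments are large enough
# that its precision does not move any threshold decision.
ka_lambda <- function() {
  if (is.null(.cg_cache$lambda)) {
    f <- function(l) 0.25 * exp(CG_MATCH * l) + 0.75 * exp(CG_MISMATCH * l) - 1
    .cg_cache$lambda <- stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  }
  .cg_cache$lambda
}
KA_K <- 0.46

#' Convert a raw alignment score to bit score and e-value
#'
#' E = m n K exp(-lambda S), reported alongside the bit score
#' (lambda S - ln K) / ln 2, with search-space size m n taken as query
#' length times total database length.
#'
#' @param raw_score Raw Smith-Waterman score(s).
#' @param query_len Query length(s) in nt.
#' @param db_len Total database length in nt.
#' @return A list with `bits` and `evalue`.
#' @export
score_to_evalue <- function(raw_score, query_len, db_len) {
  bits <- (ka_lambda() * raw_score - log(KA_K)) / log(2)
  list(bits = bits, evalue = as.numeric(query_len) * db_len * 2^(-bits))
}

seq_words <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(character(0))
  words <- substring(seq, 1:(L - w + 1L), w:L)
  unique(words[!grepl("N", words, fixed = TRUE)])
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Build a homology search database
#'
#' Indexes every exact `word_size`-mer of the given genes (both strands when
#' `both_strands`); words containing N are never indexed, so N cannot seed a
#' match.
#'
#' @param genes A [gene_set()], a list of them, or a data frame with columns
#'   `gene_id`, `genome_id`, `seq`.
#' @param params A [search_params()].
#' @return An object of class `search_db`.
#' @export
build_search_db <- function(genes, params = search_params()) {
  tab <- as_gene_table(genes)
  if (!nrow(tab)) stop("cannot build a search database from zero genes")
  w <- params$word_size
  idx <- data.table::rbindlist(lapply(seq_len(nrow(tab)), function(i) {
    fw <- seq_words(tab$seq[i], w)
    parts <- list(data.table::data.table(word = fw, sub = i, strand = "+"))
    if (params$both_strands) {
      rv <- seq_words(revcomp(tab$seq[i]), w)
      parts <- c(parts, list(data.table::data.table(word = rv, sub = i,
                                                    strand = "-")))
    }
    data.table::rbindlist(parts)
  }))
  data.table::setkey(idx, word)
  structure(list(genes = tab, index = idx, params = params,
                 total_len = sum(nchar(tab$seq))),
            class = "search_db")
}

#' @export
print.search_db <- function(x, ...) {
  cat("<search_db> ", nrow(x$genes), " genes, ", x$total_len, " nt, ",
      nrow(x$index), " indexed words\n", sep = "")
  invisible(x)
}

# normalize the various gene carriers to a flat table
as_gene_table <- function(genes) {
  if (inherits(genes, "gene_set"))
    return(data.frame(gene_id = genes$genes$gene_id,
                      genome_id = genes$genome_id,
                      seq = genes$genes$seq, stringsAsFactors = FALSE))
  if (is.list(genes) && all(vapply(genes, inherits, TRUE, "gene_set")))
    return(do.call(rbind, lapply(genes, as_gene_table)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "seq") %in% names(genes)))
  if (is.null(genes$genome_id)) genes$genome_id <- NA_character_
  genes[, c("gene_id", "genome_id", "seq")]
}

#' Search query genes against a database
#'
#' Candidate query-subject pairs are those sharing at least one exact seed
#' word (on either strand when enabled); candidates are then locally aligned
#' (match +2, mismatch -3, gap open 5, gap extend 2) and the best alignment
#' per pair is reported when it passes both the minimum alignment length and
#' the e-value ceiling. One hit per query-subject pair.
#'
#' @param queries Gene carrier as in [build_search_db()].
#' @param db A [search_db()].
#' @param params A [search_params()]; defaults to the database's.
#' @param include_self Report a query aligned to the identically-named
#'   subject (needed only for self-comparisons).
#' @return A data frame of hits: `query_id`, `subject_id`, `query_genome`,
#'   `subject_genome`, `aln_len`, `identity` (fraction), `score` (bits),
#'   `evalue`, `strand`; sorted by query then ascending e-value.
#' @export
search_homologs <- function(queries, db, params = NULL, include_self = FALSE) {
  stopifnot(inherits(db, "search_db"))
  if (is.null(params)) params <- db$params
  qtab <- as_gene_table(queries)
  empty <- hit_frame()
  if (!nrow(qtab)) return(empty)
  w <- params$word_size
  qwords <- data.table::rbindlist(lapply(seq_len(nrow(qtab)), function(i)
    data.table::data.table(word = seq_words(qtab$seq[i], w), qry = i)))
  if (!nrow(qwords)) return(empty)
  cand <- db$index[qwords, on = "word", nomatch = NULL,
                   allow.cartesian = TRUE]
  if (!nrow(cand)) return(empty)
  cand <- unique(cand[, c("qry", "sub", "strand")])
  if (!include_self)
    cand <- cand[qtab$gene_id[cand$qry] != db$genes$gene_id[cand$sub], ]
  if (!nrow(cand)) return(empty)
  hits <- align_candidates(cand, qtab, db$genes, db$total_len, params)
  hits[order(hits$query_id, hits$evalue, hits$subject_id), , drop = FALSE]
}

hit_frame <- function() {
  data.frame(query_id = character(), subject_id = character(),
             query_genome = character(), subject_genome = character(),
             aln_len = integer(), identity = numeric(), score = numeric(),
             evalue = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

# align all candidate (query, subject, strand) triples in one elementwise
# pairwiseAlignment call; S4 per-call overhead dominates otherwise
align_candidates <- function(cand, qtab, stab, db_len, params) {
  submat <- cg_submat()
  cand <- as.data.frame(cand)
  sseq <- stab$seq[cand$sub]
  rc <- cand$strand == "-"
  if (any(rc)) sseq[rc] <- revcomp(sseq[rc])
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(qtab$seq[cand$qry]),
    Biostrings::DNAStringSet(sseq), type = "local",
    substitutionMatrix = submat,
    gapOpening = CG_GAP_OPEN, gapExtension = CG_GAP_EXTEND)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  hits <- data.frame(query_id = qtab$gene_id[cand$qry],
                     subject_id = stab$gene_id[cand$sub],
                     query_genome = qtab$genome_id[cand$qry],
                     subject_genome = stab$genome_id[cand$sub],
                     aln_len = as.integer(alen),
                     identity = ifelse(alen > 0,
                                       Biostrings::nmatch(aln) / alen, 0),
                     raw_score = Biostrings::score(aln),
                     qlen = nchar(qtab$seq[cand$qry]),
                     strand = cand$strand, stringsAsFactors = FALSE)
  ev <- score_to_evalue(hits$raw_score, hits$qlen, db_len)
  hits$score <- ev$bits
  hits$evalue <- ev$evalue
  # best strand per pair, then thresholds
  hits <- hits[order(hits$query_id, hits$subject_id, -hits$raw_score), ]
  hits <- hits[!duplicated(hits[, c("query_id", "subject_id")]), ]
  keep <- hits$raw_score > 0 & hits$aln_len >= params$min_aln_len &
    hits$evalue <= params$evalue_max
  hits <- hits[keep, c("query_id", "subject_id", "query_genome",
                       "subject_genome", "aln_len", "identity", "score",
                       "evalue", "strand"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits as a blastn-style tabular TSV
#'
#' Columns mirror `-outfmt 6`: qseqid, sseqid, pident, length, bitscore,
#' evalue.
#'
#' @param hits A hit table from [search_homologs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                    pident = round(100 * hits$identity, 2),
                    length = hits$aln_len,
                    bitscore = round(hits$score, 1),
                    evalue = signif(hits$evalue, 3))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is the external blastn backend available?
#' @return `TRUE` when `blastn` and `makeblastdb` are on the PATH.
#' @export
blastn_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

#' Search with the external blastn backend
#'
#' Same contract as [search_homologs()], delegated to an installed NCBI
#' blastn; hits failing the minimum alignment length are filtered after the
#' fact. One best hit per query-subject pair is kept.
#'
#' @inheritParams search_homologs
#' @param subjects Gene carrier for the database side.
#' @return Hit data frame as in [search_homologs()].
#' @export
search_homologs_blastn <- function(queries, subjects,
                                   params = search_params(),
                                   include_self = FALSE) {
  if (!blastn_available())
    stop(structure(class = c("backend_unavailable", "error", "condition"),
                   list(message = "blastn/makeblastdb not found on PATH",
                        call = sys.call())))
  qtab <- as_gene_table(queries)
  stab <- as_gene_table(subjects)
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "q.fasta"); sf <- file.path(td, "s.fasta")
  write_flat_fasta(qtab, qf); write_flat_fasta(stab, sf)
  mk <- system2("makeblastdb", c("-in", sf, "-dbtype", "nucl"),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(mk, "status")) && attr(mk, "status") != 0)
    stop("makeblastdb failed: ", paste(mk, collapse = "\n"))
  outf <- file.path(td, "hits.tsv")
  args <- c("-query", qf, "-db", sf, "-word_size", params$word_size,
            "-evalue", format(params$evalue_max, scientific = FALSE),
            "-strand", if (params$both_strands) "both" else "plus",
            "-outfmt", "'6 qseqid sseqid pident length bitscore evalue'",
            "-out", outf)
  err <- system2("blastn", args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(err, "status")) && attr(err, "status") != 0)
    stop("blastn failed: ", paste(err, collapse = "\n"))
  if (!file.exists(outf) || file.info(outf)$size == 0) return(hit_frame())
  raw <- utils::read.delim(outf, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("query_id", "subject_id", "pident",
                                         "aln_len", "score", "evalue"))
  raw <- raw[order(raw$query_id, raw$subject_id, -raw$score), ]
  raw <- raw[!duplicated(raw[, c("query_id", "subject_id")]), ]
  if (!include_self) raw <- raw[raw$query_id != raw$subject_id, ]
  raw <- raw[raw$aln_len >= params$min_aln_len &
               raw$evalue <= params$evalue_max, ]
  if (!nrow(raw)) return(hit_frame())
  gmap_q <- stats::setNames(qtab$genome_id, qtab$gene_id)
  gmap_s <- stats::setNames(stab$genome_id, stab$gene_id)
  out <- data.frame(query_id = raw$query_id, subject_id = raw$subject_id,
                    query_genome = unname(gmap_q[raw$query_id]),
                    subject_genome = unname(gmap_s[raw$subject_id]),
                    aln_len = as.integer(raw$aln_len),
                    identity = raw$pident / 100,
                    score = raw$score, evalue = raw$evalue,
                    strand = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(out$query_id, out$evalue, out$subject_id), ]
  rownames(out) <- NULL
  out
}

write_flat_fasta <- function(tab, path) {
  seqs <- Biostrings::DNAStringSet(tab$seq)
  names(seqs) <- tab$gene_id
  Biostrings::writeXStringSet(seqs, filepath = path)
}
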