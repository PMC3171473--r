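#' Core gene families of a single genome
#'
#' At a terminal unit (one genome), genes are grouped into families by
#' within-genome homology: connected components of the self-search hit
#' graph. Genes with no within-genome homolog form singleton families, so
#' every retained gene belongs to exactly one family. Multi-member families
#' are the genome's paralog groups, which later travel together with their
#' family ("removed together with paralogs").
#'
#' @param genome A filtered [gene_set()].
#' @param params A [search_params()].
#' @return A `clade_core_set`: list with `clade_id` (the genome id),
#'   `families` (named list; each family has `members` and `per_genome`),
#'   and `n_genomes = 1`.
#' @export
leaf_cores <- function(genome, params = search_params()) {
  stopifnot(inherits(genome, "gene_set"))
  ids <- genome$genes$gene_id
  comp <- if (length(ids) > 1L) {
    db <- build_search_db(genome, params)
    hits <- search_homologs(genome, db, params)
    graph_components(ids, hits$query_id, hits$subject_id)
  } else stats::setNames(rep(1L, length(ids)), ids)
  fams <- split(ids, comp[ids])
  fams <- fams[order(vapply(fams, min, ""))]
  families <- lapply(fams, function(m)
    list(members = sort(m),
         per_genome = stats::setNames(list(sort(m)), genome$genome_id)))
  names(families) <- paste0(genome$genome_id, "#", seq_along(families))
  structure(list(clade_id = genome$genome_id, families = families,
                 n_genomes = 1L),
            class = "clade_core_set")
}

#' @export
print.clade_core_set <- function(x, ...) {
  cat("<clade_core_set> clade '", x$clade_id, "': ", length(x$families),
      " core families over ", x$n_genomes, " genome(s)\n", sep = "")
  invisible(x)
}

graph_components <- function(vertices, from, to) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(vertices)
  if (length(from))
    g <- igraph::add_edges(g, rbind(match(from, vertices), match(to, vertices)))
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), vertices)
}

#' Core families of a clade from its children's core sets
#'
#' The clade's database holds the member genes of every child core family;
#' each child's member genes are searched against it. Child families are the
#' nodes of a merger graph, joined by an edge whenever a qualifying hit
#' links their members; connected components containing at least one family
#' from every direct child become the clade's core families (single-linkage
#' is the weakest relation under which every taxon contributes at least
#' one homolog). Components missing a child are not core here: their families
#' stay recorded with the clades where they last qualified. If any child
#' contributes no families the clade is coreless without running a search.
#'
#' @param clade_id Id of the clade being formed.
#' @param child_sets List of `clade_core_set` objects, one per direct child.
#' @param gene_table Data frame (`gene_id`, `genome_id`, `seq`) covering all
#'   member genes.
#' @param params A [search_params()].
#' @return A `clade_core_set` for the clade, with attribute `absorbed`
#'   (named list mapping each new family to the child family keys it
#'   merged).
#' @export
clade_cores <- function(clade_id, child_sets, gene_table,
                        params = search_params()) {
  stopifnot(length(child_sets) >= 1L)
  child_sets <- unname(child_sets)   # keep family keys intact under c()
  n_genomes <- sum(vapply(child_sets, function(s) s$n_genomes, 1L))
  if (any(vapply(child_sets, function(s) length(s$families) == 0L, TRUE))) {
    out <- structure(list(clade_id = clade_id, families = list(),
                          n_genomes = n_genomes),
                     class = "clade_core_set")
    attr(out, "absorbed") <- list()
    attr(out, "stopped") <- TRUE
    return(out)
  }
  if (length(child_sets) == 1L) {
    # singleton chain: the child's families are trivially ubiquitous here
    out <- structure(list(clade_id = clade_id,
                          families = child_sets[[1]]$families,
                          n_genomes = n_genomes),
                     class = "clade_core_set")
    attr(out, "absorbed") <- as.list(stats::setNames(
      lapply(names(child_sets[[1]]$families), identity),
      names(child_sets[[1]]$families)))
    attr(out, "pass_through") <- TRUE
    return(out)
  }
  fam_keys <- unlist(lapply(child_sets, function(s) names(s$families)))
  fam_child <- rep(seq_along(child_sets),
                   vapply(child_sets, function(s) length(s$families), 1L))
  all_fams <- do.call(c, lapply(child_sets, function(s) s$families))
  gene_fam <- stats::setNames(
    rep(fam_keys, vapply(all_fams, function(f) length(f$members), 1L)),
    unlist(lapply(all_fams, function(f) f$members)))
  member_ids <- names(gene_fam)
  gtab <- gene_table[match(member_ids, gene_table$gene_id), , drop = FALSE]
  if (anyNA(gtab$gene_id))
    stop("gene_table is missing member sequences for clade ", clade_id)
  db <- build_search_db(gtab, params)
  hits <- search_homologs(gtab, db, params)
  ef <- gene_fam[hits$query_id]
  et <- gene_fam[hits$subject_id]
  keep <- ef != et
  comp <- graph_components(fam_keys, ef[keep], et[keep])
  families <- list()
  absorbed <- list()
  for (cid in unique(comp[fam_keys])) {
    ck <- fam_keys[comp[fam_keys] == cid]
    if (!all(seq_along(child_sets) %in% fam_child[match(ck, fam_keys)]))
      next
    members <- sort(unique(unlist(lapply(all_fams[ck],
                                         function(f) f$members))))
    pg <- list()
    for (f in all_fams[ck])
      for (g in names(f$per_genome))
        pg[[g]] <- sort(unique(c(pg[[g]], f$per_genome[[g]])))
    key <- paste0(clade_id, "#", length(families) + 1L)
    families[[key]] <- list(members = members, per_genome = pg[order(names(pg))])
    absorbed[[key]] <- ck
  }
  ord <- order(vapply(families, function(f) min(f$members), ""))
  families <- families[ord]
  absorbed <- absorbed[names(families)]
  out <- structure(list(clade_id = clade_id, families = families,
                        n_genomes = n_genomes),
                   class = "clade_core_set")
  attr(out, "absorbed") <- absorbed
  out
}

#' Run the recursive core-gene discovery over a guide taxonomy
#'
#' Clades are processed bottom-up in post-order: terminal units (genomes)
#' first, then each internal clade as soon as all of its direct children
#' have core sets. A family absorbed into a parent core family is
#' re-assigned upward, so the final catalog records every family - and
#' hence every gene - at the single highest clade where it is ubiquitous;
#' the per-clade core counts before this re-assignment are kept in the
#' clade summary. The recursion stops above any coreless clade.
#'
#' @param tax A pruned [guide_taxonomy()] whose genomes all appear in
#'   `genomes`.
#' @param genomes Named list of filtered [gene_set()] objects.
#' @param params A [search_params()].
#' @param select_representatives Also pick one representative per genome
#'   per catalog family (see [select_representative()]).
#' @return An object of class `core_result` with elements `clade_summary`
#'   (clade_id, n_genomes, n_core, n_terminal, status), `catalog` (one row
#'   per family member: clade_id, family_id, genome_id, gene_id,
#'   is_representative), `families` (terminal family records), `consumed`
#'   (gene ids assigned to the catalog), `stop_log`, `clade_children`, and
#'   the inputs used.
#' @export
run_core_discovery <- function(tax, genomes, params = search_params(),
                               select_representatives = TRUE) {
  stopifnot(inherits(tax, "guide_taxonomy"))
  if (is.null(names(genomes)) || !all(nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, function(g) g$genome_id, "")
  missing_g <- setdiff(tax$genomes$genome_id, names(genomes))
  if (length(missing_g))
    stop("taxonomy genomes without gene sets: ", paste(missing_g, collapse = ", "))
  gene_table <- as_gene_table(genomes[tax$genomes$genome_id])

  registry <- new.env(parent = emptyenv())  # fam key -> record
  sets <- list()                            # clade_id -> clade_core_set
  clade_children <- list()
  rows <- list()
  stop_log <- list()

  note_families <- function(set) {
    for (k in names(set$families)) {
      rec <- set$families[[k]]
      registry[[k]] <- list(members = rec$members, per_genome = rec$per_genome,
                            clade_id = set$clade_id, alive = TRUE)
    }
  }
  process_leaf <- function(gid) {
    set <- leaf_cores(genomes[[gid]], params)
    sets[[gid]] <<- set
    note_families(set)
    rows[[length(rows) + 1L]] <<- data.frame(
      clade_id = gid, n_genomes = 1L, n_core = length(set$families),
      status = "leaf", stringsAsFactors = FALSE)
  }
  process_clade <- function(cid, child_ids) {
    clade_children[[cid]] <<- child_ids
    set <- clade_cores(cid, sets[child_ids], gene_table, params)
    sets[[cid]] <<- set
    status <- if (isTRUE(attr(set, "stopped"))) "stopped"
      else if (isTRUE(attr(set, "pass_through"))) "pass"
      else if (length(set$families)) "ok" else "no_core"
    if (status == "stopped")
      stop_log[[length(stop_log) + 1L]] <<- data.frame(
        clade_id = cid, reason = "coreless child", stringsAsFactors = FALSE)
    if (status == "no_core")
      stop_log[[length(stop_log) + 1L]] <<- data.frame(
        clade_id = cid, reason = "no cross-child core", stringsAsFactors = FALSE)
    if (status == "pass") {
      for (k in names(set$families)) registry[[k]]$clade_id <- cid
    } else if (status == "ok") {
      absorbed <- attr(set, "absorbed")
      for (k in names(set$families)) {
        for (old in absorbed[[k]]) registry[[old]]$alive <- FALSE
        rec <- set$families[[k]]
        registry[[k]] <- list(members = rec$members,
                              per_genome = rec$per_genome,
                              clade_id = cid, alive = TRUE)
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      clade_id = cid, n_genomes = set$n_genomes,
      n_core = length(set$families), status = status,
      stringsAsFactors = FALSE)
  }

  for (tid in postorder_clades(tax)) {
    gg <- tax$genomes$genome_id[tax$genomes$taxon_id == tid]
    ch <- children_of(tax, tid)
    if (!length(ch)) {        # terminal taxon node
      if (length(gg) == 1L && gg == tid) {
        process_leaf(gg)
      } else {
        for (g in gg) process_leaf(g)
        process_clade(tid, gg)
      }
    } else {
      if (length(gg))
        stop("internal clade '", tid, "' has directly attached genomes")
      process_clade(tid, ch)
    }
  }

  keys <- ls(registry)
  alive <- keys[vapply(keys, function(k) isTRUE(registry[[k]]$alive), TRUE)]
  fams <- lapply(alive, function(k) registry[[k]])
  clade_of <- vapply(fams, function(f) f$clade_id, "")
  min_member <- vapply(fams, function(f) min(f$members), "")
  ord <- order(clade_of, min_member)
  fams <- fams[ord]; clade_of <- clade_of[ord]
  fam_ids <- character(length(fams))
  for (cl in unique(clade_of)) {
    ix <- which(clade_of == cl)
    fam_ids[ix] <- sprintf("%s:%03d", cl, seq_along(ix))
  }
  names(fams) <- fam_ids

  if (select_representatives && length(fams))
    fams <- lapply(fams, select_representative, gene_table = gene_table,
                   params = params)

  catalog <- data.table::rbindlist(lapply(seq_along(fams), function(i) {
    f <- fams[[i]]
    data.table::data.table(
      clade_id = f$clade_id, family_id = names(fams)[i],
      genome_id = rep(names(f$per_genome),
                      vapply(f$per_genome, length, 1L)),
      gene_id = unlist(f$per_genome, use.names = FALSE))
  }))
  catalog <- as.data.frame(catalog)
  if (!nrow(catalog))
    catalog <- data.frame(clade_id = character(), family_id = character(),
                          genome_id = character(), gene_id = character(),
                          stringsAsFactors = FALSE)
  rep_of <- unlist(lapply(fams, function(f) f$representative))
  catalog$is_representative <- catalog$gene_id %in% rep_of

  summary <- do.call(rbind, rows)
  n_term <- table(clade_of)
  summary$n_terminal <- as.integer(n_term[summary$clade_id])
  summary$n_terminal[is.na(summary$n_terminal)] <- 0L
  summary <- summary[, c("clade_id", "n_genomes", "n_core", "n_terminal",
                         "status")]

  structure(list(clade_summary = summary, catalog = catalog,
                 families = fams, consumed = unique(catalog$gene_id),
                 stop_log = if (length(stop_log)) do.call(rbind, stop_log)
                            else data.frame(clade_id = character(),
                                            reason = character()),
                 clade_children = clade_children,
                 gene_table = gene_table, params = params),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat("<core_result> ", nrow(x$clade_summary), " clades, ",
      length(x$families), " terminal core families, ",
      length(x$consumed), " genes assigned\n", sep = "")
  invisible(x)
}

#' Select the representative paralog for each genome of a family
#'
#' Genomes with a single member contribute that member. For a genome with
#' paralogs, the representative is the paralog with the highest mean local
#' alignment score against the family members drawn from genomes having
#' exactly one member (the most conserved variant); ties break by the best
#' single comparison, then lexicographic gene id. If every genome is
#' multi-member there is no unambiguous reference set and the family medoid
#' (highest mean intra-family score) is taken per genome.
#'
#' @param family A family record with `per_genome` (named list of member
#'   gene ids per genome).
#' @param gene_table Data frame (`gene_id`, `seq`) covering the members.
#' @param params A [search_params()].
#' @return The family with a `representative` field (named character
#'   vector, one gene per genome).
#' @export
select_representative <- function(family, gene_table,
                                  params = search_params()) {
  pg <- family$per_genome
  if (any(vapply(pg, length, 1L) == 0L))
    stop("family has a genome with no members")
  sizes <- vapply(pg, length, 1L)
  seqs <- stats::setNames(gene_table$seq[match(unlist(pg), gene_table$gene_id)],
                          unlist(pg))
  singles <- unlist(pg[sizes == 1L], use.names = FALSE)
  rep_out <- character(length(pg))
  names(rep_out) <- names(pg)
  rep_out[sizes == 1L] <- singles
  multi <- names(pg)[sizes > 1L]
  for (g in multi) {
    cand <- pg[[g]]
    refs <- if (length(singles)) singles else setdiff(unlist(pg), cand)
    # family confined to one genome: medoid against the other paralogs
    per_cand <- lapply(cand, function(x) {
      rr <- if (length(refs)) refs else setdiff(cand, x)
      if (!length(rr)) return(c(mean = 0, best = 0))
      v <- pair_scores(seqs[[x]], seqs[rr], params)
      c(mean = mean(v), best = max(v))
    })
    mean_sc <- vapply(per_cand, `[[`, 0, "mean")
    best <- which(mean_sc == max(mean_sc))
    if (length(best) > 1L) {
      maxone <- vapply(per_cand[best], `[[`, 0, "best")
      best <- best[maxone == max(maxone)]
    }
    rep_out[g] <- sort(cand[best])[1]
  }
  family$representative <- rep_out
  family
}

# best-strand local alignment raw scores of one sequence against several
pair_scores <- function(seq, refs, params) {
  submat <- cg_submat()
  pat <- Biostrings::DNAStringSet(refs)
  fw <- Biostrings::score(Biostrings::pairwiseAlignment(
    pat, Biostrings::DNAString(seq), type = "local",
    substitutionMatrix = submat, gapOpening = CG_GAP_OPEN,
    gapExtension = CG_GAP_EXTEND))
  if (!params$both_strands) return(fw)
  rv <- Biostrings::score(Biostrings::pairwiseAlignment(
    pat, Biostrings::DNAString(revcomp(seq)), type = "local",
    substitutionMatrix = submat, gapOpening = CG_GAP_OPEN,
    gapExtension = CG_GAP_EXTEND))
  pmax(fw, rv)
}

#' Write the core-family catalog as TSV
#' @param result A [run_core_discovery()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_core_tsv <- function(result, path) {
  utils::write.table(result$catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the per-clade core summary as JSON
#' @param result A [run_core_discovery()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_core_summary_json <- function(result, path) {
  s <- result$clade_summary
  obj <- stats::setNames(lapply(seq_len(nrow(s)), function(i)
    list(n_genomes = s$n_genomes[i], n_core = s$n_core[i],
         n_terminal = s$n_terminal[i], status = s$status[i])),
    s$clade_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export family representatives as FASTA
#'
#' One record per genome per family, named `family_id|genome_id|gene_id`.
#'
#' @param result A [run_core_discovery()] result (with representatives).
#' @param path Output FASTA path.
#' @param clade_id Optional clade filter.
#' @return `path`, invisibly.
#' @export
export_representatives_fasta <- function(result, path, clade_id = NULL) {
  cat_df <- result$catalog[result$catalog$is_representative, , drop = FALSE]
  if (!is.null(clade_id))
    cat_df <- cat_df[cat_df$clade_id %in% clade_id, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(
    result$gene_table$seq[match(cat_df$gene_id, result$gene_table$gene_id)])
  names(seqs) <- paste(cat_df$family_id, cat_df$genome_id, cat_df$gene_id,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
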