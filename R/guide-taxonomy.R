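#' Guide taxonomy
#'
#' The guide taxonomy is the user-supplied clade hierarchy (e.g. the NCBI
#' Taxonomy) that orders the recursive core-gene search. It is a rooted tree
#' of named clades with genomes attached at terminal nodes; terminal nodes
#' may sit at unequal depths, and a clade with a single child is preserved.
#'
#' Internally: `nodes` is a data frame (`taxon_id`, `name`, `rank`,
#' `parent_id`, root has `NA` parent) whose row order fixes child order, and
#' `genomes` maps each `genome_id` to its terminal `taxon_id`.
#'
#' @param nodes Node table as described above.
#' @param genomes Data frame with columns `genome_id`, `taxon_id`.
#' @return An object of class `guide_taxonomy`.
#' @export
guide_taxonomy <- function(nodes, genomes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  genomes <- as.data.frame(genomes, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon_id", "name", "rank", "parent_id") %in% names(nodes)),
            all(c("genome_id", "taxon_id") %in% names(genomes)))
  if (anyDuplicated(nodes$taxon_id))
    stop("duplicate taxon_id in taxonomy")
  roots <- nodes$taxon_id[is.na(nodes$parent_id)]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root, found ", length(roots))
  orphan <- setdiff(stats::na.omit(nodes$parent_id), nodes$taxon_id)
  if (length(orphan)) stop("unknown parent id(s): ", paste(orphan, collapse = ", "))
  if (anyDuplicated(genomes$genome_id))
    stop("genome listed under two lineages: ",
         paste(unique(genomes$genome_id[duplicated(genomes$genome_id)]),
               collapse = ", "))
  bad <- setdiff(genomes$taxon_id, nodes$taxon_id)
  if (length(bad)) stop("genomes attached to unknown taxa: ",
                        paste(bad, collapse = ", "))
  internal <- genomes$taxon_id %in% nodes$parent_id
  if (any(internal))
    stop("genomes may only attach to terminal nodes; offending taxa: ",
         paste(unique(genomes$taxon_id[internal]), collapse = ", "))
  rownames(nodes) <- rownames(genomes) <- NULL
  structure(list(root = roots, nodes = nodes, genomes = genomes),
            class = "guide_taxonomy")
}

#' @export
print.guide_taxonomy <- function(x, ...) {
  cat("<guide_taxonomy> ", nrow(x$nodes), " clades, ",
      nrow(x$genomes), " genomes, root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Load a guide taxonomy from a lineage table or a Newick file
#'
#' A lineage table has rows `genome_id<TAB>rank1<TAB>rank2...` from root to
#' leaf (rows may have unequal depth); shared prefixes are merged into
#' internal clades, and node ids are full lineage paths so that repeated
#' names at different ranks stay distinct. If rows disagree on the top rank,
#' a synthetic root (`"root"`) is added above them. A Newick source is read
#' with leaves as genome ids; unlabeled internal nodes get anonymous ids.
#'
#' @param path Path to a tab-delimited lineage file or a Newick file.
#' @param format `"auto"` (sniff: a leading `(` means Newick), `"lineage"`
#'   or `"newick"`.
#' @return A [guide_taxonomy()].
#' @export
load_taxonomy <- function(path, format = c("auto", "lineage", "newick")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty taxonomy source: ", path)
  if (format == "auto")
    format <- if (startsWith(trimws(lines[1]), "(")) "newick" else "lineage"
  if (format == "newick")
    taxonomy_from_newick(ape::read.tree(text = paste(lines, collapse = "")))
  else
    taxonomy_from_lineages(strsplit(lines, "\t", fixed = TRUE))
}

#' Build a guide taxonomy from root-to-leaf lineages
#'
#' @param lineages A list: each element `c(genome_id, rank1, rank2, ...)`.
#' @return A [guide_taxonomy()].
#' @export
taxonomy_from_lineages <- function(lineages) {
  if (!length(lineages)) stop("empty lineage set")
  if (any(vapply(lineages, length, 1L) < 2L))
    stop("each lineage row needs a genome_id and at least one rank")
  tops <- unique(vapply(lineages, function(x) x[2], ""))
  if (length(tops) > 1L)
    lineages <- lapply(lineages, function(x) c(x[1], "root", x[-1]))
  nodes <- data.frame(taxon_id = character(), name = character(),
                      rank = character(), parent_id = character(),
                      stringsAsFactors = FALSE)
  seen <- character()
  genome_id <- vapply(lineages, function(x) x[1], "")
  leaf_taxon <- character(length(lineages))
  for (i in seq_along(lineages)) {
    ranks <- lineages[[i]][-1]
    path_ids <- cumpaste(ranks)
    for (d in seq_along(ranks)) {
      id <- path_ids[d]
      if (!(id %in% seen)) {
        nodes <- rbind(nodes, data.frame(
          taxon_id = id, name = ranks[d], rank = "",
          parent_id = if (d == 1L) NA_character_ else path_ids[d - 1L],
          stringsAsFactors = FALSE))
        seen <- c(seen, id)
      }
    }
    leaf_taxon[i] <- path_ids[length(path_ids)]
  }
  guide_taxonomy(nodes, data.frame(genome_id = genome_id,
                                   taxon_id = leaf_taxon,
                                   stringsAsFactors = FALSE))
}

cumpaste <- function(x) {
  out <- character(length(x))
  acc <- ""
  for (i in seq_along(x)) {
    acc <- if (i == 1L) x[i] else paste(acc, x[i], sep = "/")
    out[i] <- acc
  }
  out
}

#' Build a guide taxonomy from an `ape` tree
#'
#' Leaf labels become genome ids, each attached to its own terminal clade;
#' internal nodes keep their labels when present, otherwise get ids
#' `n1, n2, ...` in `ape` node order.
#'
#' @param tree An object of class `phylo`.
#' @return A [guide_taxonomy()].
#' @export
taxonomy_from_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  node_ids <- character(ntip + nnode)
  node_ids[seq_len(ntip)] <- tree$tip.label
  inner <- tree$node.label
  if (is.null(inner) || !all(nzchar(inner)))
    inner <- paste0("n", seq_len(nnode))
  node_ids[ntip + seq_len(nnode)] <- inner
  parent <- rep(NA_character_, ntip + nnode)
  # edges ordered so that children appear in newick order under each parent
  for (k in seq_len(nrow(tree$edge)))
    parent[tree$edge[k, 2]] <- node_ids[tree$edge[k, 1]]
  root_num <- ntip + 1L
  ord <- c(root_num, tree$edge[, 2])  # root first, then child order by edge list
  nodes <- data.frame(taxon_id = node_ids[ord],
                      name = node_ids[ord], rank = "",
                      parent_id = parent[ord], stringsAsFactors = FALSE)
  genomes <- data.frame(genome_id = tree$tip.label,
                        taxon_id = tree$tip.label, stringsAsFactors = FALSE)
  guide_taxonomy(nodes, genomes)
}

children_of <- function(tax, taxon_id) {
  tax$nodes$taxon_id[!is.na(tax$nodes$parent_id) &
                       tax$nodes$parent_id == taxon_id]
}

#' Post-order clade listing
#'
#' Every clade appears after all of its descendants; children are visited in
#' stored order, so the listing is deterministic.
#'
#' @param tax A [guide_taxonomy()].
#' @return Character vector of taxon ids in post-order.
#' @export
postorder_clades <- function(tax) {
  stopifnot(inherits(tax, "guide_taxonomy"))
  out <- character(0)
  recurse <- function(id) {
    for (ch in children_of(tax, id)) recurse(ch)
    out[[length(out) + 1L]] <<- id
  }
  recurse(tax$root)
  out
}

#' Genomes under a clade
#'
#' @param tax A [guide_taxonomy()].
#' @param taxon_id Clade id.
#' @return Character vector of genome ids in the clade's subtree.
#' @export
genomes_under <- function(tax, taxon_id) {
  stopifnot(inherits(tax, "guide_taxonomy"))
  if (!taxon_id %in% tax$nodes$taxon_id)
    stop("unknown taxon_id: ", taxon_id)
  ids <- taxon_id
  acc <- character(0)
  while (length(ids)) {
    acc <- c(acc, tax$genomes$genome_id[tax$genomes$taxon_id %in% ids])
    ids <- tax$nodes$taxon_id[!is.na(tax$nodes$parent_id) &
                                tax$nodes$parent_id %in% ids]
  }
  acc
}

#' Prune a guide taxonomy to a set of genomes
#'
#' Genomes outside `keep` are dropped; internal clades left with no genome
#' underneath are deleted; clades left with one child are retained (a clade
#' of one genome still receives a core set).
#'
#' @param tax A [guide_taxonomy()].
#' @param keep Character vector of genome ids to retain.
#' @return The pruned [guide_taxonomy()].
#' @export
prune_taxonomy <- function(tax, keep) {
  stopifnot(inherits(tax, "guide_taxonomy"))
  genomes <- tax$genomes[tax$genomes$genome_id %in% keep, , drop = FALSE]
  if (!nrow(genomes)) stop("pruning removed every genome")
  live <- vapply(tax$nodes$taxon_id,
                 function(id) length(genomes_under_static(tax, id, genomes)) > 0,
                 TRUE)
  nodes <- tax$nodes[live, , drop = FALSE]
  guide_taxonomy(nodes, genomes)
}

genomes_under_static <- function(tax, taxon_id, genomes) {
  ids <- taxon_id
  acc <- character(0)
  while (length(ids)) {
    acc <- c(acc, genomes$genome_id[genomes$taxon_id %in% ids])
    ids <- tax$nodes$taxon_id[!is.na(tax$nodes$parent_id) &
                                tax$nodes$parent_id %in% ids]
  }
  acc
}

#' Write a guide taxonomy as Newick
#'
#' Terminal clades expand to their genome ids; a terminal clade holding
#' several genomes becomes a multifurcation over them.
#'
#' @param tax A [guide_taxonomy()].
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
taxonomy_to_newick <- function(tax, path = NULL) {
  stopifnot(inherits(tax, "guide_taxonomy"))
  q <- function(x) gsub("[,():;]", "_", x)
  build <- function(id) {
    ch <- children_of(tax, id)
    gg <- tax$genomes$genome_id[tax$genomes$taxon_id == id]
    parts <- c(vapply(ch, build, ""), q(gg))
    if (!length(parts)) return(q(id))
    if (!length(ch) && length(gg) == 1L && q(gg) == q(id))
      return(q(gg))
    paste0("(", paste(parts, collapse = ","), ")", q(id))
  }
  nwk <- paste0(build(tax$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
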