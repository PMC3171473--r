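#' Pairwise sequence distances
#'
#' A built-in stand-in for external multiple alignment: each pair is checked
#' for a qualifying homology hit under `params` (local alignment, both
#' strands when enabled); pairs with none are maximally distant (1.0).
#' Qualifying pairs are aligned globally with free end gaps and scored as
#' 1 - identity (matches over alignment columns).
#'
#' @param seqs Named character vector of nucleotide sequences (one per
#'   genome, >= 2).
#' @param params A [search_params()].
#' @return A symmetric labeled distance matrix with zero diagonal.
#' @export
pairwise_seq_distances <- function(seqs, params = search_params()) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  seqs <- clean_nucleotides(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  submat <- cg_submat()
  db_len <- sum(nchar(seqs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- seq_pair_distance(seqs[[i]], seqs[[j]], submat,
                                              db_len, params)
    }
  }
  d
}

seq_pair_distance <- function(a, b, submat, db_len, params) {
  cand <- list(b)
  if (params$both_strands) cand <- c(cand, list(revcomp(b)))
  best <- NULL
  best_aln <- NULL
  best_raw <- -Inf
  for (bb in cand) {
    loc <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(bb), type = "local",
      substitutionMatrix = submat, gapOpening = CG_GAP_OPEN,
      gapExtension = CG_GAP_EXTEND)
    if (Biostrings::score(loc) > best_raw) {
      best_raw <- Biostrings::score(loc)
      best <- bb
      best_aln <- loc
    }
  }
  ev <- score_to_evalue(best_raw, nchar(a), db_len)
  hit_len <- nchar(as.character(Biostrings::alignedPattern(best_aln)))
  if (best_raw <= 0 || hit_len < params$min_aln_len ||
      ev$evalue > params$evalue_max)
    return(1.0)
  glob <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(best), type = "overlap",
    substitutionMatrix = submat, gapOpening = CG_GAP_OPEN,
    gapExtension = CG_GAP_EXTEND)
  alen <- nchar(as.character(Biostrings::alignedPattern(glob)))
  1 - Biostrings::nmatch(glob) / alen
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape`), with negative branch lengths
#' clamped to zero and the deficit shifted onto the sister branch so leaf
#' path lengths are preserved where possible. Two labels yield the trivial
#' two-leaf tree.
#'
#' @param dm Symmetric labeled distance matrix.
#' @param clamp_negative Clamp negative edges (default `TRUE`).
#' @return An unrooted `phylo` tree.
#' @export
build_nj_tree <- function(dm, clamp_negative = TRUE) {
  dm <- as.matrix(dm)
  labs <- rownames(dm)
  if (is.null(labs)) stop("distance matrix must be labeled")
  if (nrow(dm) < 2L) stop("need at least 2 labels")
  if (nrow(dm) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", labs[1],
                                        dm[1, 2] / 2, labs[2], dm[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(dm)
  if (clamp_negative && any(tr$edge.length < 0)) {
    neg <- which(tr$edge.length < 0)
    for (e in neg) {
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      parent <- tr$edge[e, 1]
      sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
      if (length(sib)) {
        s <- sib[1]
        tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
      }
    }
  }
  tr
}

#' Midpoint rooting
#'
#' Places the root at the center of the tree diameter (the longest
#' leaf-to-leaf path), making the two endpoints of that path equidistant
#' from the root. When every branch length is zero the midpoint is taken
#' on edge counts, with a warning.
#'
#' @param tree A `phylo` tree with >= 2 leaves.
#' @return The rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need at least 2 leaves")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at topological midpoint")
    t2 <- tree
    t2$edge.length <- rep(1, nrow(t2$edge))
    t2 <- phangorn::midpoint(t2)
    t2$edge.length <- rep(0, nrow(t2$edge))
    return(t2)
  }
  phangorn::midpoint(tree)
}

#' Leaf-to-leaf path distances
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric labeled matrix of path branch lengths.
#' @export
leaf_path_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}

#' Scale a tree to unit total branch length
#'
#' @param tree A `phylo` tree with positive total branch length.
#' @return The tree with every branch divided by the total.
#' @export
normalize_total_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  total <- sum(tree$edge.length)
  if (!isTRUE(total > 0)) stop("total branch length must be positive")
  tree$edge.length <- tree$edge.length / total
  tree
}

#' Phylogenetic alpha-diversity of a clade
#'
#' Total branch length of the subtree below the most recent common ancestor
#' of the members on a rooted reference tree (the MRCA's own stem branch is
#' excluded). A singleton member set has diversity zero.
#'
#' @param ref_tree A rooted `phylo` tree.
#' @param members Character vector of leaf labels (subset of the tree).
#' @return Total subtree branch length.
#' @export
alpha_diversity <- function(ref_tree, members) {
  stopifnot(inherits(ref_tree, "phylo"))
  members <- unique(members)
  unknown <- setdiff(members, ref_tree$tip.label)
  if (length(unknown)) stop("unknown member(s): ", paste(unknown, collapse = ", "))
  if (length(members) < 1L) stop("need at least one member")
  if (length(members) == 1L) return(0)
  mrca <- ape::getMRCA(ref_tree, members)
  ntip <- length(ref_tree$tip.label)
  root <- ntip + 1L
  if (mrca == root) return(sum(ref_tree$edge.length))
  sub <- ape::extract.clade(ref_tree, mrca)
  sum(sub$edge.length)
}

#' Inter- versus intra-group mean distance ratio
#'
#' Leaf path distances on a (typically total-length-normalized) tree are
#' averaged across pairs spanning the two groups (inter) and within each
#' group, with the intra mean pooled over both groups' within pairs; the
#' ratio is inter over pooled intra. Population standard deviations
#' accompany each mean.
#'
#' @param tree A `phylo` tree containing all group members as leaves.
#' @param group_a,group_b Disjoint leaf sets of size >= 2.
#' @return List with `ratio`, `inter`, `intra_a`, `intra_b`, `intra_pooled`
#'   (each mean and sd), and pair counts.
#' @export
inter_intra_ratio <- function(tree, group_a, group_b) {
  group_a <- unique(group_a); group_b <- unique(group_b)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 members for intra-group distances")
  d <- leaf_path_distances(tree)
  miss <- setdiff(c(group_a, group_b), rownames(d))
  if (length(miss)) stop("leaves not in tree: ", paste(miss, collapse = ", "))
  inter <- as.vector(d[group_a, group_b])
  intra_a <- d[group_a, group_a][upper.tri(diag(length(group_a)))]
  intra_b <- d[group_b, group_b][upper.tri(diag(length(group_b)))]
  pooled <- c(intra_a, intra_b)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(ratio = mean(inter) / mean(pooled),
       inter = c(mean = mean(inter), sd = pop_sd(inter)),
       intra_a = c(mean = mean(intra_a), sd = pop_sd(intra_a)),
       intra_b = c(mean = mean(intra_b), sd = pop_sd(intra_b)),
       intra_pooled = c(mean = mean(pooled), sd = pop_sd(pooled)),
       n_inter = length(inter), n_intra = length(pooled))
}

#' Read / write Newick trees
#'
#' Thin wrappers over `ape` so tree files round-trip with quoted labels and
#' branch lengths.
#'
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a labeled distance matrix as TSV
#' @param dm Labeled square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  utils::write.table(cbind(label = rownames(dm), as.data.frame(dm)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
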