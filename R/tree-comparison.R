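#' Percentile co-clustering matrix
#'
#' Binarizes a leaf distance matrix: pairs whose distance falls at or below
#' the given percentile of all unordered-pair distances are "connected"
#' (belong to the same small subtree). The threshold is the linearly
#' interpolated empirical quantile; ties at the threshold are included so
#' the relation is well defined. The diagonal is zero by convention.
#'
#' @param dm Symmetric labeled distance matrix (>= 3 labels).
#' @param percentile Percentile in (0, 100); default 10.
#' @return An object of class `coclustering`: list with `labels`, binary
#'   matrix `m`, `threshold_value`, `percentile`.
#' @export
coclustering <- function(dm, percentile = 10) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 labels")
  if (!(percentile > 0 && percentile <= 100)) stop("percentile must be in (0, 100]")
  vals <- dm[upper.tri(dm)]
  if (length(unique(vals)) == 1L)
    warning("all pairwise distances identical; co-clustering is degenerate")
  thr <- stats::quantile(vals, percentile / 100, names = FALSE, type = 7)
  m <- (dm <= thr) * 1L
  diag(m) <- 0L
  structure(list(labels = rownames(dm), m = m, threshold_value = thr,
                 percentile = percentile),
            class = "coclustering")
}

#' @export
print.coclustering <- function(x, ...) {
  cat("<coclustering> ", length(x$labels), " leaves, threshold ",
      signif(x$threshold_value, 4), " (", x$percentile, "th percentile), ",
      sum(x$m[upper.tri(x$m)]), " connected pairs\n", sep = "")
  invisible(x)
}

tree_cocluster <- function(tree, percentile, label_order) {
  d <- leaf_path_distances(tree)
  d <- d[label_order, label_order, drop = FALSE]
  coclustering(d, percentile)
}

#' Co-clustering distance between two trees
#'
#' Both trees are reduced to binary co-clustering matrices over their shared
#' leaves, and the distance is the Euclidean (Frobenius) norm of the matrix
#' difference, counting both symmetric cells of each unordered pair. The
#' measure depends only on relative leaf placement within small subtrees,
#' so trees built by very different algorithms remain comparable.
#'
#' @param tree_a,tree_b `phylo` trees with identical leaf label sets.
#' @param percentile Co-clustering percentile (default 10).
#' @return Non-negative distance (0 iff the matrices are equal).
#' @export
tree_distance <- function(tree_a, tree_b, percentile = 10) {
  labs <- shared_labels(tree_a, tree_b)
  ma <- tree_cocluster(tree_a, percentile, labs)$m
  mb <- tree_cocluster(tree_b, percentile, labs)$m
  cocluster_matrix_distance(ma, mb)
}

cocluster_matrix_distance <- function(ma, mb) sqrt(sum((ma - mb)^2))

shared_labels <- function(tree_a, tree_b) {
  la <- tree_a$tip.label
  lb <- tree_b$tip.label
  diff <- c(setdiff(la, lb), setdiff(lb, la))
  if (length(diff))
    stop("leaf label sets differ; symmetric difference: ",
         paste(sort(diff), collapse = ", "))
  sort(la)
}

#' Permutation test for tree similarity
#'
#' The null distribution is generated by randomly shuffling the second
#' tree's leaf labels (tree shape and branch lengths fixed), recomputing
#' the co-clustering distance each time. The add-one p-value
#' `(1 + #\{null <= observed\}) / (1 + n_perm)` is reported, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param tree_a,tree_b `phylo` trees with identical leaf label sets.
#' @param n_perm Number of label shuffles (>= 1).
#' @param seed Integer seed; required for reproducibility.
#' @param percentile Co-clustering percentile (default 10).
#' @return An object of class `tree_distance_test`: `distance`, `p_value`,
#'   `n_permutations`, `null_mean`, `null_sd`, `percentile`, `seed`.
#' @export
permutation_pvalue <- function(tree_a, tree_b, n_perm = 1000L, seed,
                               percentile = 10) {
  stopifnot(n_perm >= 1L)
  if (missing(seed)) stop("a seed is required")
  labs <- shared_labels(tree_a, tree_b)
  ma <- tree_cocluster(tree_a, percentile, labs)$m
  # shuffling labels permutes rows/cols of the co-clustering matrix; the
  # distance multiset (hence the threshold) is shuffle-invariant
  mb <- tree_cocluster(tree_b, percentile, labs)$m
  observed <- cocluster_matrix_distance(ma, mb)
  n <- length(labs)
  null_d <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cocluster_matrix_distance(ma, mb[p, p, drop = FALSE])
  }, 0))
  p <- (1 + sum(null_d <= observed)) / (1 + n_perm)
  structure(list(distance = observed, p_value = p,
                 n_permutations = as.integer(n_perm),
                 null_mean = mean(null_d), null_sd = stats::sd(null_d),
                 percentile = percentile, seed = seed),
            class = "tree_distance_test")
}

#' @export
print.tree_distance_test <- function(x, ...) {
  cat("<tree_distance_test> distance ", signif(x$distance, 4),
      ", null ", signif(x$null_mean, 4), " +/- ", signif(x$null_sd, 3),
      ", p = ", signif(x$p_value, 3), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Write a co-clustering matrix as TSV
#' @param cc A [coclustering()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coclustering_tsv <- function(cc, path) {
  write_distance_tsv(cc$m, path)
}
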