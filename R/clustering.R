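#' Drop rarely observed conditions before pattern analysis
#'
#' Condition columns with fewer positive patients than `min_count` within the
#' stratum are removed (conditions observed in almost nobody carry no usable
#' co-occurrence signal and would produce degenerate correlations). Dropped
#' columns are recorded in the `dropped` attribute.
#'
#' @param matrix Patients x conditions 0/1 matrix.
#' @param min_count Minimum number of positive patients to retain a
#'   condition (>= 1).
#' @return The filtered matrix, with attribute `dropped` (named integer
#'   vector of removed conditions and their counts).
#' @export
filter_rare_conditions <- function(matrix, min_count = 3L) {
  stopifnot(min_count >= 1)
  cnt <- colSums(matrix)
  drop <- cnt < min_count
  if (all(drop)) stop("no conditions remain after rare-condition filtering")
  out <- matrix[, !drop, drop = FALSE]
  attr(out, "dropped") <- cnt[drop]
  out
}

#' Pearson-correlation distance between condition indicator columns
#'
#' Columns are standardized (z-scored; a no-op for the Pearson correlation,
#' retained to make the standardization step explicit) and the dissimilarity
#' is `d(i, j) = 1 - r(i, j)` by default, so perfectly co-occurring
#' conditions are at distance 0 and perfectly complementary ones at
#' distance 2. `1 - r` is not a metric; the triangle inequality is not
#' guaranteed.
#'
#' @param matrix Patients x conditions matrix (binary indicators, though any
#'   numeric columns with positive variance work).
#' @param transform `"one_minus_r"` (default) or `"sqrt"` for
#'   `sqrt(2 * (1 - r))`.
#' @return Symmetric distance matrix with zero diagonal, entries in `[0, 2]`.
#' @export
correlation_distance <- function(matrix,
                                 transform = c("one_minus_r", "sqrt")) {
  transform <- match.arg(transform)
  m <- as.matrix(matrix)
  v <- apply(m, 2, stats::var)
  if (any(v == 0 | is.na(v))) {
    stop("zero-variance condition column(s): ",
         paste(colnames(m)[v == 0 | is.na(v)], collapse = ", "),
         " (filter rare conditions first)")
  }
  z <- scale(m)
  r <- stats::cor(z)
  d <- if (transform == "one_minus_r") 1 - r else sqrt(2 * (1 - r))
  d[d < 0] <- 0  # guard against negative round-off at r ~ 1
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering (bottom-up, Lance-Williams)
#'
#' Hand-rolled agglomeration: start from singleton clusters, repeatedly merge
#' the closest pair under the linkage rule and update distances with the
#' Lance-Williams recurrences. Ties on the merge distance are broken by the
#' lexicographically smallest pair of cluster labels, where a cluster is
#' labelled by its smallest original leaf index; this makes the merge
#' sequence fully deterministic.
#'
#' @param distances Symmetric, non-negative distance matrix with zero
#'   diagonal and at least 2 rows; dimnames give the leaf labels.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return Object of class `condition_dendrogram`: list with `merge`
#'   (hclust-style (k-1) x 2 matrix, negative entries = leaves), `height`,
#'   `labels`, `linkage`.
#' @export
agglomerative_cluster <- function(distances,
                                  linkage = c("average", "complete",
                                              "single")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(distances)
  k <- nrow(d)
  if (k < 2) stop("need at least 2 leaves")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  labels <- colnames(d) %||% as.character(seq_len(k))

  # active cluster bookkeeping
  active <- seq_len(k)            # positions still alive in d
  size <- rep(1L, k)
  node <- -seq_len(k)             # hclust node id of each active position
  minleaf <- seq_len(k)           # tie-break label: smallest leaf index
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)

  for (step in seq_len(k - 1L)) {
    # find closest active pair; break ties lexicographically on
    # (min leaf of first, min leaf of second) with labels sorted
    best <- NULL
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (a in seq_along(active)[-length(active)]) {
      ia <- active[a]
      for (b in (a + 1L):length(active)) {
        ib <- active[b]
        dd <- d[ia, ib]
        key <- sort(c(minleaf[ia], minleaf[ib]))
        better <- dd < best_d - 1e-12 ||
          (abs(dd - best_d) <= 1e-12 &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best <- c(ia, ib); best_d <- dd; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best_d
    # Lance-Williams update into position i
    ni <- size[i]; nj <- size[j]
    for (h in active) {
      if (h == i || h == j) next
      dhi <- d[h, i]; dhj <- d[h, j]
      dnew <- switch(linkage,
                     single = min(dhi, dhj),
                     complete = max(dhi, dhj),
                     average = (ni * dhi + nj * dhj) / (ni + nj))
      d[h, i] <- dnew; d[i, h] <- dnew
    }
    size[i] <- ni + nj
    node[i] <- step
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active <- active[active != j]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage), class = "condition_dendrogram")
}

#' @export
print.condition_dendrogram <- function(x, ...) {
  cat(sprintf("<condition_dendrogram> %d leaves, %s linkage\n",
              length(x$labels), x$linkage))
  lab <- function(v) vapply(v, function(vi)
    if (vi < 0) x$labels[-vi] else paste0("#", vi), character(1))
  for (i in seq_along(x$height)) {
    cat(sprintf("  %2d: %s + %s @ %.4f\n", i, lab(x$merge[i, 1]),
                lab(x$merge[i, 2]), x$height[i]))
  }
  invisible(x)
}

#' @export
as.hclust.condition_dendrogram <- function(x, ...) {
  # leaf order by traversal so the plot has no crossing branches
  order_of <- function(node) {
    if (node < 0) return(-node)
    c(order_of(x$merge[node, 1]), order_of(x$merge[node, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = order_of(nrow(x$merge)), labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "correlation"),
            class = "hclust")
}

#' @export
plot.condition_dendrogram <- function(x, main = "Comorbidity dendrogram",
                                      ylab = "1 - r", ...) {
  plot(as.hclust(x), main = main, ylab = ylab, ...)
  invisible(x)
}

#' Export a dendrogram as a Newick tree
#'
#' Merge heights become branch lengths via the standard ultrametric
#' interpretation of the dendrogram.
#'
#' @param tree A `condition_dendrogram`.
#' @param path Output file; if `NULL`, the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(as.hclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Export the merge table of a dendrogram as CSV
#' @param tree A `condition_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_merge_table <- function(tree, path) {
  lab <- function(v) vapply(v, function(vi)
    if (vi < 0) tree$labels[-vi] else paste0("#", vi), character(1))
  utils::write.csv(data.frame(step = seq_along(tree$height),
                              left = lab(tree$merge[, 1]),
                              right = lab(tree$merge[, 2]),
                              height = tree$height,
                              linkage = tree$linkage), path,
                   row.names = FALSE)
  invisible(path)
}

#' Cut a dendrogram into condition groups
#'
#' Cutting at `n_clusters` keeps the last `n_clusters - 1` merges undone;
#' cutting at `height` undoes every merge above that height. Singleton
#' groups are reported but only groups with at least two conditions count as
#' comorbidity clusters.
#'
#' @param tree A `condition_dendrogram`.
#' @param n_clusters Number of groups to cut into (mutually exclusive with
#'   `height`).
#' @param height Cut height.
#' @return Object of class `condition_cut`: list with `groups` (all groups as
#'   character vectors) and `clusters` (the groups of size >= 2).
#' @export
extract_clusters <- function(tree, n_clusters = NULL, height = NULL) {
  k <- length(tree$labels)
  if (is.null(n_clusters) == is.null(height))
    stop("give exactly one of n_clusters or height")
  if (!is.null(n_clusters)) {
    if (n_clusters < 1 || n_clusters > k)
      stop("n_clusters must lie in 1..", k)
    n_merge <- k - n_clusters
  } else {
    n_merge <- sum(tree$height <= height)
  }
  # union-find over leaves, replaying the first n_merge merges; merges are
  # in execution order so step s only references nodes from steps < s
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_root <- integer(nrow(tree$merge))
  root_of <- function(v) if (v < 0) find(-v) else find(node_root[v])
  for (s in seq_len(n_merge)) {
    ra <- root_of(tree$merge[s, 1]); rb <- root_of(tree$merge[s, 2])
    parent[rb] <- ra
    node_root[s] <- ra
  }
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- split(tree$labels, roots)
  names(groups) <- NULL
  groups <- groups[order(vapply(groups, function(g)
    min(match(g, tree$labels)), integer(1)))]
  structure(list(groups = groups,
                 clusters = Filter(function(g) length(g) >= 2, groups),
                 n_merges = n_merge, linkage = tree$linkage),
            class = "condition_cut")
}

#' @export
print.condition_cut <- function(x, ...) {
  cat(sprintf("<condition_cut> %d group(s), %d cluster(s) of size >= 2\n",
              length(x$groups), length(x$clusters)))
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Assign patients to comorbidity clusters
#'
#' Default membership rule `"all"`: a patient belongs to a cluster iff every
#' condition of that cluster is positive for them. Under exclusive
#' assignment (default) a patient matching several clusters goes to the one
#' with the most matched conditions, ties broken by earlier cluster order.
#'
#' @param clusters List of disjoint condition sets (size >= 2 each), or a
#'   `condition_cut` (its `clusters` element is used).
#' @param matrix Patients x conditions 0/1 matrix (rownames = patient ids).
#' @param at_least If given, membership requires only `at_least` of the
#'   cluster's conditions instead of all of them.
#' @param exclusive Assign each patient to at most one cluster? Default
#'   `TRUE`.
#' @return Object of class `condition_cluster_set`: list with `clusters`
#'   (each: `conditions`, `label`, `patient_ids`, `n`) and `membership`
#'   (character vector per patient: cluster label or "none").
#' @export
assign_patients <- function(clusters, matrix, at_least = NULL,
                            exclusive = TRUE) {
  if (inherits(clusters, "condition_cut")) clusters <- clusters$clusters
  if (length(clusters) > 1) {
    all_conds <- unlist(clusters)
    if (anyDuplicated(all_conds))
      stop("cluster condition sets must be disjoint")
  }
  ids <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  labels <- vapply(clusters, paste, character(1), collapse = "+")
  n_match <- matrix(0L, nrow(matrix), length(clusters))
  member <- matrix(FALSE, nrow(matrix), length(clusters))
  for (ci in seq_along(clusters)) {
    conds <- clusters[[ci]]
    miss <- setdiff(conds, colnames(matrix))
    if (length(miss)) stop("unknown condition(s): ",
                           paste(miss, collapse = ", "))
    nm <- rowSums(matrix[, conds, drop = FALSE])
    need <- if (is.null(at_least)) length(conds) else min(at_least,
                                                          length(conds))
    n_match[, ci] <- nm
    member[, ci] <- nm >= need
  }
  membership <- rep("none", nrow(matrix))
  if (length(clusters)) {
    if (exclusive) {
      for (i in which(rowSums(member) > 0)) {
        cand <- which(member[i, ])
        best <- cand[which.max(n_match[i, cand])]  # earlier index wins ties
        membership[i] <- labels[best]
      }
    } else {
      for (i in which(rowSums(member) > 0)) {
        membership[i] <- paste(labels[member[i, ]], collapse = "|")
      }
    }
  }
  names(membership) <- ids
  out_clusters <- lapply(seq_along(clusters), function(ci) {
    pids <- if (exclusive) ids[membership == labels[ci]]
            else ids[member[, ci]]
    list(conditions = clusters[[ci]], label = labels[ci],
         patient_ids = pids, n = length(pids))
  })
  structure(list(clusters = out_clusters, membership = membership,
                 exclusive = exclusive), class = "condition_cluster_set")
}

#' @export
print.condition_cluster_set <- function(x, ...) {
  cat(sprintf("<condition_cluster_set> %d cluster(s), %s assignment\n",
              length(x$clusters),
              if (x$exclusive) "exclusive" else "overlapping"))
  for (cl in x$clusters)
    cat(sprintf("  %-40s n = %d\n", cl$label, cl$n))
  cat(sprintf("  without identified cluster: %d\n",
              sum(x$membership == "none")))
  invisible(x)
}
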