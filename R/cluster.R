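#' Ward hierarchical clustering of modality coordinates
#'
#' Agglomerative clustering with the Ward minimum-variance criterion on
#' Euclidean distances between modality principal coordinates, cut at k
#' clusters. Deterministic.
#'
#' @param coords Numeric matrix (modalities x axes) with rownames.
#' @param k Number of clusters, `2 <= k <=` number of modalities.
#' @return List of class `clbp_assignment`: `method`, `labels` (named
#'   integer vector, cluster ids contiguous from 1), `k`, `params`.
#' @export
hac_ward <- function(coords, k) {
  coords <- as.matrix(coords)
  .check_coords_k(coords, k)
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  .assignment("hac_ward", labels, k, list(), tree = hc)
}

#' k-means clustering of modality coordinates
#'
#' Best of `n_init` seeded random starts by within-cluster sum of squares;
#' deterministic for a fixed seed.
#'
#' @param coords Numeric matrix (modalities x axes) with rownames.
#' @param k Number of clusters.
#' @param seed RNG seed for the starts.
#' @param n_init Number of random starts.
#' @return A `clbp_assignment`.
#' @export
kmeans_cluster <- function(coords, k, seed = 20250904, n_init = 50) {
  coords <- as.matrix(coords)
  .check_coords_k(coords, k)
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = n_init, iter.max = 100)
  .assignment("kmeans", km$cluster, k,
              list(seed = seed, n_init = n_init, wcss = km$tot.withinss))
}

#' Optimal univariate partition (Fisher's method)
#'
#' Exact dynamic programming over contiguous partitions of points on a
#' line, minimizing the total within-class sum of squares; the standard
#' optimal 1-D analogue of k-means. Cluster ids are ordered along the
#' line (1 = lowest coordinates). Deterministic.
#'
#' @param coord_1d Named numeric vector (one coordinate per modality,
#'   F1 by default in the pipeline).
#' @param k Number of classes, `1 <= k <=` number of points.
#' @return A `clbp_assignment` with `params$wcss`.
#' @export
univariate_partition <- function(coord_1d, k) {
  x <- coord_1d
  n <- length(x)
  if (k < 1 || k > n) stop("univariate_partition(): need 1 <= k <= n")
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  ss <- function(i, j) {  # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) {
    D[1, j] <- ss(1, j)
    B[1, j] <- 1L
  }
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        arg <- m
        for (i in m:j) {
          val <- D[m - 1, i - 1] + ss(i, j)
          if (val < best - 1e-12) {
            best <- val
            arg <- i
          }
        }
        D[m, j] <- best
        B[m, j] <- arg
      }
    }
  }
  lab_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- B[m, j]
    lab_sorted[i:j] <- m
    j <- i - 1
  }
  labels <- integer(n)
  labels[ord] <- lab_sorted
  names(labels) <- names(x)
  # ids already contiguous and ordered along the line; keep them
  structure(list(method = "univariate", labels = labels, k = k,
                 params = list(wcss = D[k, n])),
            class = "clbp_assignment")
}

.check_coords_k <- function(coords, k) {
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (k < 2 || k > nrow(coords)) {
    stop("need 2 <= k <= number of modalities (", nrow(coords), ")")
  }
}

.assignment <- function(method, labels, k, params, tree = NULL) {
  # make cluster ids contiguous from 1, in order of first appearance
  ids <- unique(labels)
  labels <- setNames(match(labels, ids), names(labels))
  out <- list(method = method, labels = labels, k = length(ids),
              params = params)
  if (!is.null(tree)) out$tree <- tree
  structure(out, class = "clbp_assignment")
}

#' Consensus final cluster anchored on a modality
#'
#' The final cluster representing the worst cLBP state is the set of
#' modalities that belong, in every one of the parallel clustering
#' methods, to the cluster containing the anchor modality (the highest
#' pain-interference tercile in the pipeline) - i.e. the intersection
#' over methods of the anchor's clusters. Modalities are additionally
#' ordered by Euclidean distance to the anchor when coordinates are
#' supplied.
#'
#' @param assignments List of `clbp_assignment` objects over the same
#'   modality set (typically Ward, k-means and univariate).
#' @param anchor Anchor modality name.
#' @param coords Optional coordinate matrix for the proximity ordering.
#' @return List of class `clbp_consensus`: `anchor`,
#'   `per_method_anchor_cluster`, `final_cluster` (in proximity order when
#'   coords are given), `ordering`.
#' @export
consensus_final_cluster <- function(assignments, anchor, coords = NULL) {
  stopifnot(length(assignments) >= 1)
  mods <- sort(names(assignments[[1]]$labels))
  for (a in assignments) {
    if (!identical(sort(names(a$labels)), mods)) {
      stop("consensus_final_cluster(): assignments cover different modality sets")
    }
  }
  if (!anchor %in% mods) {
    stop("consensus_final_cluster(): anchor '", anchor, "' not among modalities")
  }
  per <- lapply(assignments, function(a) {
    names(a$labels)[a$labels == a$labels[[anchor]]]
  })
  names(per) <- vapply(assignments, `[[`, "", "method")
  final <- Reduce(intersect, per)
  ordering <- NULL
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    d <- sqrt(colSums((t(coords) - coords[anchor, ])^2))
    ordering <- names(sort(d))
    final <- ordering[ordering %in% final]
  }
  structure(list(anchor = anchor, per_method_anchor_cluster = per,
                 final_cluster = final, ordering = ordering),
            class = "clbp_consensus")
}

#' Run the three parallel clusterings and their consensus
#'
#' Ward and k-means run on the retained principal coordinates; the
#' univariate partition runs on F1 alone.
#'
#' @param mca A `clbp_mca`.
#' @param k Number of clusters for each method.
#' @param axes Axes to use (default the first two).
#' @param anchor Anchor modality name.
#' @param seed,n_init Passed to [kmeans_cluster()].
#' @return A `clbp_consensus` with the per-method assignments attached as
#'   attribute `assignments`.
#' @export
cluster_modalities <- function(mca, anchor, k = 3, axes = NULL,
                               seed = 20250904, n_init = 50) {
  coords <- mca$modality_coords
  if (is.null(axes)) axes <- seq_len(min(2, ncol(coords)))
  cc <- coords[, axes, drop = FALSE]
  asg <- list(
    hac_ward(cc, k),
    kmeans_cluster(cc, k, seed = seed, n_init = n_init),
    univariate_partition(cc[, 1], k)
  )
  out <- consensus_final_cluster(asg, anchor, coords = cc)
  attr(out, "assignments") <- asg
  out
}
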