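#' k-medoids clustering of one sort's item positions
#'
#' Partitions the item coordinates into `k` medoid-based clusters by the
#' classic BUILD + SWAP k-medoids algorithm (PAM) on Euclidean distances, via
#' [cluster::pam()].  A medoid is the cluster member whose average distance
#' to the other members is smallest; every item is assigned to its nearest
#' medoid.  Raw pixel coordinates are used without standardisation since
#' both axes share units.  The procedure is deterministic.
#'
#' @param xy n x 2 numeric matrix of item coordinates.
#' @param k number of clusters, `1 <= k <= n`.
#' @param ids optional item ids (default rownames of `xy` or `1..n`).
#' @return an object of class `"cluster_result"`: list with `k`,
#'   `medoid_ids`, `assignment` (named integer vector, item to cluster
#'   index), `avg_silhouette` (mean silhouette width, 0 when `k` equals 1 or
#'   `n`; singleton clusters contribute 0) and `total_cost` (sum of
#'   distances from items to their medoid).
#' @export
fs_pam <- function(xy, k, ids = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (is.null(ids)) ids <- if (!is.null(rownames(xy))) rownames(xy) else as.character(seq_len(n))
  stopifnot(length(ids) == n, ncol(xy) == 2)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("k must be between 1 and the number of items")
  if (k == n) {
    res <- list(k = k, medoid_ids = ids,
                assignment = setNames(seq_len(n), ids),
                avg_silhouette = 0, total_cost = 0)
    return(structure(res, class = "cluster_result"))
  }
  fit <- cluster::pam(xy, k, metric = "euclidean", keep.diss = FALSE,
                      keep.data = FALSE)
  assignment <- setNames(as.integer(fit$clustering), ids)
  medoid_idx <- fit$id.med
  dmed <- sqrt(rowSums((xy - xy[medoid_idx[assignment], , drop = FALSE])^2))
  avg_sil <- if (k == 1) 0 else unname(fit$silinfo$avg.width)
  structure(list(k = k, medoid_ids = ids[medoid_idx], assignment = assignment,
                 avg_silhouette = avg_sil, total_cost = sum(dmed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d, avg silhouette %.3f, cost %.1f>\n",
              x$k, x$avg_silhouette, x$total_cost))
  invisible(x)
}

#' Estimate the number of clusters in a sort
#'
#' Runs [fs_pam()] for every `k` in `k_range` and returns the `k` that
#' maximises the average silhouette width, ties broken toward the smaller
#' `k`.  The default range 2..10 mirrors the conventional k-medoids
#' model-selection default; `k = 1` is excluded because the silhouette is
#' undefined there (and one-cluster sorts do not occur in practice).
#'
#' @param xy n x 2 numeric matrix of item coordinates (n >= 3).
#' @param k_range candidate cluster counts; clipped to `[2, n - 1]`.
#' @param ids optional item ids.
#' @return list with `best_k` and `result` (the winning
#'   `"cluster_result"`), plus `silhouettes` (named vector over `k_range`).
#' @export
estimate_k <- function(xy, k_range = 2:10, ids = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 items to estimate a cluster count")
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range empty after clipping to [2, n - 1]")
  fits <- lapply(k_range, function(k) fs_pam(xy, k, ids))
  sil <- vapply(fits, `[[`, 0, "avg_silhouette")
  names(sil) <- k_range
  best <- which.max(sil)  # first max = smallest k on ties
  list(best_k = k_range[best], result = fits[[best]], silhouettes = sil)
}

#' Cluster counts across a cohort
#'
#' Estimates every participant's cluster count ([estimate_k()]) and
#' summarises per condition: mean cluster count and the proportion of
#' 2-cluster sorts.
#'
#' @param cohort list of [sort_record()]s, each with >= 3 items.
#' @param k_range candidate cluster counts passed to [estimate_k()].
#' @return list with `participants` (data.frame `participant_id`,
#'   `condition`, `n_clusters`, `avg_silhouette`) and `by_condition`
#'   (data.frame `condition`, `mean_clusters`, `prop_two_cluster`).
#' @export
cluster_counts <- function(cohort, k_range = 2:10) {
  rows <- lapply(cohort, function(s) {
    est <- estimate_k(cbind(s$x, s$y), k_range, ids = s$item_ids)
    data.frame(participant_id = s$participant_id, condition = s$condition,
               n_clusters = est$best_k,
               avg_silhouette = est$result$avg_silhouette,
               stringsAsFactors = FALSE)
  })
  participants <- do.call(rbind, rows)
  agg <- lapply(split(participants, participants$condition), function(df) {
    data.frame(condition = df$condition[1],
               mean_clusters = mean(df$n_clusters),
               prop_two_cluster = mean(df$n_clusters == 2),
               stringsAsFactors = FALSE)
  })
  by_condition <- do.call(rbind, agg)
  rownames(by_condition) <- NULL
  list(participants = participants, by_condition = by_condition)
}
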