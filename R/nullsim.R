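#' Random-placement null study
#'
#' Simulates a cohort of sorters who place every item independently and
#' uniformly at random on the canvas, then computes all pairwise alignments
#' within the cohort and aggregates them per sorter (mean Fisher-z to all
#' others).  Under random placement distance vectors are independent, so
#' per-sorter mean alignment concentrates near 0 and categoricality is
#' unrelated to alignment — the null against which the
#' categoricality-alignment relationship in real sorts is judged.
#'
#' Ranks are precomputed once per sorter and dyad correlations obtained as a
#' single matrix cross-product, so cohorts of several thousand run in
#' seconds.  Categoricality uses a fixed nominal half/half A/B labelling of
#' the items (random placement is label-exchangeable) and is bridged per
#' sorter by the minimum rule (mean over the sorter's dyads of the pairwise
#' minimum).
#'
#' @param n_sorters number of simulated sorters (>= 2).
#' @param n_items number of items (split half A / half B for the nominal
#'   labelling).
#' @param canvas_w,canvas_h canvas size in pixels.
#' @param seed integer seed.
#' @return an object of class `"null_study"`: list with `n_sorters`,
#'   `n_items`, `mean_alignment` (per-sorter means, Fisher-z),
#'   `categoricality` (per-sorter scores), `cat_min_bridge` (per-sorter
#'   min-bridged categoricality), `max_mean_alignment`, `max_dyad_alignment`
#'   and `corr_cat_alignment` (Pearson r between the bridged categoricality
#'   and mean alignment).
#' @export
random_placement_study <- function(n_sorters = 3000, n_items = 20,
                                   canvas_w = 1024, canvas_h = 768, seed = 1) {
  stopifnot(n_sorters >= 2, n_items >= 4)
  set.seed(seed)
  n_pairs <- n_items * (n_items - 1) / 2
  labels <- rep(c("A", "B"), each = ceiling(n_items / 2))[seq_len(n_items)]
  within <- as.numeric(dist(as.numeric(factor(labels)))) == 0
  D <- matrix(NA_real_, n_sorters, n_pairs)
  for (i in seq_len(n_sorters)) {
    xy <- cbind(runif(n_items, 0, canvas_w), runif(n_items, 0, canvas_h))
    D[i, ] <- as.numeric(dist(xy))
  }
  m <- zmatrix_from_dmat(D)
  mean_z <- rowMeans(m$z, na.rm = TRUE)
  cat_score <- log(rowMeans(D[, !within, drop = FALSE]) /
                     rowMeans(D[, within, drop = FALSE]))
  cat_min_bridge <- min_bridge_means(cat_score)
  structure(list(
    n_sorters = n_sorters, n_items = n_items,
    mean_alignment = mean_z, categoricality = cat_score,
    cat_min_bridge = cat_min_bridge,
    max_mean_alignment = max(mean_z),
    max_dyad_alignment = max(m$z, na.rm = TRUE),
    corr_cat_alignment = if (sd(cat_min_bridge) > 0 && sd(mean_z) > 0)
      cor(cat_min_bridge, mean_z) else NA_real_),
    class = "null_study")
}

# per-element mean over all other elements of pmin(x_i, x_j), via sorting
# and prefix sums (O(n log n))
min_bridge_means <- function(x) {
  n <- length(x)
  o <- order(x)
  s <- x[o]
  cs <- cumsum(s)
  # for the r-th smallest value: others below contribute their own value,
  # others above contribute s_r
  r <- seq_len(n)
  tot <- (cs - s) + s * (n - r)
  out <- numeric(n)
  out[o] <- tot / (n - 1)
  out
}

#' @export
print.null_study <- function(x, ...) {
  cat(sprintf("<null_study: %d random sorters, %d items>\n", x$n_sorters, x$n_items))
  cat(sprintf("  max per-sorter mean alignment: %.4f (max dyad z %.4f)\n",
              x$max_mean_alignment, x$max_dyad_alignment))
  cat(sprintf("  corr(min-bridged categoricality, mean alignment): %.4f\n",
              x$corr_cat_alignment))
  invisible(x)
}

#' Grid-sort demonstration
#'
#' Constructs two sorts that place the items, in the same assignment, on an
#' evenly spaced lattice filling the canvas.  Their distance vectors are
#' identical, so alignment is perfect (rho = 1, z at the clip value) even
#' though the arrangement has no clustered structure; and under an
#' alternating A/B labelling of the grid cells, categoricality is close to
#' zero.  The demonstration shows that high alignment does not by itself
#' imply categorical (or any) clustering.
#'
#' @param n_items number of items.
#' @param canvas_w,canvas_h canvas size in pixels.
#' @return list with the two [sort_record()]s (`sort1`, `sort2`), the
#'   alternating labelling (`category_of`), `rho`, `z`, and the two
#'   categoricality scores.
#' @export
grid_pair_demo <- function(n_items = 20, canvas_w = 1024, canvas_h = 768) {
  ncol_ <- ceiling(sqrt(n_items * canvas_w / canvas_h))
  nrow_ <- ceiling(n_items / ncol_)
  if (ncol_ * nrow_ < n_items) stop("n_items is not grid-compatible")
  cells <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))[seq_len(n_items), ]
  x <- (cells$col - 0.5) * canvas_w / ncol_
  y <- (cells$row - 0.5) * canvas_h / nrow_
  ids <- sprintf("it%02d", seq_len(n_items))
  category_of <- setNames(rep(c("A", "B"), length.out = n_items), ids)
  s1 <- sort_record("grid_1", "synthetic:grid", ids, x, y, canvas_w, canvas_h)
  s2 <- sort_record("grid_2", "synthetic:grid", ids, x, y, canvas_w, canvas_h)
  al <- alignment(pairwise_distances(s1), pairwise_distances(s2))
  list(sort1 = s1, sort2 = s2, category_of = category_of,
       rho = unname(al["rho"]), z = unname(al["z"]),
       categoricality_1 = categoricality(s1, category_of)$score,
       categoricality_2 = categoricality(s2, category_of)$score)
}
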