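#' Pairwise item distances of one sort
#'
#' Computes the Euclidean pixel distance between every unordered pair of
#' items, in canonical pair order: items are sorted lexicographically by id
#' and pairs enumerated `(1,2), (1,3), ..., (1,n), (2,3), ...`.  Category
#' identity plays no role here; the distance vector is "blind" to it.
#'
#' @param sort a [sort_record()] with at least 2 items.
#' @return an object of class `"distance_vector"`: list with `participant_id`,
#'   `items` (sorted ids), `pair_i`, `pair_j` (item ids of each pair) and `d`
#'   (numeric distances, length `n(n-1)/2`).
#' @export
#' @examples
#' s <- sort_record("p1", "demo", c("a", "b"), x = c(0, 3), y = c(0, 4))
#' pairwise_distances(s)$d  # 5
pairwise_distances <- function(sort) {
  stopifnot(inherits(sort, "sort_record"))
  if (length(sort$item_ids) < 2) stop("need at least 2 items")
  ord <- order(sort$item_ids)
  ids <- sort$item_ids[ord]
  xy <- cbind(sort$x, sort$y)[ord, , drop = FALSE]
  d <- as.numeric(dist(xy))
  n <- length(ids)
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  structure(list(participant_id = sort$participant_id, items = ids,
                 pair_i = ids[pi_], pair_j = ids[pj_], d = d),
            class = "distance_vector")
}

# logical mask over the canonical pairs: TRUE where both items share a category
within_pair_mask <- function(dv, category_of) {
  ci <- category_of[dv$pair_i]
  cj <- category_of[dv$pair_j]
  if (any(is.na(ci)) || any(is.na(cj)))
    stop("category_of is missing some items")
  ci == cj
}

#' Categoricality of a sort
#'
#' The log ratio of the mean between-category pairwise distance to the mean
#' within-category pairwise distance:
#' `score = log(mean_between / mean_within)`.  Positive scores mean
#' same-category items sit closer together than different-category items.
#' Being a ratio of distances, the score is invariant under rigid motion and
#' uniform rescaling of the whole sort, so it does not depend on how much of
#' the canvas a participant used.  A sort with tight clusters that mix the
#' two categories scores low, by design.
#'
#' @param sort a [sort_record()] with at least 2 items per category.
#' @param category_of named character vector mapping item id to `"A"`/`"B"`.
#' @return an object of class `"categoricality"`: list with `participant_id`,
#'   `mean_between`, `mean_within` (pixels) and `score` (dimensionless,
#'   natural log).
#' @export
categoricality <- function(sort, category_of) {
  dv <- pairwise_distances(sort)
  w <- within_pair_mask(dv, category_of)
  cats <- category_of[dv$items]
  if (min(table(cats)) < 2) stop("need at least 2 items per category")
  mean_within <- mean(dv$d[w])
  mean_between <- mean(dv$d[!w])
  if (mean_within <= 0)
    stop("undefined categoricality: all same-category items coincide")
  structure(list(participant_id = dv$participant_id,
                 mean_between = mean_between, mean_within = mean_within,
                 score = log(mean_between / mean_within)),
            class = "categoricality")
}

#' @export
print.categoricality <- function(x, ...) {
  cat(sprintf("<categoricality %s: %.3f (between %.1f / within %.1f px)>\n",
              x$participant_id, x$score, x$mean_between, x$mean_within))
  invisible(x)
}

# Spearman rho with average ranks for ties; errors on zero-variance input
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("distance vectors differ in length")
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined rank correlation: a distance vector has zero variance")
  cor(a, b, method = "spearman")
}

#' Alignment between two sorts
#'
#' The similarity of two participants' arrangements, measured as the Spearman
#' rank correlation between their canonical pairwise item-distance vectors,
#' reported together with its Fisher z transform (`atanh`, with the
#' correlation clipped to `±clip` so identical sorts stay finite).  Because
#' only the ranks of distances enter, alignment is invariant under
#' independent translation, rotation, reflection and uniform scaling of
#' either sort.
#'
#' @param d1,d2 [pairwise_distances()] of the two sorts; must cover the same
#'   item set.
#' @param clip clipping bound for the Fisher transform.
#' @return named numeric vector `c(rho = ..., z = ...)`.
#' @export
alignment <- function(d1, d2, clip = 1 - 1e-6) {
  stopifnot(inherits(d1, "distance_vector"), inherits(d2, "distance_vector"))
  if (!identical(d1$items, d2$items))
    stop("sorts cover different item sets; alignment is not comparable")
  rho <- spearman_rho(d1$d, d2$d)
  c(rho = rho, z = fisher_z(rho, clip))
}

#' Alignment restricted to within- or between-category pairs
#'
#' As [alignment()], but the rank correlation is computed only over the
#' same-category pairs (`subset = "within_category"`; 90 of the 190 pairs for
#' a 10+10 item set) or only over the cross-category pairs
#' (`"between_category"`; 100 pairs).
#'
#' @inheritParams alignment
#' @param subset which pairs to keep.
#' @param category_of named character vector mapping item id to category.
#' @return named numeric vector `c(rho = ..., z = ...)`.
#' @export
subset_alignment <- function(d1, d2,
                             subset = c("within_category", "between_category"),
                             category_of, clip = 1 - 1e-6) {
  subset <- match.arg(subset)
  stopifnot(inherits(d1, "distance_vector"), inherits(d2, "distance_vector"))
  if (!identical(d1$items, d2$items))
    stop("sorts cover different item sets; alignment is not comparable")
  keep <- within_pair_mask(d1, category_of)
  if (subset == "between_category") keep <- !keep
  if (sum(keep) < 3) stop("too few pairs in subset for a rank correlation")
  rho <- spearman_rho(d1$d[keep], d2$d[keep])
  c(rho = rho, z = fisher_z(rho, clip))
}

# rank matrix (one row per sorter) -> symmetric Fisher-z matrix, diag NA.
# ranks are computed once per sorter so large cohorts reduce to one matrix
# cross-product (Spearman = Pearson on ranks).
zmatrix_from_dmat <- function(D, clip = 1 - 1e-6) {
  if (any(apply(D, 1, sd) == 0))
    stop("undefined rank correlation: a distance vector has zero variance")
  R <- t(apply(D, 1, rank))
  C <- cor(t(R))
  Z <- atanh(clip_rho(C, clip))
  diag(Z) <- NA_real_
  C2 <- C; diag(C2) <- NA_real_
  list(rho = C2, z = Z)
}

#' Within-condition alignment of a cohort
#'
#' Computes every within-condition dyad's alignment and each participant's
#' mean alignment (mean Fisher-z over all of that participant's dyads, the
#' aggregation that sidesteps dyad non-independence).  Cross-condition dyads
#' are never formed.
#'
#' @param cohort list of [sort_record()]s; every condition must contain at
#'   least 2 participants and all sorts must share one item set.
#' @param clip clipping bound for the Fisher transform.
#' @return list with:
#'   \describe{
#'     \item{`participants`}{data.frame `participant_id`, `condition`,
#'       `mean_alignment` (mean z) and `mean_rho`.}
#'     \item{`dyads`}{data.frame `condition`, `id_i`, `id_j`, `rho`, `z`
#'       (each unordered within-condition pair once, `id_i < id_j`).}
#'     \item{`z_by_condition`}{named list of symmetric z matrices.}
#'   }
#' @export
alignment_matrix <- function(cohort, clip = 1 - 1e-6) {
  stopifnot(length(cohort) >= 2)
  conds <- vapply(cohort, `[[`, "", "condition")
  parts <- vapply(cohort, `[[`, "", "participant_id")
  if (anyDuplicated(parts)) stop("duplicate participant_ids in cohort")
  dvs <- lapply(cohort, pairwise_distances)
  items0 <- dvs[[1]]$items
  for (dv in dvs) if (!identical(dv$items, items0))
    stop("all sorts must cover the same item set")
  p_rows <- list(); d_rows <- list(); zmats <- list()
  for (cond in unique(conds)) {
    sel <- which(conds == cond)
    if (length(sel) < 2)
      stop(sprintf("condition '%s' has a single participant; alignment undefined", cond))
    D <- do.call(rbind, lapply(dvs[sel], `[[`, "d"))
    m <- zmatrix_from_dmat(D, clip)
    ids <- parts[sel]
    dimnames(m$z) <- dimnames(m$rho) <- list(ids, ids)
    zmats[[cond]] <- m$z
    ut <- which(upper.tri(m$z), arr.ind = TRUE)
    d_rows[[cond]] <- data.frame(
      condition = cond, id_i = ids[ut[, 1]], id_j = ids[ut[, 2]],
      rho = m$rho[ut], z = m$z[ut], stringsAsFactors = FALSE)
    p_rows[[cond]] <- data.frame(
      participant_id = ids, condition = cond,
      mean_alignment = rowMeans(m$z, na.rm = TRUE),
      mean_rho = rowMeans(m$rho, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  participants <- do.call(rbind, p_rows)
  rownames(participants) <- NULL
  dyads <- do.call(rbind, d_rows)
  rownames(dyads) <- NULL
  list(participants = participants, dyads = dyads, z_by_condition = zmats)
}

#' Bridge two individual scores to one dyad-level covariate
#'
#' Alignment lives at the dyad level while categoricality (or cluster count)
#' is an individual measure.  The bridge summarises the pair of individual
#' scores three ways: their minimum, their maximum, and their absolute
#' difference.  For scores 1 and 0.4 these are 0.4, 1 and 0.6.  Symmetric in
#' its arguments.
#'
#' @param score_i,score_j the two participants' scores.
#' @return named numeric vector `c(min = , max = , absdiff = )`.
#' @export
dyad_bridge <- function(score_i, score_j) {
  stopifnot(is.finite(score_i), is.finite(score_j))
  c(min = min(score_i, score_j), max = max(score_i, score_j),
    absdiff = abs(score_i - score_j))
}

#' Reaction-time trial filter
#'
#' Keeps correct-trial RTs that are at least 150 ms and no more than 2
#' subject SDs above the subject's mean (mean and SD computed on the input,
#' before any exclusion).  The SD rule is upper-tail only; anticipations are
#' handled by the 150 ms floor.
#'
#' @param rt numeric vector of one subject's correct-trial RTs in ms.
#' @return the surviving RTs, in input order.
#' @export
rt_filter <- function(rt) {
  if (!length(rt)) return(rt)
  m <- mean(rt)
  s <- if (length(rt) > 1) sd(rt) else 0
  rt[rt >= 150 & rt <= m + 2 * s]
}

#' Participant-level exclusion rules
#'
#' Applies the data-quality rules where the relevant data exist: a
#' participant is excluded if they failed to move all items during the sort
#' (`moved_all = FALSE`), scored below 80% accuracy on the match-to-sample
#' task, or got fewer than 7 of 9 catch trials correct.  Exactly 7/9 is kept.
#'
#' @param cohort list of [sort_record()]s.
#' @param logs optional data.frame of task logs with columns
#'   `participant_id` and any of `accuracy` (proportion correct) and
#'   `catch_correct` (count out of `catch_total`, default 9).  Participants
#'   absent from `logs` are only subject to the sort-completion rule.
#' @return data.frame `participant_id`, `kept` (logical), `reason`
#'   (`"ok"`, `"sort-incomplete"`, `"low-accuracy"` or `"failed-catch"`; the
#'   first failing rule in that order is reported).
#' @export
participant_filter <- function(cohort, logs = NULL) {
  ids <- vapply(cohort, `[[`, "", "participant_id")
  moved <- vapply(cohort, `[[`, TRUE, "moved_all")
  reason <- ifelse(moved, "ok", "sort-incomplete")
  if (!is.null(logs)) {
    stopifnot("participant_id" %in% names(logs))
    m <- match(ids, logs$participant_id)
    if (!is.null(logs$accuracy)) {
      acc <- logs$accuracy[m]
      reason[reason == "ok" & !is.na(acc) & acc < 0.80] <- "low-accuracy"
    }
    if (!is.null(logs$catch_correct)) {
      cc <- logs$catch_correct[m]
      reason[reason == "ok" & !is.na(cc) & cc < 7] <- "failed-catch"
    }
  }
  data.frame(participant_id = ids, kept = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}
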