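#' Sorter strategy configuration
#'
#' Describes how one simulated participant places items on the canvas.
#' Strategies:
#' \describe{
#'   \item{`random_uniform`}{every item i.i.d. uniform over the canvas.}
#'   \item{`grid`}{items on an evenly spaced lattice filling the canvas,
#'     item-to-cell assignment shuffled by the seed.}
#'   \item{`categorical`}{two cluster centres `center_separation` pixels
#'     apart (horizontally, canvas-centred); each item sits at its own
#'     category's centre plus isotropic Gaussian noise with SD `within_sd`.}
#'   \item{`mixed_clusters`}{`n_clusters` tight clusters whose membership
#'     deliberately interleaves A and B items, so the sort is clustered but
#'     not categorical.}
#' }
#' Gaussian noise is reflected at the canvas borders, which preserves the
#' within-cluster spread better than truncation.
#'
#' @param strategy placement strategy (see Details).
#' @param n_clusters number of clusters for `mixed_clusters`.
#' @param center_separation distance between cluster centres in pixels.
#' @param within_sd isotropic within-cluster SD in pixels (> 0 for cluster
#'   strategies).
#' @param canvas_w,canvas_h canvas size in pixels.
#' @param seed integer RNG seed; placement is deterministic given the seed.
#' @return an object of class `"sorter_config"`.
#' @export
sorter_config <- function(strategy = c("random_uniform", "grid", "categorical",
                                       "mixed_clusters"),
                          n_clusters = 2L, center_separation = 250,
                          within_sd = 100, canvas_w = 1024, canvas_h = 768,
                          seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(n_clusters >= 1, center_separation >= 0,
            canvas_w > 0, canvas_h > 0)
  if (strategy %in% c("categorical", "mixed_clusters") && within_sd <= 0)
    stop("within_sd must be > 0 for cluster strategies")
  if (center_separation > min(canvas_w, canvas_h))
    stop("cluster centers must fit inside the canvas")
  structure(list(strategy = strategy, n_clusters = as.integer(n_clusters),
                 center_separation = center_separation, within_sd = within_sd,
                 canvas_w = canvas_w, canvas_h = canvas_h,
                 seed = as.integer(seed)),
            class = "sorter_config")
}

#' A single participant's sort
#'
#' One final arrangement: the (x, y) pixel position of every item on the
#' canvas plus condition metadata.  `moved_all` records whether the
#' participant moved every item (sorts with `moved_all = FALSE` are excluded
#' by [participant_filter()]).
#'
#' @param participant_id character identifier.
#' @param condition condition label (e.g. `"baseline"`, `"no_labels"`,
#'   `"with_labels"`, or `"synthetic:<strategy>"`).
#' @param item_ids character vector of item ids (canonical order is sorted).
#' @param x,y numeric coordinate vectors, same length as `item_ids`.
#' @param canvas_w,canvas_h canvas size in pixels.
#' @param moved_all logical.
#' @return an object of class `"sort_record"`.
#' @export
sort_record <- function(participant_id, condition, item_ids, x, y,
                        canvas_w = 1024, canvas_h = 768, moved_all = TRUE) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) != length(x) || length(x) != length(y))
    stop("item_ids, x and y must have equal length")
  if (anyDuplicated(item_ids)) stop("duplicate item_ids in sort record")
  if (any(x < 0 | x > canvas_w | y < 0 | y > canvas_h))
    stop("coordinates outside the canvas")
  structure(list(participant_id = as.character(participant_id),
                 condition = as.character(condition),
                 item_ids = item_ids, x = as.numeric(x), y = as.numeric(y),
                 canvas_w = canvas_w, canvas_h = canvas_h,
                 moved_all = isTRUE(moved_all)),
            class = "sort_record")
}

#' @export
print.sort_record <- function(x, ...) {
  cat(sprintf("<sort_record %s (%s): %d items on %g x %g canvas>\n",
              x$participant_id, x$condition, length(x$item_ids),
              x$canvas_w, x$canvas_h))
  invisible(x)
}

# fold a coordinate back into [lo, hi] by reflection at the borders
reflect_into <- function(z, lo, hi) {
  w <- hi - lo
  z <- (z - lo) %% (2 * w)
  lo + ifelse(z > w, 2 * w - z, z)
}

#' The default 20-item free-sort item set
#'
#' Ten items per category, ids `A01..A10` and `B01..B10`.
#'
#' @return list with `item_ids` (character vector, canonical order) and
#'   `category_of` (named character vector mapping item id to `"A"`/`"B"`).
#' @export
default_item_set <- function() {
  ids <- c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10))
  list(item_ids = ids,
       category_of = setNames(substr(ids, 1, 1), ids))
}

#' Simulate one sort
#'
#' Places the items on the canvas according to the configured strategy (see
#' [sorter_config()]).  Deterministic given `cfg$seed`.
#'
#' @param item_ids character vector of item ids.
#' @param category_of named character vector mapping item id to `"A"`/`"B"`;
#'   required for the `categorical` strategy.
#' @param cfg a [sorter_config()].
#' @param participant_id,condition metadata recorded on the result.
#' @return a [sort_record()].
#' @export
simulate_sort <- function(item_ids, category_of = NULL, cfg = sorter_config(),
                          participant_id = "s1",
                          condition = paste0("synthetic:", cfg$strategy)) {
  stopifnot(inherits(cfg, "sorter_config"))
  n <- length(item_ids)
  w <- cfg$canvas_w; h <- cfg$canvas_h
  set.seed(cfg$seed)
  if (cfg$strategy == "random_uniform") {
    x <- runif(n, 0, w); y <- runif(n, 0, h)
  } else if (cfg$strategy == "grid") {
    ncol_ <- ceiling(sqrt(n * w / h))
    nrow_ <- ceiling(n / ncol_)
    cells <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))[seq_len(n), ]
    assign <- sample.int(n)                 # seed-shuffled item-to-cell map
    x <- ((cells$col - 0.5) * w / ncol_)[order(assign)]
    y <- ((cells$row - 0.5) * h / nrow_)[order(assign)]
  } else if (cfg$strategy == "categorical") {
    if (is.null(category_of)) stop("categorical strategy needs category_of")
    cats <- category_of[item_ids]
    if (any(is.na(cats))) stop("category_of is missing some items")
    centers <- rbind(A = c(w / 2 - cfg$center_separation / 2, h / 2),
                     B = c(w / 2 + cfg$center_separation / 2, h / 2))
    mu <- centers[cats, , drop = FALSE]
    x <- reflect_into(mu[, 1] + rnorm(n, 0, cfg$within_sd), 0, w)
    y <- reflect_into(mu[, 2] + rnorm(n, 0, cfg$within_sd), 0, h)
  } else {  # mixed_clusters
    k <- cfg$n_clusters
    ang <- 2 * pi * (seq_len(k) - 1) / k
    centers <- cbind(w / 2 + cfg$center_separation / 2 * cos(ang),
                     h / 2 + cfg$center_separation / 2 * sin(ang))
    # interleave categories, then cut into contiguous blocks, so every
    # cluster holds a mix of A and B items
    if (!is.null(category_of)) {
      cats <- category_of[item_ids]
      ord <- order(stats::ave(seq_len(n), cats, FUN = seq_along), cats)
    } else {
      ord <- seq_len(n)
    }
    memb <- integer(n)
    memb[ord] <- rep(seq_len(k), each = ceiling(n / k), length.out = n)
    x <- reflect_into(centers[memb, 1] + rnorm(n, 0, cfg$within_sd), 0, w)
    y <- reflect_into(centers[memb, 2] + rnorm(n, 0, cfg$within_sd), 0, h)
  }
  sort_record(participant_id, condition, item_ids, x, y, w, h, moved_all = TRUE)
}

#' Default condition parameterisation of the synthetic cohort
#'
#' Three conditions of categorical sorters emulating the study design:
#' `baseline` and `no_labels` share the same moderate separation-to-spread
#' ratio (centres 250 px apart, within-cluster SD 100 px); `with_labels`
#' places more compact clusters further apart (300 px / 90 px), so its
#' expected categoricality and alignment exceed the other two conditions.
#'
#' @param canvas_w,canvas_h canvas size in pixels.
#' @return named list of [sorter_config()] templates (seeds are overwritten
#'   per participant by [simulate_cohort()]).
#' @export
default_cohort_params <- function(canvas_w = 1024, canvas_h = 768) {
  base <- sorter_config("categorical", center_separation = 250, within_sd = 100,
                        canvas_w = canvas_w, canvas_h = canvas_h)
  lab <- sorter_config("categorical", center_separation = 300, within_sd = 90,
                       canvas_w = canvas_w, canvas_h = canvas_h)
  list(baseline = base, no_labels = base, with_labels = lab)
}

#' Simulate a multi-condition cohort of sorters
#'
#' Generates `n_per_condition` sort records for every condition in
#' `condition_params`.  Per-participant seeds are derived deterministically
#' from `seed`, so the same master seed reproduces the same cohort exactly.
#'
#' @param n_per_condition participants per condition (>= 2; pairwise
#'   alignment is undefined for a singleton condition).
#' @param condition_params named list of [sorter_config()] templates, one per
#'   condition (default [default_cohort_params()]).
#' @param seed master integer seed.
#' @param item_ids,category_of item set (default [default_item_set()]).
#' @return list of [sort_record()] objects.
#' @export
simulate_cohort <- function(n_per_condition = 40,
                            condition_params = default_cohort_params(),
                            seed = 1,
                            item_ids = default_item_set()$item_ids,
                            category_of = default_item_set()$category_of) {
  if (n_per_condition < 2)
    stop("need at least 2 participants per condition (alignment undefined)")
  out <- list()
  idx <- 0L
  for (cond in names(condition_params)) {
    cfg <- condition_params[[cond]]
    for (i in seq_len(n_per_condition)) {
      idx <- idx + 1L
      cfg$seed <- derive_seed(seed, idx)
      out[[idx]] <- simulate_sort(item_ids, category_of, cfg,
                                  participant_id = sprintf("%s_%03d", cond, i),
                                  condition = cond)
    }
  }
  out
}

#' Simulate a per-participant table with a purely mediated condition effect
#'
#' Generative model for mediation recovery checks: the condition shifts
#' categoricality (`cat_shift`), and alignment depends on categoricality
#' (slope `slope`) plus independent noise — the condition has no direct path
#' to alignment.  Fitting alignment on condition alone therefore shows an
#' effect that vanishes once categoricality is entered as a covariate.
#'
#' @param n_per_condition participants per condition.
#' @param cat_shift shift in mean categoricality between the two conditions.
#' @param slope effect of categoricality on alignment.
#' @param cat_sd,noise_sd SDs of categoricality and of the alignment noise.
#' @param seed integer seed.
#' @return data.frame with columns `participant_id`, `condition`,
#'   `categoricality`, `mean_alignment`.
#' @export
simulate_mediated_table <- function(n_per_condition = 200, cat_shift = 0.3,
                                    slope = 0.6, cat_sd = 0.5, noise_sd = 0.05,
                                    seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_condition
  condition <- rep(c("no_labels", "with_labels"), each = n_per_condition)
  categoricality <- 0.4 + cat_shift * (condition == "with_labels") +
    rnorm(n, 0, cat_sd)
  mean_alignment <- 0.05 + slope * categoricality + rnorm(n, 0, noise_sd)
  data.frame(participant_id = sprintf("p%03d", seq_len(n)),
             condition = condition, categoricality = categoricality,
             mean_alignment = mean_alignment, stringsAsFactors = FALSE)
}
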