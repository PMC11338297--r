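#' Fit the full free-sort analysis to a cohort
#'
#' The central modelling function: takes a cohort of sort records and
#' computes, per participant, categoricality, mean within-condition
#' alignment and the estimated cluster count; per dyad, alignment and the
#' three bridged categoricality covariates (minimum, maximum, absolute
#' difference); and, across conditions, the condition-effect models for
#' alignment and categoricality (all pairwise contrasts), the Poisson model
#' for cluster counts, the logistic model for 2-cluster sorts, the
#' correlations between alignment and each bridged covariate, and the
#' mediation of every condition effect on alignment by the min-bridged
#' categoricality.
#'
#' @param cohort list of [sort_record()]s; every condition needs >= 2
#'   participants and all sorts must share one item set.
#' @param category_of named character vector mapping item id to `"A"`/`"B"`;
#'   defaults to the first letter of each item id when these are `"A"`/`"B"`
#'   prefixed.
#' @param k_range candidate cluster counts for [estimate_k()].
#' @param clip Fisher-z clipping bound.
#' @return an object of class `"freesort"`: list with `participants`
#'   (per-participant table incl. bridged covariates), `dyads`, `effects`
#'   (named list of [condition_effect()] fits), `cluster_models`,
#'   `mediation` (named list of [mediation()] results, one per condition
#'   pair), `bridge_cor`, `by_condition` summary and the `call`.
#' @seealso [run_pipeline()] for the end-to-end wrapper,
#'   [simulate_cohort()] for synthetic input.
#' @export
#' @examples
#' coh <- simulate_cohort(n_per_condition = 8, seed = 42)
#' fit <- freesort(coh)
#' print(fit)
#' coef(fit)
freesort <- function(cohort, category_of = NULL, k_range = 2:10,
                     clip = 1 - 1e-6) {
  stopifnot(length(cohort) >= 2)
  if (is.null(category_of)) {
    ids <- sort(cohort[[1]]$item_ids)
    pre <- substr(ids, 1, 1)
    if (!all(pre %in% c("A", "B")))
      stop("supply category_of: item ids are not A/B prefixed")
    category_of <- setNames(pre, ids)
  }
  al <- alignment_matrix(cohort, clip)
  cat_scores <- vapply(cohort, function(s) categoricality(s, category_of)$score, 0)
  names(cat_scores) <- vapply(cohort, `[[`, "", "participant_id")
  cl <- cluster_counts(cohort, k_range)

  participants <- al$participants
  participants$categoricality <- cat_scores[participants$participant_id]
  m <- match(participants$participant_id, cl$participants$participant_id)
  participants$n_clusters <- cl$participants$n_clusters[m]
  participants$avg_silhouette <- cl$participants$avg_silhouette[m]

  dyads <- al$dyads
  ci <- cat_scores[dyads$id_i]; cj <- cat_scores[dyads$id_j]
  dyads$cat_min <- pmin(ci, cj)
  dyads$cat_max <- pmax(ci, cj)
  dyads$cat_absdiff <- abs(ci - cj)
  ni <- participants$n_clusters[match(dyads$id_i, participants$participant_id)]
  nj <- participants$n_clusters[match(dyads$id_j, participants$participant_id)]
  dyads$ncl_min <- pmin(ni, nj)

  bridge_mean <- function(col) {
    v <- c(tapply(c(dyads[[col]], dyads[[col]]),
                  c(dyads$id_i, dyads$id_j), mean))
    v[participants$participant_id]
  }
  participants$cat_min_bridge <- bridge_mean("cat_min")
  participants$cat_max_bridge <- bridge_mean("cat_max")
  participants$cat_absdiff_bridge <- bridge_mean("cat_absdiff")
  participants$ncl_min_bridge <- bridge_mean("ncl_min")

  conds <- unique(participants$condition)
  pairs <- all_condition_pairs(participants$condition)
  effects <- list(); med <- list()
  cluster_models <- NULL
  if (length(pairs)) {
    eff_rows <- function(outcome) {
      fits <- lapply(pairs, function(p) condition_effect(participants, outcome, p))
      terms <- do.call(rbind, lapply(fits, `[[`, "terms"))
      new_fit_result("linear", terms)
    }
    effects$mean_alignment <- eff_rows("mean_alignment")
    effects$categoricality <- eff_rows("categoricality")
    cluster_models <- list(poisson = cluster_count_model(participants),
                           two_cluster = two_cluster_model(participants))
    for (p in pairs)
      med[[paste(p, collapse = " vs ")]] <-
        mediation(participants, "cat_min_bridge", "mean_alignment", p)
  }
  by_condition <- do.call(rbind, lapply(split(participants, participants$condition),
    function(df) data.frame(
      condition = df$condition[1], n = nrow(df),
      mean_alignment = mean(df$mean_alignment),
      mean_categoricality = mean(df$categoricality),
      mean_clusters = mean(df$n_clusters),
      prop_two_cluster = mean(df$n_clusters == 2),
      stringsAsFactors = FALSE)))
  rownames(by_condition) <- NULL

  structure(list(participants = participants, dyads = dyads,
                 effects = effects, cluster_models = cluster_models,
                 mediation = med,
                 bridge_cor = bridge_correlations(participants),
                 by_condition = by_condition, k_range = k_range,
                 category_of = category_of, call = match.call()),
            class = "freesort")
}

#' @export
print.freesort <- function(x, digits = 3, ...) {
  cat("Free-sort analysis\n")
  cat(sprintf("  %d participants, %d conditions, %d items\n",
              nrow(x$participants), length(unique(x$participants$condition)),
              length(x$category_of)))
  print(format(x$by_condition, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.freesort <- function(object, ...) {
  structure(list(fit = object), class = "summary.freesort")
}

#' @export
print.summary.freesort <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  if (length(f$effects)) {
    cat("\nCondition effects on mean alignment:\n")
    print(format(f$effects$mean_alignment$terms, digits = digits), row.names = FALSE)
    cat("\nCondition effects on categoricality:\n")
    print(format(f$effects$categoricality$terms, digits = digits), row.names = FALSE)
    cat("\nCluster-count (Poisson) contrasts:\n")
    print(format(f$cluster_models$poisson$terms, digits = digits), row.names = FALSE)
    cat("\n2-cluster (logistic) contrasts:\n")
    print(format(f$cluster_models$two_cluster$terms, digits = digits), row.names = FALSE)
  }
  cat("\nAlignment ~ bridged covariate correlations:\n")
  print(format(f$bridge_cor, digits = digits), row.names = FALSE)
  if (length(f$mediation)) {
    cat("\nMediation by min-bridged categoricality:\n")
    for (nm in names(f$mediation)) {
      m <- f$mediation[[nm]]
      cat(sprintf("  %s: raw b = %.4f (p = %.3g) -> adjusted b = %.4f (p = %.3g): %s\n",
                  nm, m$condition_coef_raw, m$condition_p_raw,
                  m$condition_coef_adjusted, m$condition_p_adjusted, m$verdict))
    }
  }
  invisible(x)
}

#' @export
coef.freesort <- function(object, outcome = "mean_alignment", ...) {
  if (!length(object$effects)) return(numeric(0))
  terms <- object$effects[[outcome]]$terms
  setNames(terms$estimate, terms$term)
}

#' Plot a free-sort fit
#'
#' Scatter of per-participant mean alignment against the min-bridged
#' categoricality, coloured by condition — the package's analogue of the
#' categoricality-mediates-alignment figure.
#'
#' @param x a `"freesort"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.freesort <- function(x, ...) {
  p <- x$participants
  conds <- unique(p$condition)
  cols <- setNames(seq_along(conds) + 1L, conds)
  plot(p$cat_min_bridge, p$mean_alignment, col = cols[p$condition], pch = 19,
       xlab = "min-bridged categoricality (mean over dyads)",
       ylab = "mean alignment (Fisher z)", ...)
  if (length(conds) > 1)
    legend("topleft", legend = conds, col = cols, pch = 19, bty = "n")
  invisible(x)
}
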