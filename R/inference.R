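new_fit_result <- function(model_kind, terms, r_squared = NA_real_,
                           degenerate = FALSE, note = NULL) {
  structure(list(model_kind = model_kind, terms = terms,
                 r_squared = r_squared, degenerate = degenerate, note = note),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat(sprintf("<%s fit%s>\n", x$model_kind,
              if (x$degenerate) " (degenerate)" else ""))
  print(format(x$terms, digits = digits), row.names = FALSE)
  if (!is.na(x$r_squared)) cat(sprintf("R-squared: %.3f\n", x$r_squared))
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

# centered two-level condition indicator; slope equals the between-condition
# difference regardless of centering
condition_indicator <- function(tab, contrast) {
  stopifnot(length(contrast) == 2)
  sub <- tab[tab$condition %in% contrast, , drop = FALSE]
  if (length(unique(sub$condition)) < 2)
    stop("both contrast conditions must be present")
  if (min(table(sub$condition)) < 2)
    stop("need at least 2 participants per condition")
  ind <- as.numeric(sub$condition == contrast[2])
  sub$cond_c <- ind - mean(ind)
  sub
}

#' Condition effect on a per-participant outcome
#'
#' Ordinary least squares of the outcome on a centered condition indicator
#' for one named pair of conditions; the slope is the difference in condition
#' means (second minus first element of `contrast`), reported with its SE,
#' t statistic and p value.
#'
#' @param tab per-participant data.frame with columns `condition` and the
#'   outcome.
#' @param outcome name of the outcome column (e.g. `"mean_alignment"` or
#'   `"categoricality"`).
#' @param contrast character vector of two condition labels; the first is
#'   the reference.
#' @return a `"fit_result"` with one slope row in `terms` and the model
#'   `r_squared`.
#' @export
condition_effect <- function(tab, outcome = "mean_alignment",
                             contrast = c("no_labels", "with_labels")) {
  stopifnot(outcome %in% names(tab))
  sub <- condition_indicator(tab, contrast)
  y <- sub[[outcome]]
  if (sd(y) == 0) stop("degenerate fit: outcome has zero variance")
  fit <- lm(y ~ cond_c, data = sub)
  sm <- summary(fit)
  co <- sm$coefficients["cond_c", ]
  if (!is.finite(co["Std. Error"]) || co["Std. Error"] <= 0)
    stop("degenerate fit: slope standard error is not positive")
  terms <- data.frame(
    term = sprintf("%s - %s", contrast[2], contrast[1]),
    estimate = unname(co["Estimate"]), se = unname(co["Std. Error"]),
    statistic = unname(co["t value"]), p = unname(co["Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  new_fit_result("linear", terms, r_squared = sm$r.squared)
}

#' Mediation of a condition effect by a covariate
#'
#' Fits the outcome on the centered condition indicator alone, then again
#' with the covariate entered.  Reports the raw and adjusted condition
#' coefficients, the covariate's coefficient, and `variance_accounted`
#' (the covariate's squared partial correlation in the adjusted model,
#' `t^2 / (t^2 + df)`; the adjusted model's R^2 is reported alongside).
#' Verdict: `"complete"` if the raw effect is significant but the adjusted
#' condition term is not (alpha = .05), `"partial"` if the adjusted
#' condition term remains significant but shrinks in magnitude while the
#' covariate itself is significant (a covariate unrelated to the outcome
#' cannot mediate), `"none"` otherwise.
#'
#' @param tab per-participant data.frame with `condition`, the outcome and
#'   the covariate columns.
#' @param covariate name of the covariate column (e.g. the min-bridged
#'   categoricality, `"cat_min_bridge"`).
#' @param outcome name of the outcome column.
#' @param contrast two condition labels, reference first.
#' @param alpha significance level for the verdict.
#' @return an object of class `"mediation_result"`.
#' @export
mediation <- function(tab, covariate = "cat_min_bridge",
                      outcome = "mean_alignment",
                      contrast = c("no_labels", "with_labels"), alpha = 0.05) {
  stopifnot(outcome %in% names(tab), covariate %in% names(tab))
  sub <- condition_indicator(tab, contrast)
  y <- sub[[outcome]]
  xcov <- sub[[covariate]] - mean(sub[[covariate]])
  if (sd(xcov) == 0) stop("covariate has zero variance")
  raw <- summary(lm(y ~ cond_c, data = sub))$coefficients
  adj_fit <- lm(y ~ cond_c + xcov, data = sub)
  adj_sum <- suppressWarnings(summary(adj_fit))  # a collinear covariate is
  adj <- adj_sum$coefficients                    # diagnosed below, not warned
  if (nrow(adj) < 3 || any(!is.finite(adj[, "Std. Error"])) ||
      adj_sum$sigma < 1e-10)
    stop("degenerate fit: covariate is collinear with the outcome or condition")
  t_cov <- adj["xcov", "t value"]
  df <- adj_fit$df.residual
  raw_b <- raw["cond_c", "Estimate"]; raw_p <- raw["cond_c", "Pr(>|t|)"]
  adj_b <- adj["cond_c", "Estimate"]; adj_p <- adj["cond_c", "Pr(>|t|)"]
  cov_p <- adj["xcov", "Pr(>|t|)"]
  verdict <- if (raw_p < alpha && adj_p >= alpha) "complete"
  else if (adj_p < alpha && cov_p < alpha && abs(adj_b) < abs(raw_b)) "partial"
  else "none"
  structure(list(
    condition_coef_raw = unname(raw_b), condition_p_raw = unname(raw_p),
    condition_coef_adjusted = unname(adj_b),
    condition_p_adjusted = unname(adj_p),
    covariate = covariate,
    covariate_coef = unname(adj["xcov", "Estimate"]),
    covariate_se = unname(adj["xcov", "Std. Error"]),
    covariate_t = unname(t_cov),
    variance_accounted = unname(t_cov^2 / (t_cov^2 + df)),
    model_r_squared = adj_sum$r.squared,
    verdict = verdict, contrast = contrast),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation of condition (%s vs %s) by %s>\n",
              x$contrast[1], x$contrast[2], x$covariate))
  cat(sprintf("  condition effect: raw b = %.4f (p = %.3g), adjusted b = %.4f (p = %.3g)\n",
              x$condition_coef_raw, x$condition_p_raw,
              x$condition_coef_adjusted, x$condition_p_adjusted))
  cat(sprintf("  covariate: b = %.4f, SE = %.4f, t = %.2f; variance accounted %.1f%%\n",
              x$covariate_coef, x$covariate_se, x$covariate_t,
              100 * x$variance_accounted))
  cat(sprintf("  verdict: %s mediation\n",
              if (x$verdict == "none") "no" else x$verdict))
  invisible(x)
}

glm_pair_contrast <- function(tab, outcome_vec, family, contrast) {
  sub <- condition_indicator(tab, contrast)
  y <- outcome_vec[tab$condition %in% contrast]
  fit <- suppressWarnings(glm(y ~ cond_c, data = sub, family = family))
  sep <- !fit$converged || any(abs(fit$coefficients) > 15)
  co <- summary(fit)$coefficients["cond_c", ]
  data.frame(term = sprintf("%s - %s", contrast[2], contrast[1]),
             estimate = unname(co[1]), se = unname(co[2]),
             statistic = unname(co[3]), p = unname(co[4]),
             degenerate = sep, stringsAsFactors = FALSE)
}

all_condition_pairs <- function(conds) {
  lv <- unique(conds)
  if (length(lv) < 2) return(list())
  cmb <- combn(lv, 2, simplify = FALSE)
  cmb
}

#' Poisson model for cluster counts
#'
#' Poisson regression (log link) of the per-participant cluster count on the
#' condition, reported as pairwise contrasts (z statistics).  Cluster counts
#' must be >= 1 — a sort always has at least one cluster.
#'
#' @param tab per-participant data.frame with columns `condition` and
#'   `n_clusters`.
#' @return a `"fit_result"` (`model_kind = "poisson"`) with one row per
#'   condition pair; estimates are log rate ratios.
#' @export
cluster_count_model <- function(tab) {
  stopifnot(all(c("condition", "n_clusters") %in% names(tab)))
  if (any(tab$n_clusters < 1)) stop("cluster counts must be >= 1")
  pairs <- all_condition_pairs(tab$condition)
  if (!length(pairs)) stop("need at least 2 conditions")
  rows <- lapply(pairs, function(p)
    glm_pair_contrast(tab, tab$n_clusters, poisson(), p))
  terms <- do.call(rbind, rows)
  new_fit_result("poisson", terms, degenerate = any(terms$degenerate))
}

#' Logistic model for 2-cluster sorts
#'
#' Logistic regression of the indicator `n_clusters == 2` on the condition,
#' reported as pairwise contrasts (log odds ratios).  Complete separation
#' (a condition with all-2-cluster or no-2-cluster sorts) is flagged as a
#' degenerate fit rather than reported as a finite estimate.
#'
#' @param tab per-participant data.frame with columns `condition` and
#'   `n_clusters`.
#' @return a `"fit_result"` (`model_kind = "logistic"`).
#' @export
two_cluster_model <- function(tab) {
  stopifnot(all(c("condition", "n_clusters") %in% names(tab)))
  ind <- as.numeric(tab$n_clusters == 2)
  pairs <- all_condition_pairs(tab$condition)
  if (!length(pairs)) stop("need at least 2 conditions")
  rows <- lapply(pairs, function(p) glm_pair_contrast(tab, ind, binomial(), p))
  terms <- do.call(rbind, rows)
  new_fit_result("logistic", terms, degenerate = any(terms$degenerate))
}

#' Correlations between mean alignment and bridged covariates
#'
#' Pearson correlations, across participants, between the per-participant
#' mean alignment and each bridged covariate: minimum, maximum and absolute
#' difference of pairwise categoricality (each averaged over the
#' participant's within-condition dyads), plus the min-bridged cluster count
#' when present.
#'
#' @param tab per-participant data.frame with `mean_alignment` and the
#'   bridged covariate columns `cat_min_bridge`, `cat_max_bridge`,
#'   `cat_absdiff_bridge` (and optionally `ncl_min_bridge`).
#' @return data.frame `covariate`, `r`, `p`.
#' @export
bridge_correlations <- function(tab) {
  stopifnot("mean_alignment" %in% names(tab))
  covs <- intersect(c("cat_min_bridge", "cat_max_bridge", "cat_absdiff_bridge",
                      "ncl_min_bridge"), names(tab))
  if (!length(covs)) stop("no bridged covariate columns found")
  rows <- lapply(covs, function(cv) {
    x <- tab[[cv]]; y <- tab$mean_alignment
    if (sd(x) == 0 || sd(y) == 0)
      stop(sprintf("undefined correlation: '%s' or alignment has zero variance", cv))
    ct <- cor.test(x, y)
    data.frame(covariate = cv, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
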