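#' Write a cohort of sorts to CSV
#'
#' Long layout, one row per item: columns `participant_id`, `condition`,
#' `item_id`, `x`, `y`, `canvas_w`, `canvas_h`, `moved_all`.
#'
#' @param cohort list of [sort_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sorts <- function(cohort, path) {
  rows <- lapply(cohort, function(s)
    data.frame(participant_id = s$participant_id, condition = s$condition,
               item_id = s$item_ids, x = s$x, y = s$y,
               canvas_w = s$canvas_w, canvas_h = s$canvas_h,
               moved_all = s$moved_all, stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read sort records from CSV
#'
#' Reads the long layout written by [write_sorts()], or, with
#' `wide = TRUE`, a wide layout with one row per participant and paired
#' `<item>_x` / `<item>_y` columns.  Schema violations (missing columns,
#' missing or off-canvas coordinates, duplicate participant/item rows) are
#' reported with the offending row numbers.
#'
#' @param path CSV file.
#' @param wide logical; is the file in the wide layout?
#' @return list of [sort_record()]s.
#' @export
read_sorts <- function(path, wide = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (wide) df <- wide_to_long(df)
  required <- c("participant_id", "condition", "item_id", "x", "y",
                "canvas_w", "canvas_h", "moved_all")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!complete.cases(df[c("x", "y")]))
  if (length(bad))
    stop("missing coordinates in rows: ", paste(head(bad, 10), collapse = ", "))
  off <- which(df$x < 0 | df$x > df$canvas_w | df$y < 0 | df$y > df$canvas_h)
  if (length(off))
    stop("off-canvas coordinates in rows: ", paste(head(off, 10), collapse = ", "))
  dup <- which(duplicated(df[c("participant_id", "item_id")]))
  if (length(dup))
    stop("duplicate (participant, item) rows: ", paste(head(dup, 10), collapse = ", "))
  lapply(split(df, df$participant_id), function(g)
    sort_record(g$participant_id[1], g$condition[1], g$item_id, g$x, g$y,
                g$canvas_w[1], g$canvas_h[1], moved_all = all(g$moved_all)))
}

wide_to_long <- function(df) {
  xcols <- grep("_x$", names(df), value = TRUE)
  items <- sub("_x$", "", xcols)
  meta <- setdiff(names(df), c(paste0(items, "_x"), paste0(items, "_y")))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    data.frame(df[i, meta, drop = FALSE],
               item_id = items,
               x = as.numeric(df[i, paste0(items, "_x")]),
               y = as.numeric(df[i, paste0(items, "_y")]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic pipeline; serialises
#' losslessly through JSON.  Every stochastic stage derives its seed from
#' `seed`.
#'
#' @param n_per_condition participants per condition.
#' @param seed master integer seed.
#' @param condition_params named list of [sorter_config()]s (default
#'   [default_cohort_params()]).
#' @param k_range candidate cluster counts.
#' @param clip Fisher-z clipping bound.
#' @param out_dir optional output directory for the CSV/JSON report.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_per_condition = 40, seed = 1,
                            condition_params = default_cohort_params(),
                            k_range = 2:10, clip = 1 - 1e-6, out_dir = NULL) {
  structure(list(n_per_condition = n_per_condition, seed = seed,
                 condition_params = condition_params, k_range = k_range,
                 clip = clip, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the synthetic pipeline end to end
#'
#' Simulates the cohort, applies the participant filter, fits the full
#' analysis with [freesort()], and (when `out_dir` is set) writes
#' `participants.csv`, `dyads.csv` and `report.json`.  Every output carries
#' the seed and a hash of the configuration, and the whole run is
#' reproducible from `(config, seed)`: the same config produces
#' byte-identical reports.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `fit` (the `"freesort"` object), `exclusions` (the
#'   [participant_filter()] table) and `report` (the report list that is
#'   serialised to JSON).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort <- simulate_cohort(cfg$n_per_condition, cfg$condition_params,
                            seed = cfg$seed)
  excl <- participant_filter(cohort)
  kept <- cohort[excl$kept]
  message(sprintf("pipeline: %d sorts simulated, %d kept after filtering",
                  length(cohort), length(kept)))
  n_cond <- length(unique(vapply(kept, `[[`, "", "condition")))
  fit <- freesort(kept, k_range = cfg$k_range, clip = cfg$clip)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  report <- list(
    config_hash = hash, seed = cfg$seed,
    n_participants = nrow(fit$participants),
    by_condition = fit$by_condition,
    effects = lapply(fit$effects, `[[`, "terms"),
    cluster_models = lapply(fit$cluster_models, `[[`, "terms"),
    bridge_correlations = fit$bridge_cor,
    mediation = lapply(fit$mediation, function(m)
      m[c("condition_coef_raw", "condition_p_raw", "condition_coef_adjusted",
          "condition_p_adjusted", "covariate_coef", "variance_accounted",
          "verdict")]),
    exclusions = excl[!excl$kept, , drop = FALSE],
    note = if (n_cond < 2) "single condition: no contrasts" else NULL)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    ptab <- fit$participants; dtab <- fit$dyads
    ptab$config_hash <- hash; ptab$seed <- cfg$seed
    dtab$config_hash <- hash; dtab$seed <- cfg$seed
    write.csv(ptab, file.path(cfg$out_dir, "participants.csv"), row.names = FALSE)
    write.csv(dtab, file.path(cfg$out_dir, "dyads.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }
  list(fit = fit, exclusions = excl, report = report)
}
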