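#' Read a waveform record from a 3-row delimited matrix
#'
#' The conventional dump layout stores one record as a numeric matrix with
#' the three channels in separate rows. Supported layouts:
#' `"rows-ppg-abp-ecg"` (the re-hosted dump convention), `"rows-ecg-ppg-abp"`
#' and `"columns"` (three named/ordered columns ecg, ppg, abp).
#'
#' @param path Path to a whitespace- or comma-delimited text file.
#' @param layout Channel layout (see above).
#' @param fs Sampling rate, Hz (default 125).
#' @param record_id Identifier; defaults to the file name.
#' @return A record list: `record_id`, `ecg`, `ppg`, `abp`, `fs`.
#' @export
read_record_matrix <- function(path, layout = c("rows-ppg-abp-ecg",
                                                "rows-ecg-ppg-abp", "columns"),
                               fs = 125, record_id = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  if (layout == "columns") m <- t(m)
  if (nrow(m) != 3) {
    stop("expected 3 channels, found ", nrow(m), " in ", path)
  }
  if (mean(!is.finite(m)) > 0.05) stop("NaN density above 5% in ", path)
  ch <- switch(layout,
               "rows-ppg-abp-ecg" = list(ppg = 1, abp = 2, ecg = 3),
               "rows-ecg-ppg-abp" = ,
               "columns" = list(ecg = 1, ppg = 2, abp = 3))
  list(record_id = record_id %||% basename(path),
       ecg = as.numeric(m[ch$ecg, ]), ppg = as.numeric(m[ch$ppg, ]),
       abp = as.numeric(m[ch$abp, ]), fs = fs)
}

#' Write a waveform record as a 3-row delimited matrix
#'
#' Inverse of [read_record_matrix()]; optionally writes the record's ground
#' truth (when present) as a JSON sidecar next to the matrix file.
#'
#' @param record A record list (`ecg`, `ppg`, `abp`, optionally `truth`).
#' @param path Output path.
#' @param layout Channel layout (rows only).
#' @param sidecar Write `<path>.truth.json` when the record carries ground
#'   truth (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_record_matrix <- function(record, path,
                                layout = c("rows-ppg-abp-ecg", "rows-ecg-ppg-abp"),
                                sidecar = TRUE) {
  layout <- match.arg(layout)
  rows <- switch(layout,
                 "rows-ppg-abp-ecg" = rbind(record$ppg, record$abp, record$ecg),
                 "rows-ecg-ppg-abp" = rbind(record$ecg, record$ppg, record$abp))
  utils::write.table(format(rows, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(record$truth)) {
    jsonlite::write_json(record$truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings plus the global seed, so a run is fully
#' reproducible from the config alone. Unknown entries are rejected.
#'
#' @param synth A [synth_config()] (ignored when records are supplied to
#'   [run_pipeline()] directly).
#' @param selection A [selection_config()].
#' @param window_s Aggregation window, seconds.
#' @param min_beats Minimum accepted beats per window.
#' @param ptt_anchor PPG anchor for pulse transit time.
#' @param holdout_fraction Fraction of subjects held out for testing.
#' @param lambda_grid,alpha_grid,n_folds Cross-validation grids.
#' @param max_missing_col Drop feature columns masked in more than this
#'   fraction of rows (default 0.2).
#' @param seed Global seed.
#' @return A `"bp_pipeline_config"` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            selection = selection_config(),
                            window_s = 30, min_beats = 5L,
                            ptt_anchor = "max_slope",
                            holdout_fraction = 0.25,
                            lambda_grid = 10^seq(-2, 3, length.out = 20),
                            alpha_grid = c(0, 0.5, 1),
                            n_folds = 5L,
                            max_missing_col = 0.2,
                            seed = 1L) {
  structure(list(synth = synth, selection = selection, window_s = window_s,
                 min_beats = as.integer(min_beats), ptt_anchor = ptt_anchor,
                 holdout_fraction = holdout_fraction,
                 lambda_grid = lambda_grid, alpha_grid = alpha_grid,
                 n_folds = as.integer(n_folds),
                 max_missing_col = max_missing_col,
                 seed = as.integer(seed)),
            class = "bp_pipeline_config")
}

#' Build the window-level feature table from waveform records
#'
#' Runs quality screening, filtering, R-peak and PPG fiducial detection,
#' beat-feature extraction, ABP target extraction and window aggregation for
#' every record, returning one tibble of analysis rows (plus per-record
#' processing log).
#'
#' @param records List of record lists (`ecg`, `ppg`, `abp`, `fs`,
#'   `record_id`).
#' @param config A [pipeline_config()].
#' @return Tibble of window rows with `record_id`; attribute `log` is a
#'   tibble of per-record counts and rejection reasons.
#' @export
extract_feature_table <- function(records, config = pipeline_config()) {
  rows <- list(); logs <- list()
  for (rec in records) {
    fs <- rec$fs
    flags <- screen_quality(rec)
    if (!attr(flags, "accepted")) {
      logs[[rec$record_id]] <- tibble::tibble(
        record_id = rec$record_id, accepted = FALSE,
        reason = paste(names(flags)[flags], collapse = ","),
        n_beats = 0L, n_windows = 0L)
      next
    }
    spec <- filter_spec(fs)
    ecg <- filter_ecg(rec$ecg, spec)
    ppg <- remove_baseline(rec$ppg, fs)
    rp <- detect_r_peaks(ecg, fs)
    if (length(rp) < 3) {
      logs[[rec$record_id]] <- tibble::tibble(
        record_id = rec$record_id, accepted = FALSE, reason = "too_few_beats",
        n_beats = length(rp), n_windows = 0L)
      next
    }
    fid <- detect_ppg_fiducials(ppg, fs, rp)
    bf <- extract_beat_features(fid, ecg, ppg, fs, ptt_anchor = config$ptt_anchor)
    tg <- extract_targets_from_abp(rec$abp, rp)
    bf <- dplyr::left_join(bf, tg, by = "beat")
    win <- aggregate_window(bf, rp, fs, window_s = config$window_s,
                            min_beats = config$min_beats)
    if (nrow(win)) win$record_id <- rec$record_id
    rows[[rec$record_id]] <- win
    logs[[rec$record_id]] <- tibble::tibble(
      record_id = rec$record_id, accepted = TRUE, reason = "",
      n_beats = sum(bf$ok), n_windows = nrow(win))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "log") <- dplyr::bind_rows(logs)
  out
}

#' Run the full estimation pipeline
#'
#' Simulates (or consumes) a cohort, builds the window feature table, splits
#' subjects into train/held-out sets, runs the hybrid MSU feature selector
#' per target, fits a cross-validated elastic net on the fused top-k
#' features, and evaluates held-out predictions with RMSE/MAE, BHS grading
#' and the advisory AAMI check.
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of records; when `NULL` a cohort is
#'   simulated from `config$synth`.
#' @param method `"msu-hybrid"` (default) or `"pearson"` — which ranking
#'   chooses the regression features.
#' @return A `"bp_pipeline_result"`: per-target selection, model and report,
#'   the feature table, processing log, config and config hash.
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL,
                         method = c("msu-hybrid", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "bp_pipeline_config"))
  if (is.null(records)) records <- simulate_cohort(config$synth)$records
  tab <- extract_feature_table(records, config)
  if (!nrow(tab)) {
    stop("no analysis windows survived quality screening (",
         sum(!attr(tab, "log")$accepted), " records rejected)")
  }
  drop_cols <- names(tab)[vapply(tab, function(col) {
    mean(is.na(col)) > config$max_missing_col ||
      (is.numeric(col) && stats::sd(col, na.rm = TRUE) == 0)
  }, logical(1))]
  feat_cols <- setdiff(names(tab), c("record_id", "window", "n_beats",
                                     "sbp", "dbp", drop_cols))
  dat <- tab[stats::complete.cases(tab[c(feat_cols, "sbp", "dbp")]),
             c("record_id", feat_cols, "sbp", "dbp")]

  subjects <- unique(dat$record_id)
  set.seed(config$seed)
  n_test <- max(1L, round(length(subjects) * config$holdout_fraction))
  test_ids <- sample(subjects, n_test)
  train <- dat[!dat$record_id %in% test_ids, ]
  test <- dat[dat$record_id %in% test_ids, ]

  fit_target <- function(target) {
    other <- setdiff(c("sbp", "dbp"), target)
    d_tr <- train[c(feat_cols, target)]
    if (method == "msu-hybrid") {
      sel <- select_features(d_tr, target, config$selection, seed = config$seed)
      chosen <- sel$fused$feature
    } else {
      sel <- pearson_baseline_rank(d_tr, target)
      chosen <- utils::head(sel$feature, config$selection$top_k)
    }
    cv <- cv_select(train[chosen], train[[target]],
                    lambda_grid = config$lambda_grid,
                    alpha_grid = config$alpha_grid,
                    n_folds = config$n_folds, seed = config$seed)
    model <- cv$model
    model$target <- target
    pred <- predict(model, test[chosen])
    list(selection = sel, model = model,
         report = evaluate_bp(pred, test[[target]], target = target),
         predictions = tibble::tibble(record_id = test$record_id,
                                      pred = pred, true = test[[target]]))
  }
  res <- list(sbp = fit_target("sbp"), dbp = fit_target("dbp"))
  structure(list(sbp = res$sbp, dbp = res$dbp, feature_table = tab,
                 train_ids = setdiff(subjects, test_ids), test_ids = test_ids,
                 log = attr(tab, "log"), method = method, config = config,
                 config_hash = rlang::hash(config)),
            class = "bp_pipeline_result")
}

#' @export
print.bp_pipeline_result <- function(x, ...) {
  cat("Cuffless BP pipeline run (", x$method, "; config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  lg <- x$log
  cat("  records:", nrow(lg), "(", sum(lg$accepted), "accepted )\n")
  cat("  windows:", nrow(x$feature_table), "| held-out subjects:",
      length(x$test_ids), "\n")
  print(x$sbp$report)
  print(x$dbp$report)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
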