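#' Read an active/decoy test-set label table
#'
#' CSV columns: `compound_id`, `target`, `label` (`active` or `decoy`,
#' case-insensitive). Duplicate `(compound_id, target)` pairs, unknown
#' label values and empty files are rejected with classed errors.
#'
#' @param path CSV path.
#' @return Tibble with columns `compound_id`, `target`, `label`.
#' @seealso [test_set_summary()]
#' @export
read_test_set <- function(path) {
  if (!file.exists(path)) ph4_abort("ph4_io_error", paste("no such file:", path))
  labs <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) ph4_abort("ph4_malformed_csv", conditionMessage(e))
  )
  compile_test_set(labs)
}

#' Validate and normalise a test-set label table
#'
#' @param labs Data frame with columns `compound_id`, `target`, `label`.
#' @return Normalised tibble (labels lower-cased).
#' @export
compile_test_set <- function(labs) {
  labs <- as_tibble(labs)
  if (!nrow(labs)) ph4_abort("ph4_empty_test_set", "test set is empty")
  need <- c("compound_id", "target", "label")
  if (!all(need %in% names(labs))) {
    ph4_abort("ph4_schema_error",
              "test set needs columns compound_id, target, label")
  }
  labs <- labs[, need]
  labs$compound_id <- as.character(labs$compound_id)
  labs$target <- as.character(labs$target)
  labs$label <- tolower(as.character(labs$label))
  if (!all(labs$label %in% c("active", "decoy"))) {
    ph4_abort("ph4_bad_label", "labels must be 'active' or 'decoy'")
  }
  dup <- duplicated(labs[, c("compound_id", "target")])
  if (any(dup)) {
    ph4_abort("ph4_duplicate_label", paste(
      "duplicate (compound_id, target) rows:",
      paste(unique(labs$compound_id[dup]), collapse = ", ")
    ))
  }
  labs
}

#' Per-target test-set composition
#'
#' @param labs A label tibble from [read_test_set()].
#' @return Tibble with one row per target: `target`, `actives`, `decoys`,
#'   `total`.
#' @export
test_set_summary <- function(labs) {
  labs |>
    group_by(.data$target) |>
    summarise(
      actives = sum(.data$label == "active"),
      decoys = sum(.data$label == "decoy"),
      total = n(),
      .groups = "drop"
    )
}

#' Construct a confusion-count record
#'
#' Bookkeeping of one screen against a labelled test set: true/false
#' positives and negatives, with the derived totals `A = tp + fn`
#' (actives), `D = tn + fp` (decoys), `N = A + D`.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return One-row tibble of class `confusion_counts` with columns `tp`,
#'   `fp`, `tn`, `fn`, `A`, `D`, `N`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    ph4_abort("ph4_schema_error", "confusion counts must be non-negative integers")
  }
  out <- tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    A = as.integer(tp + fn), D = as.integer(tn + fp),
    N = as.integer(tp + fn + tn + fp)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Confusion counts of a screen against one target's labels
#'
#' Compounds labelled for the target must all have been screened (a
#' labelled compound absent from the screen's universe is an error listing
#' the missing ids); a labelled compound is positive iff the screen called
#' it a hit.
#'
#' @param report A `screen_report`.
#' @param labels Label tibble (columns `compound_id`, `label`; rows for one
#'   target).
#' @return A `confusion_counts` row.
#' @export
confusion_from_screen <- function(report, labels) {
  labels <- as_tibble(labels)
  missing <- setdiff(labels$compound_id, report$results$molecule_id)
  if (length(missing)) {
    ph4_abort("ph4_unscreened_compound", paste(
      "labelled compounds never screened:",
      paste(head(missing, 10L), collapse = ", "),
      if (length(missing) > 10L) sprintf("(and %d more)", length(missing) - 10L) else ""
    ))
  }
  j <- left_join(labels, report$results[, c("molecule_id", "hit")],
                 by = c(compound_id = "molecule_id"))
  confusion_counts(
    tp = sum(j$label == "active" & j$hit),
    fp = sum(j$label == "decoy" & j$hit),
    tn = sum(j$label == "decoy" & !j$hit),
    fn = sum(j$label == "active" & !j$hit)
  )
}

#' Sum confusion counts across targets
#'
#' Field-wise integer sums; the collective counts over all target
#' kinases' test sets. Metrics of the aggregate must be computed from the
#' summed counts, never by averaging per-target metrics.
#'
#' @param per_target Non-empty list of `confusion_counts` (or a tibble of
#'   stacked rows).
#' @return A `confusion_counts` row of the totals.
#' @export
aggregate_counts <- function(per_target) {
  if (is.data.frame(per_target)) per_target <- list(per_target)
  if (!length(per_target)) ph4_abort("ph4_empty_input", "no counts to aggregate")
  all_rows <- bind_rows(per_target)
  confusion_counts(sum(all_rows$tp), sum(all_rows$fp),
                   sum(all_rows$tn), sum(all_rows$fn))
}

metric_names <- c("se", "sp", "ya", "e", "acc", "dr", "f1", "mcc")
metric_digits <- c(se = 3, sp = 3, ya = 3, e = 3, acc = 3, dr = 3, f1 = 4, mcc = 4)

#' Compute the eight-metric validation suite
#'
#' From a confusion-count record with at least one active and one decoy,
#' computes sensitivity `se = tp/(tp+fn)`, specificity `sp = tn/(tn+fp)`,
#' yield of actives (precision) `ya = tp/(tp+fp)`, enrichment
#' `e = ya * N / A` (hit-list active rate over whole-set prevalence),
#' accuracy `acc = (tp+tn)/N`, discrimination ratio `dr = se/sp`, F1
#' score `f1 = 2 tp / (2 tp + fp + fn)` and Matthews correlation
#' coefficient
#' `mcc = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Metrics whose denominator is zero are flagged undefined (`NA`), never
#' silently zero. Values are exact (double) ratios; reporting precision is
#' applied separately by [round_metrics()].
#'
#' @param counts A `confusion_counts` row.
#' @return An object of class `metrics_report`: list with `metrics`
#'   (named numeric, `NA` when undefined), `undefined` (names of flagged
#'   metrics) and `counts`.
#' @examples
#' m <- compute_metrics(confusion_counts(tp = 55, fp = 91, tn = 2223, fn = 18))
#' round_metrics(m)
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  A <- tp + fn; D <- tn + fp; N <- A + D
  if (A < 1L || D < 1L) {
    ph4_abort("ph4_degenerate_test_set",
              "need at least one active (A >= 1) and one decoy (D >= 1)")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- tp / A
  sp <- tn / D
  ya <- safe_div(tp, tp + fp)
  e <- if (is.na(ya)) NA_real_ else ya * N / A
  acc <- (tp + tn) / N
  dr <- if (sp == 0) NA_real_ else se / sp
  # f1 is the harmonic mean of se and ya, so it is undefined whenever ya is
  f1 <- if (tp + fp == 0 || 2 * tp + fp + fn == 0) NA_real_ else {
    2 * tp / (2 * tp + fp + fn)
  }
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mcc_den)
  metrics <- c(se = se, sp = sp, ya = ya, e = e, acc = acc, dr = dr,
               f1 = f1, mcc = mcc)
  structure(
    list(
      metrics = metrics,
      undefined = names(metrics)[is.na(metrics)],
      counts = counts
    ),
    class = "metrics_report"
  )
}

#' Round metrics to reporting precision
#'
#' Half-up rounding at the table precision used throughout the package:
#' 3 decimals for `se`, `sp`, `ya`, `e`, `acc`, `dr`; 4 decimals for `f1`
#' and `mcc`. Undefined metrics stay `NA`.
#'
#' @param m A `metrics_report` or named numeric vector of raw metrics.
#' @return Named numeric vector of rounded metrics.
#' @export
round_metrics <- function(m) {
  v <- if (inherits(m, "metrics_report")) m$metrics else m
  out <- v
  for (nm in intersect(names(v), metric_names)) {
    if (!is.na(v[[nm]])) out[[nm]] <- round_half_up(v[[nm]], metric_digits[[nm]])
  }
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  r <- round_metrics(x)
  cat(sprintf(
    "<metrics_report tp=%d fp=%d tn=%d fn=%d (A=%d, D=%d, N=%d)>\n",
    x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn,
    x$counts$A, x$counts$D, x$counts$N
  ))
  cat(paste(sprintf("%s=%s", names(r),
                    ifelse(is.na(r), "undef", format(r))), collapse = "  "), "\n")
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble with `metric`, `value` (raw), `rounded`, `defined`.
#' @export
tidy.metrics_report <- function(x, ...) {
  r <- round_metrics(x)
  tibble(
    metric = names(x$metrics),
    value = unname(x$metrics),
    rounded = unname(r),
    defined = !is.na(x$metrics)
  )
}

#' One-row summary of a metrics report (rounded)
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble of the rounded metrics plus the counts.
#' @export
glance.metrics_report <- function(x, ...) {
  bind_cols(as_tibble(as.list(round_metrics(x))),
            x$counts[, c("tp", "fp", "tn", "fn")])
}

#' Rank models by a validation metric
#'
#' Descending by `key`; ties broken alphabetically by model name. An
#' undefined (`NA`) key in any row is an error.
#'
#' @param rows Tibble with a `model` column and metric columns (e.g. the
#'   output of stacking [glance.metrics_report()] rows, or
#'   [benchmark_model_metrics()]).
#' @param key Metric column to rank by (e.g. `"mcc"`).
#' @return `rows`, reordered.
#' @export
rank_models <- function(rows, key = "mcc") {
  rows <- as_tibble(rows)
  if (!key %in% names(rows)) {
    ph4_abort("ph4_unknown_metric", paste("no such metric column:", key))
  }
  if (anyNA(rows[[key]])) {
    ph4_abort("ph4_undefined_metric", paste("metric", key, "undefined in some rows"))
  }
  rows[order(-rows[[key]], rows$model), ]
}

#' Back-solve integer confusion counts from rounded metrics
#'
#' Exhaustively searches `tp` in `[0, A]` and hit counts in
#' `[tp, tp + D]` for integer confusion matrices whose exact sensitivity
#' and yield of actives round (half-up, at `digits` decimals) to the
#' printed values. Useful for recovering the raw counts behind a
#' published, rounded metrics row.
#'
#' @param se_printed,ya_printed Printed (rounded) sensitivity and yield of
#'   actives, both in `[0, 1]`.
#' @param A,D Numbers of actives and decoys (>= 1).
#' @param digits Printed precision (decimals).
#' @return Tibble of candidate solutions (`tp`, `fp`, `tn`, `fn`, `hits`),
#'   one row when unique; errors (`ph4_no_solution`) when no integer
#'   solution is consistent.
#' @examples
#' back_solve_counts(0.753, 0.377, A = 73, D = 2314)
#' @export
back_solve_counts <- function(se_printed, ya_printed, A, D, digits = 3) {
  stopifnot(A >= 1, D >= 1,
            se_printed >= 0, se_printed <= 1,
            ya_printed >= 0, ya_printed <= 1)
  tps <- 0:A
  tps <- tps[round_half_up(tps / A, digits) == se_printed]
  sols <- list()
  for (tp in tps) {
    hits <- max(tp, 1L):(tp + D)
    ok <- round_half_up(tp / hits, digits) == ya_printed
    if (tp == 0L && ya_printed == 0) ok <- ok | hits == 0L
    for (h in hits[ok]) {
      fp <- h - tp
      sols[[length(sols) + 1L]] <- tibble(
        tp = tp, fp = fp, tn = D - fp, fn = A - tp, hits = h
      )
    }
  }
  if (!length(sols)) {
    ph4_abort("ph4_no_solution", "no integer confusion matrix matches the rounded metrics")
  }
  bind_rows(sols)
}

#' Find integer confusion matrices reproducing a full printed metrics row
#'
#' For a row of all eight rounded metrics and known test-set totals,
#' searches every `(tp, fp)` pair consistent with the printed sensitivity
#' for counts whose eight computed metrics all round (half-up, at the
#' standard reporting precision) to the printed row.
#'
#' @param row Named list / one-row data frame with `se`, `sp`, `ya`, `e`,
#'   `acc`, `dr`, `f1`, `mcc` (printed values).
#' @param A,D Actives and decoys totals.
#' @return Tibble of consistent counts (`tp`, `fp`, `tn`, `fn`); zero rows
#'   when the printed row is inconsistent.
#' @export
consistent_counts <- function(row, A, D) {
  row <- as.list(row)
  tps <- 0:A
  tps <- tps[round_half_up(tps / A, 3) == row$se]
  grid <- tidyr::expand_grid(tp = tps, fp = 0:D)
  if (!nrow(grid)) return(tibble(tp = integer(), fp = integer(),
                                 tn = integer(), fn = integer()))
  tp <- grid$tp; fp <- grid$fp
  tn <- D - fp; fn <- A - tp
  N <- A + D
  hits <- tp + fp
  se <- tp / A; sp <- tn / D
  ya <- ifelse(hits > 0, tp / hits, NA_real_)
  e <- ya * N / A
  acc <- (tp + tn) / N
  dr <- ifelse(sp > 0, se / sp, NA_real_)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(den > 0, (tp * tn - fp * fn) / sqrt(den), NA_real_)
  ok <- !is.na(ya) & !is.na(dr) & !is.na(f1) & !is.na(mcc) &
    round_half_up(se, 3) == row$se &
    round_half_up(sp, 3) == row$sp &
    round_half_up(ya, 3) == row$ya &
    round_half_up(e, 3) == row$e &
    round_half_up(acc, 3) == row$acc &
    round_half_up(dr, 3) == row$dr &
    round_half_up(f1, 4) == row$f1 &
    round_half_up(mcc, 4) == row$mcc
  tibble(tp = tp[ok], fp = fp[ok], tn = tn[ok], fn = fn[ok])
}

#' Bundled benchmark fixtures
#'
#' `benchmark_model_metrics()` returns the published validation metrics of
#' 17 candidate multi-kinase pharmacophore models (`Ph4-1` ... `Ph4-17`)
#' on a VEGFR-2 / FGFR-1 / BRAF active-decoy test collection;
#' `benchmark_test_sets()` returns that collection's per-target
#' composition (26/801, 20/600, 27/913 actives/decoys; 73 actives and
#' 2314 decoys overall, a decoy:active ratio of about 30).
#'
#' @return A tibble (see above).
#' @export
benchmark_model_metrics <- function() {
  readr::read_csv(
    system.file("extdata", "benchmark_model_metrics.csv", package = "ph4screen"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' @rdname benchmark_model_metrics
#' @export
benchmark_test_sets <- function() {
  readr::read_csv(
    system.file("extdata", "benchmark_test_sets.csv", package = "ph4screen"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Write a metrics table to CSV
#'
#' Mirrors the standard reporting layout: one row per model with the eight
#' rounded metrics.
#'
#' @param rows Tibble with `model` plus metric columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  readr::write_csv(rows, path)
  invisible(path)
}
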