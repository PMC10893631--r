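test_that("test-set compilation validates labels and summarises per target", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "compound_id,target,label",
    "c1,VEGFR2,active", "c2,VEGFR2,decoy", "c3,FGFR1,Active", "c4,BRAF,decoy"
  ), path)
  labs <- read_test_set(path)
  expect_equal(nrow(labs), 4L)
  s <- test_set_summary(labs)
  expect_equal(s$actives[s$target == "VEGFR2"], 1L)
  expect_equal(sum(s$total), 4L)

  writeLines("compound_id,target,label", path)
  expect_error(read_test_set(path), class = "ph4_empty_test_set")

  writeLines(c("compound_id,target,label", "c1,VEGFR2,active",
               "c1,VEGFR2,decoy"), path)
  expect_error(read_test_set(path), class = "ph4_duplicate_label")

  writeLines(c("compound_id,target,label", "c1,VEGFR2,maybe"), path)
  expect_error(read_test_set(path), class = "ph4_bad_label")

  # same compound under two targets is legitimate
  expect_silent(compile_test_set(tibble::tibble(
    compound_id = c("c1", "c1"), target = c("VEGFR2", "BRAF"),
    label = "active"
  )))
})

test_that("confusion counts from a screen partition the labelled set", {
  tg <- small_plant_targets(6L, 20L, 4L, 3L)
  pl <- plant_matched_library(plant_spec(tg, seed = 19L))
  rep <- screen_library(pl$library, pl$query)
  cc <- confusion_from_screen(rep, pl$labels)
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(4L, 3L, 17L, 2L))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, nrow(pl$labels))

  stray <- dplyr::bind_rows(pl$labels, tibble::tibble(
    compound_id = "ghost", target = "KIN1", label = "decoy"
  ))
  expect_error(confusion_from_screen(rep, stray),
               class = "ph4_unscreened_compound", regexp = "ghost")
})

test_that("aggregation is a field-wise integer sum", {
  a <- confusion_counts(10L, 1L, 100L, 2L)
  b <- confusion_counts(5L, 0L, 50L, 1L)
  s <- aggregate_counts(list(a, b))
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(15L, 1L, 150L, 3L))
  expect_equal(aggregate_counts(list(a)), a)
  expect_error(aggregate_counts(list()), class = "ph4_empty_input")

  # a 3-way partition of the benchmark totals re-sums exactly
  parts <- list(confusion_counts(20L, 31L, 770L, 6L),
                confusion_counts(15L, 25L, 575L, 5L),
                confusion_counts(20L, 35L, 878L, 7L))
  tot <- aggregate_counts(parts)
  expect_equal(c(tot$tp, tot$fp, tot$tn, tot$fn), c(55L, 91L, 2223L, 18L))
})

test_that("the eight metrics match closed forms and flag undefined cases", {
  perfect <- compute_metrics(confusion_counts(73L, 0L, 2314L, 0L))
  r <- round_metrics(perfect)
  expect_equal(unname(r[c("se", "sp", "ya", "acc", "f1", "mcc")]),
               rep(1, 6))
  expect_equal(unname(r["e"]), 32.699)  # N / A at 3 decimals

  none <- compute_metrics(confusion_counts(0L, 0L, 100L, 10L))
  expect_equal(unname(none$metrics["se"]), 0)
  expect_equal(unname(none$metrics["sp"]), 1)
  expect_setequal(none$undefined, c("ya", "e", "f1", "mcc"))
  expect_true(all(is.na(none$metrics[c("ya", "e", "f1", "mcc")])))

  expect_error(compute_metrics(confusion_counts(0L, 0L, 0L, 5L)),
               class = "ph4_degenerate_test_set")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(41)
  for (i in 1:200) {
    tp <- sample(1:80, 1); fn <- sample(0:40, 1)
    fp <- sample(1:300, 1); tn <- sample(1:2500, 1)
    m <- compute_metrics(confusion_counts(tp, fp, tn, fn))$metrics
    A <- tp + fn; D <- tn + fp; N <- A + D
    expect_equal(m[["acc"]], (m[["se"]] * A + m[["sp"]] * D) / N,
                 tolerance = 1e-12)
    expect_equal(m[["e"]], m[["ya"]] * N / A, tolerance = 1e-12)
    expect_equal(m[["dr"]], m[["se"]] / m[["sp"]], tolerance = 1e-12)
    if (!is.na(m[["f1"]]) && (m[["se"]] + m[["ya"]]) > 0) {
      expect_equal(m[["f1"]],
                   2 * m[["se"]] * m[["ya"]] / (m[["se"]] + m[["ya"]]),
                   tolerance = 1e-12)
    }
    expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
  }
  # mcc attains 1 exactly for a perfect split with both classes present
  expect_equal(compute_metrics(confusion_counts(5L, 0L, 7L, 0L))$metrics[["mcc"]], 1)
  expect_lt(compute_metrics(confusion_counts(5L, 1L, 7L, 0L))$metrics[["mcc"]], 1)
})

test_that("rounding is half-up at the reporting precision", {
  expect_equal(ph4screen:::round_half_up(0.0005, 3), 0.001)
  expect_equal(ph4screen:::round_half_up(0.75342, 3), 0.753)
  expect_equal(ph4screen:::round_half_up(-0.0005, 3), -0.001)
  expect_equal(ph4screen:::round_half_up(12.3175, 3), 12.318)
  m <- compute_metrics(confusion_counts(55L, 91L, 2223L, 18L))
  expect_equal(unname(round_metrics(m)),
               c(0.753, 0.961, 0.377, 12.318, 0.954, 0.784, 0.5023, 0.5131))
})

test_that("model ranking is descending with alphabetical tie-break", {
  rows <- tibble::tibble(
    model = c("b", "a", "c"),
    mcc = c(0.5, 0.7, 0.5), f1 = c(0.4, 0.6, 0.41)
  )
  ranked <- rank_models(rows, "mcc")
  expect_equal(ranked$model, c("a", "b", "c"))
  expect_equal(rank_models(rows[1, ], "mcc")$model, "b")
  expect_error(rank_models(rows, "auc"), class = "ph4_unknown_metric")
  rows$mcc[2] <- NA
  expect_error(rank_models(rows, "mcc"), class = "ph4_undefined_metric")
})

test_that("back-solving recovers integer counts from rounded metrics", {
  sol <- back_solve_counts(0.753, 0.377, 73, 2314)
  expect_equal(nrow(sol), 1L)
  expect_equal(c(sol$tp, sol$hits, sol$fp, sol$tn, sol$fn),
               c(55, 146, 91, 2223, 18))

  sol17 <- back_solve_counts(0.425, 0.484, 73, 2314)
  expect_equal(c(sol17$tp[1], sol17$hits[1]), c(31, 64))

  triv <- back_solve_counts(1.0, 1.0, 10, 100)
  expect_equal(c(triv$tp[1], triv$hits[1]), c(10, 10))

  expect_error(back_solve_counts(0.5, 1.0, 3, 10), class = "ph4_no_solution")
})

test_that("bundled benchmark fixtures are self-consistent", {
  tbl <- benchmark_model_metrics()
  expect_equal(nrow(tbl), 17L)
  comp <- benchmark_test_sets()
  expect_equal(sum(comp$actives), 73L)
  expect_equal(sum(comp$decoys), 2314L)
  expect_equal(sum(comp$actives + comp$decoys), 2387L)
  # decoy:active ratio of about 30, per target and overall
  expect_true(all(comp$decoys / comp$actives > 25 &
                    comp$decoys / comp$actives < 35))
  expect_equal(sum(comp$decoys) / sum(comp$actives), 30, tolerance = 0.1)
  ranked <- rank_models(tbl, "mcc")
  expect_equal(ranked$model[1], "Ph4-4")
})
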