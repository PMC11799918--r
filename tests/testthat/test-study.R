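mini_study <- function() fixture("mini_study", function() {
  cohort <- generate_cohort(2, seed = 31)
  run_study(cohort, list(rule = rule_observer()),
            scan_geometry(112L, 1.4, 90L, quiet = TRUE),
            acquisition_spec(500), dose_list_mA = c(500, 50),
            seed = 31, grid = grid_def(c(48L, 48L, 48L), 3))
})

test_that("the study report has complete bookkeeping", {
  rep <- mini_study()
  # one delta record per case x dose x metric (8 metrics)
  expect_identical(nrow(rep$deltas), 2L * 2L * 8L)
  expect_identical(nrow(rep$metrics), 2L * 2L)
  # dice rows: case x dose x phase x class
  expect_identical(nrow(rep$dice), 2L * 2L * 2L * 2L)
  expect_null(rep$failures)
})

test_that("standard-dose self-comparison is exactly zero and Dice one", {
  rep <- mini_study()
  sd_rows <- rep$deltas[rep$deltas$dose == 500, ]
  expect_true(all(sd_rows$delta == 0))
  expect_true(all(rep$dice$dice_vs_sd[rep$dice$dose == 500] == 1))
})

test_that("a full study re-run with identical seeds is bitwise identical", {
  rep1 <- mini_study()
  rep2 <- run_study(generate_cohort(2, seed = 31),
                    list(rule = rule_observer()),
                    scan_geometry(112L, 1.4, 90L, quiet = TRUE),
                    acquisition_spec(500), dose_list_mA = c(500, 50),
                    seed = 31, grid = grid_def(c(48L, 48L, 48L), 3))
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$deltas, rep2$deltas)
  expect_identical(rep1$dice, rep2$dice)
})

test_that("delta aggregation reproduces closed-form summaries", {
  d <- data.frame(case = rep(1:4, 2), observer = "o",
                  dose = rep(c(500, 100), each = 4),
                  metric = "ef", delta = c(0, 0, 0, 0, 1, -1, 3, -3))
  rep <- structure(list(deltas = d), class = "study_report")
  s <- aggregate_deltas(rep)
  r100 <- s[s$dose == 100, ]
  expect_equal(r100$mean_delta, 0)
  expect_equal(r100$mean_abs, 2)
  expect_equal(r100$sd_delta, sd(c(1, -1, 3, -3)))
  expect_error(aggregate_deltas(structure(list(deltas = d[0, ]),
                                          class = "study_report")),
               "empty")
})

test_that("P90 uses the linear-interpolation quantile", {
  x <- seq(0.1, 1.0, by = 0.1)
  d <- data.frame(case = 1:10, observer = "o", dose = 100,
                  metric = "ef", delta = x)
  s <- aggregate_deltas(structure(list(deltas = d), class = "study_report"))
  # brute-force: sorted values, h = 0.9*(n-1)+1 = 9.1 -> x9 + 0.1*(x10-x9)
  expect_equal(s$p90_abs, 0.9 + 0.1 * (1.0 - 0.9))
})

test_that("the threshold rule walks the ladder from the top", {
  mk <- function(p90s) {
    do.call(rbind, lapply(names(p90s), function(ds)
      data.frame(observer = "o", dose = as.numeric(ds),
                 metric = c("ef", "gls", "cs_basal"),
                 p90_abs = p90s[[ds]])))
  }
  s <- mk(list("500" = 0, "100" = 0.5, "50" = 1.0, "25" = 3.0, "10" = 8.0))
  expect_identical(find_dose_threshold(s), c(o = "50"))
  s_all <- mk(list("500" = 0, "100" = 0.5, "50" = 1.0, "25" = 1.2,
                   "10" = 2.0))
  expect_identical(find_dose_threshold(s_all), c(o = "10"))
  s_none <- mk(list("500" = 0, "100" = 5, "50" = 6, "25" = 7, "10" = 9))
  expect_identical(find_dose_threshold(s_none), c(o = "standard-only"))
  # the rule is monotone: a failure above blocks lower doses even if they
  # nominally pass
  s_gap <- mk(list("500" = 0, "100" = 5, "50" = 1.0, "25" = 1.0,
                   "10" = 1.0))
  expect_identical(find_dose_threshold(s_gap), c(o = "standard-only"))
  expect_error(find_dose_threshold(s, tolerances = c()), "empty tolerance")
})

test_that("exported reports round-trip through CSV", {
  rep <- mini_study()
  out <- file.path(tempdir(), "lvdose-study-test")
  paths <- export_report(rep, out)
  expect_true(all(file.exists(paths)))
  metrics2 <- read.csv(paths["metrics"])
  expect_equal(metrics2$ef, rep$metrics$ef)
  deltas2 <- read.csv(paths["deltas"])
  expect_equal(deltas2$delta, rep$deltas$delta)
  expect_identical(nrow(read.csv(paths["summary"])),
                   nrow(aggregate_deltas(rep)))
  manifest <- jsonlite::read_json(paths["manifest"])
  expect_identical(manifest$seed, 31L)
  expect_identical(manifest$n_cases, 2L)
  expect_false(is.null(manifest$detected_threshold_mA))
  unlink(out, recursive = TRUE)
})
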