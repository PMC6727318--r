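# end-to-end pipeline tests use a scaled-down phantom (coarser spacing,
# smaller anatomy) so the suite stays fast; the stated-world sizes are
# exercised in test-acceptance.R

shared_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_case(small_phantom_spec(), perturbation_spec(),
                          small_beams(), case_id = "ident")
    cache
  }
})

test_that("identity case passes the full checklist", {
  rep <- run_case_qa(shared_case(), qa_tolerances(resample_mm = 3))
  expect_true(rep$overall_pass)
  expect_length(rep$checklist, 9L)
  expect_equal(vapply(rep$checklist, function(r) r$label, character(1)),
               c(planqa:::MANUAL_CHECKLIST_ITEMS,
                 planqa:::AUTOMATED_CHECKLIST_ITEMS),
               ignore_attr = TRUE)
  expect_equal(rep$iso_check$diff_pct, 0, tolerance = 1e-9)
  expect_equal(rep$gamma_results[["2%/2mm"]]$pass_rate_pct, 100.0)
  expect_equal(rep$fiducial_result$max_abs_diff_mm, 0)
})

test_that("one failed manual flag blocks the overall pass", {
  bundle <- shared_case()
  bundle$manual_flags[["Femoral heads"]] <- FALSE
  rep <- run_case_qa(bundle, qa_tolerances(resample_mm = 3))
  expect_false(rep$overall_pass)
  expect_equal(rep$checklist[["Femoral heads"]]$status, "fail")
  expect_equal(rep$checklist[["Dose at isocenter"]]$status, "pass")

  bundle$manual_flags[["Femoral heads"]] <- NA
  rep2 <- run_case_qa(bundle, qa_tolerances(resample_mm = 3))
  expect_false(rep2$overall_pass)
  expect_equal(rep2$checklist[["Femoral heads"]]$status, "not_assessed")
})

test_that("a +3% uniform dose error fails the isocenter row", {
  bundle <- shared_case()
  bundle$eval_dose$grid$values <- bundle$eval_dose$grid$values * 1.03
  rep <- run_case_qa(bundle, qa_tolerances(resample_mm = 3))
  expect_false(rep$overall_pass)
  expect_equal(rep$checklist[["Dose at isocenter"]]$status, "fail")
  expect_equal(rep$iso_check$diff_pct, 3, tolerance = 1e-6)
})

test_that("reports are deterministic and survive JSON round trips", {
  rep <- run_case_qa(shared_case(), qa_tolerances(resample_mm = 3))
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_report(rep, p1, "json")
  write_report(rep, p2, "json")
  expect_identical(readLines(p1), readLines(p2))
  back <- read_report(p1)
  expect_true(back$overall_pass)
  expect_equal(back$iso_check$diff_pct, rep$iso_check$diff_pct)

  txt <- tempfile(fileext = ".txt")
  write_report(rep, txt, "text")
  lines <- readLines(txt)
  expect_true(any(grepl("Dose at isocenter", lines)))
  expect_true(any(grepl("✓", lines)))
})

test_that("pipeline failures are reported, not thrown", {
  bundle <- shared_case()
  # an all-air CT makes the body-mask stage fail inside the pipeline
  bundle$ct$values[] <- -1000
  expect_no_error(rep <- run_case_qa(bundle, qa_tolerances(resample_mm = 3)))
  expect_false(rep$overall_pass)
  expect_equal(rep$checklist[["Dose at isocenter"]]$status, "fail")
  expect_match(rep$errors$dose_comparison, "empty body mask")
})

test_that("cohort summaries implement the standard formulas", {
  s <- summarize_cohort(c(-1, 1), "toy")
  expect_equal(s$mean, 0)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$loa_high, 1.96 * sqrt(2))
  expect_equal(s$loa_low, -1.96 * sqrt(2))

  s2 <- summarize_cohort(rep(4.2, 5))
  expect_equal(s2$sd, 0)
  expect_equal(s2$loa_low, 4.2)
  expect_equal(s2$loa_high, 4.2)
  expect_error(summarize_cohort(1), "n >= 2")

  # rms^2 = mean^2 + ((n-1)/n) sd^2, exactly
  set.seed(13)
  for (n in c(2, 7, 100)) {
    x <- rnorm(n, 1, 3)
    s3 <- summarize_cohort(x)
    expect_equal(s3$rms^2, s3$mean^2 + (n - 1) / n * s3$sd^2,
                 tolerance = 1e-12)
  }
})

test_that("cohort aggregation over reports produces one row per metric", {
  r1 <- run_case_qa(shared_case(), qa_tolerances(resample_mm = 3))
  b2 <- shared_case()
  b2$eval_dose$grid$values <- b2$eval_dose$grid$values * 1.01
  r2 <- run_case_qa(b2, qa_tolerances(resample_mm = 3))
  df <- summarize_cohort_reports(list(r1, r2))
  expect_true("isocenter dose difference (%)" %in% df$metric)
  expect_true(any(grepl("gamma pass-rate", df$metric)))
  iso_row <- df[df$metric == "isocenter dose difference (%)", ]
  expect_equal(iso_row$n, 2)
  expect_equal(iso_row$mean, mean(c(r1$iso_check$diff_pct,
                                    r2$iso_check$diff_pct)))
})
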