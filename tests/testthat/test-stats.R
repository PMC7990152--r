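test_that("paired records are assembled from the four raw volumes", {
  expect_warning(recs <- build_records(load_graft_volumes()),
                 "8606")
  expect_identical(nrow(recs), 9L)
  r <- recs[recs$patient_id == "8096", ]
  expect_equal(r$V0_ib, 159)
  expect_equal(r$change_ib, 27)
  expect_equal(r$change_c, -175)
  expect_equal(r$pct_c, -100)
  expect_equal(r$paired_diff, 202)
  expect_equal(r$pct_ib, 100 * 27 / 159) # unrounded internally
  # invariant: paired_diff identity holds exactly for all patients
  expect_identical(recs$paired_diff, recs$change_ib - recs$change_c)
  # zero baseline volume -> percent undefined
  bad <- load_graft_volumes()
  bad$volume_mm3[bad$patient_id == "8096" &
                   bad$timepoint == "baseline"] <- 0
  expect_error(suppressWarnings(build_records(bad)), "zero")
})

test_that("group summary reproduces the trial's descriptive statistics", {
  recs <- suppressWarnings(build_records(load_graft_volumes()))
  s <- summarize_records(recs)
  expect_identical(s$n, 9L)
  # volume means/SDs (population denominator), frozen from direct
  # recomputation on the printed volumes
  expect_equal(round(s$baseline_ib[["mean"]]), 337)
  expect_equal(round(s$baseline_ib[["sd"]]), 139)
  expect_equal(round(s$followup_ib[["mean"]]), 446)
  expect_equal(round(s$followup_ib[["sd"]]), 172)
  expect_equal(round(s$baseline_c[["mean"]]), 309)
  expect_equal(round(s$baseline_c[["sd"]]), 159)
  expect_equal(round(s$followup_c[["mean"]]), 164)
  expect_equal(round(s$followup_c[["sd"]]), 204)
  expect_equal(s$change_ib[["mean"]], 977 / 9)
  expect_equal(s$change_c[["mean"]], -1311 / 9, tolerance = 1e-12)
  expect_equal(s$paired_diff[["mean"]], 2288 / 9)
  expect_equal(s$pct_ib[["mean"]], 35.46527, tolerance = 1e-6)
  expect_equal(s$pct_c[["mean"]], -58.50464, tolerance = 1e-6)
  # interval invariants
  expect_true(s$dispersion_interval[1] < s$paired_diff[["mean"]])
  expect_true(s$t_confidence_interval[2] > s$paired_diff[["mean"]])
  expect_lte(s$paired_diff[["sd"]], s$paired_diff[["sd_sample"]])
  expect_identical(s$df, 8)
  # degenerate summaries
  expect_error(summarize_records(recs[1, , drop = FALSE]), "2 patients")
  same <- recs
  same$paired_diff <- 100
  expect_error(summarize_records(same), "zero variance")
})

test_that("the paired t test matches the reference implementation", {
  set.seed(81)
  for (i in 1:25) {
    x <- rnorm(sample(3:15, 1), sample(-50:50, 1), runif(1, 1, 40))
    mine <- paired_t_test(x)
    ref <- t.test(x)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
    expect_lt(abs(mine$p - ref$p.value), 1e-6)
  }
  expect_error(paired_t_test(rep(5, 4)), "variance")
  expect_error(paired_t_test(3), "at least 2")
  null_case <- paired_t_test(c(-1, 1))
  expect_equal(null_case$t, 0)
  expect_equal(null_case$p, 1)
})

test_that("effect size uses the population-SD convention", {
  expect_equal(cohens_d_paired(c(-1, 1)), 0)
  expect_error(cohens_d_paired(c(3, 3)), "variance")
  set.seed(82)
  x <- rnorm(9, 20, 10)
  expect_equal(cohens_d_paired(x),
               mean(x) / sqrt(mean((x - mean(x))^2)))
})

test_that("report rendering applies presentation rounding only", {
  recs <- suppressWarnings(build_records(load_graft_volumes()))
  rep <- render_report(recs)
  expect_identical(rep$table$pct_ib[rep$table$patient_id == "8096"], 17)
  expect_identical(rep$summary$mean_paired_diff, 254)
  expect_identical(rep$summary$cohens_d, round(rep$summary$cohens_d, 2))
  expect_identical(rep$summary$p_paired_diff,
                   round(rep$summary$p_paired_diff, 5))
  js <- jsonlite::fromJSON(render_report(recs, format = "json"))
  expect_equal(js$records$paired_diff, rep$table$paired_diff)
  csv <- read.csv(text = render_report(recs, format = "csv"))
  expect_equal(csv$paired_diff, rep$table$paired_diff)
  expect_error(render_report(recs[0, ]), "no records")
})
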