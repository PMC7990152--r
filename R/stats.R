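#' Population and sample standard deviation
#'
#' `sd_population` uses the n denominator, `sd_sample` the usual n-1. The
#' trial's descriptive SDs and Cohen's d follow the population convention,
#' while the paired t statistic uses the sample convention; both are
#' exported so the choice is auditable.
#'
#' @param x numeric vector.
#' @return scalar SD.
#' @export
sd_population <- function(x) sqrt(mean((x - mean(x))^2))

#' @rdname sd_population
#' @export
sd_sample <- function(x) stats::sd(x)

#' Build paired per-patient records from a measurement table
#'
#' Joins the four volumes of each patient (treated/control side at
#' baseline/6 months) into one record with changes, percent changes and the
#' paired difference `change_treated - change_control`. Patients lacking
#' any of the four volumes (e.g. a reoperated patient with no follow-up
#' scans) are excluded with a warning naming them. Percents are kept
#' unrounded; presentation rounding happens only in [render_report()]. A
#' zero baseline volume makes the percent change undefined and is an
#' error.
#'
#' @param table a validated measurement table (see [read_measurements()]).
#' @return `data.frame` with one row per complete patient: `patient_id`,
#'   `treated_side`, `V0_ib`, `V6_ib`, `V0_c`, `V6_c`, `change_ib`,
#'   `change_c`, `pct_ib`, `pct_c`, `paired_diff` (ib = ibandronate-treated
#'   side, c = internal control side; volumes in mm^3).
#' @export
build_records <- function(table) {
  table <- validate_measurements(table)
  if (nrow(table) == 0L) stop("measurement table is empty")
  ids <- unique(table$patient_id)
  recs <- list()
  dropped <- character()
  for (id in ids) {
    sub <- table[table$patient_id == id, ]
    treated <- sub$treated_side[1]
    control <- setdiff(c("Dx", "Sin"), treated)
    pick <- function(side, tp) {
      v <- sub$volume_mm3[sub$side == side & sub$timepoint == tp]
      if (length(v) == 1L) v else NA_real_
    }
    v <- c(V0_ib = pick(treated, "baseline"), V6_ib = pick(treated, "6mo"),
           V0_c = pick(control, "baseline"), V6_c = pick(control, "6mo"))
    if (anyNA(v)) {
      dropped <- c(dropped, id)
      next
    }
    if (v[["V0_ib"]] == 0 || v[["V0_c"]] == 0)
      stop("baseline volume of patient ", id,
           " is zero: percent change undefined")
    recs[[id]] <- data.frame(
      patient_id = id, treated_side = treated,
      V0_ib = v[["V0_ib"]], V6_ib = v[["V6_ib"]],
      V0_c = v[["V0_c"]], V6_c = v[["V6_c"]],
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("excluded patients with incomplete volumes: ",
            paste(dropped, collapse = ", "))
  if (!length(recs)) stop("no patient has all four volumes")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$change_ib <- out$V6_ib - out$V0_ib
  out$change_c <- out$V6_c - out$V0_c
  out$pct_ib <- 100 * out$change_ib / out$V0_ib
  out$pct_c <- 100 * out$change_c / out$V0_c
  out$paired_diff <- out$change_ib - out$change_c
  out
}

#' Paired t test on the within-patient differences
#'
#' `t = mean(diffs) / (sd_sample(diffs) / sqrt(n))`, df = n - 1, two-sided
#' p from the Student t distribution. All differences equal (zero sample
#' SD) is an error.
#'
#' @param diffs numeric vector of paired differences (mm^3).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_test <- function(diffs) {
  n <- length(diffs)
  if (n < 2) stop("need at least 2 paired differences")
  s <- sd_sample(diffs)
  if (s == 0) stop("zero variance: t statistic undefined")
  t <- mean(diffs) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Cohen's d for paired data
#'
#' `d = mean(diffs) / sd_population(diffs)` (population denominator, the
#' convention under which the trial's printed effect size reproduces).
#'
#' @param diffs numeric vector of paired differences.
#' @return scalar effect size.
#' @export
cohens_d_paired <- function(diffs) {
  if (length(diffs) < 2) stop("need at least 2 paired differences")
  s <- sd_population(diffs)
  if (s == 0) stop("zero variance: effect size undefined")
  mean(diffs) / s
}

#' Group summary of the paired internal-control analysis
#'
#' Means and SDs of baseline/6-month volumes, changes, percent changes and
#' paired differences; the paired t test; Cohen's d; and two intervals
#' around the mean paired difference: the dispersion interval
#' `mean +/- 2 sd_population` (the convention under which the trial's
#' published interval reproduces -- reported as a descriptive dispersion
#' interval, not a standard CI) and the conventional t-based 95% CI
#' `mean +/- t(0.975, df) sd_sample / sqrt(n)`. Descriptive SDs use the
#' population (n) denominator by default; sample-denominator versions are
#' included under `*_sample` names so the convention is auditable. The
#' group percent change is the mean of the per-patient percents.
#'
#' @param records output of [build_records()] (n >= 2).
#' @return a `group_summary` list.
#' @export
summarize_records <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("need records for at least 2 patients")
  d <- records$paired_diff
  tt <- paired_t_test(d)
  msd <- function(x) c(mean = mean(x), sd = sd_population(x),
                       sd_sample = sd_sample(x))
  gains <- records$change_ib[records$change_ib > 0]
  out <- list(
    n = n,
    baseline_ib = msd(records$V0_ib), followup_ib = msd(records$V6_ib),
    baseline_c = msd(records$V0_c), followup_c = msd(records$V6_c),
    change_ib = msd(records$change_ib), change_c = msd(records$change_c),
    pct_ib = msd(records$pct_ib), pct_c = msd(records$pct_c),
    paired_diff = msd(d),
    t = tt$t, df = tt$df, p = tt$p,
    cohens_d = cohens_d_paired(d),
    dispersion_interval = mean(d) + c(-2, 2) * sd_population(d),
    t_confidence_interval = mean(d) + c(-1, 1) *
      stats::qt(0.975, tt$df) * sd_sample(d) / sqrt(n),
    # paired t of the 6-month volumes themselves (treated vs control side)
    followup_volume_test = paired_t_test(records$V6_ib - records$V6_c),
    gainers = list(n = length(gains),
                   mean_gain = if (length(gains)) mean(gains) else NA_real_,
                   range = if (length(gains)) range(gains)
                           else c(NA_real_, NA_real_)),
    control_change_range = range(records$change_c))
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Paired internal-control summary (n = %d patients)\n", x$n))
  cat(sprintf("  treated:  change %+.0f +/- %.0f mm^3 (%+.0f%% of baseline)\n",
              x$change_ib[["mean"]], x$change_ib[["sd"]],
              x$pct_ib[["mean"]]))
  cat(sprintf("  control:  change %+.0f +/- %.0f mm^3 (%+.0f%% of baseline)\n",
              x$change_c[["mean"]], x$change_c[["sd"]], x$pct_c[["mean"]]))
  cat(sprintf("  paired difference: %.0f +/- %.0f mm^3; t(%d) = %.2f, p = %.5f\n",
              x$paired_diff[["mean"]], x$paired_diff[["sd"]], x$df, x$t,
              x$p))
  cat(sprintf("  Cohen's d = %.2f; dispersion interval %.0f-%.0f mm^3; 95%% CI %.0f-%.0f mm^3\n",
              x$cohens_d, x$dispersion_interval[1], x$dispersion_interval[2],
              x$t_confidence_interval[1], x$t_confidence_interval[2]))
  invisible(x)
}

#' Render the per-patient table and group summary
#'
#' Applies the presentation rounding used for reporting: volumes and
#' changes to whole mm^3, percents to whole percent, Cohen's d to 2
#' decimals, p values to 5 decimals. Internals stay unrounded; this is the
#' only layer that rounds.
#'
#' @param records output of [build_records()].
#' @param summary output of [summarize_records()] (computed if missing).
#' @param format `"data.frame"`, `"json"` or `"csv"` (the latter two return
#'   a character scalar).
#' @return rounded per-patient table plus summary, in the requested format.
#' @export
render_report <- function(records, summary = NULL,
                          format = c("data.frame", "json", "csv")) {
  format <- match.arg(format)
  if (is.null(nrow(records)) || nrow(records) == 0L)
    stop("no records to render")
  if (is.null(summary)) summary <- summarize_records(records)
  tab <- data.frame(
    patient_id = records$patient_id, treated_side = records$treated_side,
    V0_ib = round(records$V0_ib), V6_ib = round(records$V6_ib),
    V0_c = round(records$V0_c), V6_c = round(records$V6_c),
    change_ib = round(records$change_ib), pct_ib = round(records$pct_ib),
    change_c = round(records$change_c), pct_c = round(records$pct_c),
    paired_diff = round(records$paired_diff), stringsAsFactors = FALSE)
  summ <- list(
    n = summary$n,
    mean_baseline_ib = round(summary$baseline_ib[["mean"]]),
    sd_baseline_ib = round(summary$baseline_ib[["sd"]]),
    mean_followup_ib = round(summary$followup_ib[["mean"]]),
    sd_followup_ib = round(summary$followup_ib[["sd"]]),
    mean_baseline_c = round(summary$baseline_c[["mean"]]),
    sd_baseline_c = round(summary$baseline_c[["sd"]]),
    mean_followup_c = round(summary$followup_c[["mean"]]),
    sd_followup_c = round(summary$followup_c[["sd"]]),
    mean_change_ib = round(summary$change_ib[["mean"]]),
    sd_change_ib = round(summary$change_ib[["sd"]]),
    mean_pct_ib = round(summary$pct_ib[["mean"]]),
    mean_change_c = round(summary$change_c[["mean"]]),
    sd_change_c = round(summary$change_c[["sd"]]),
    mean_pct_c = round(summary$pct_c[["mean"]]),
    mean_paired_diff = round(summary$paired_diff[["mean"]]),
    sd_paired_diff = round(summary$paired_diff[["sd"]]),
    cohens_d = round(summary$cohens_d, 2),
    p_paired_diff = round(summary$p, 5),
    p_followup_volumes = round(summary$followup_volume_test$p, 5),
    dispersion_interval = round(summary$dispersion_interval),
    t_confidence_interval = round(summary$t_confidence_interval),
    conventions = list(
      descriptive_sd = "population (n denominator)",
      t_test_sd = "sample (n-1 denominator)",
      group_percent = "mean of per-patient percents",
      dispersion_interval = "mean +/- 2 population SD (as published)",
      t_confidence_interval = "mean +/- t(0.975, df) sample SD / sqrt(n)"))
  if (format == "data.frame")
    return(list(table = tab, summary = summ))
  if (format == "json")
    return(jsonlite::toJSON(list(records = tab, summary = summ),
                            auto_unbox = TRUE, digits = NA, pretty = TRUE))
  paste(utils::capture.output(utils::write.csv(tab, row.names = FALSE)),
        collapse = "\n")
}
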