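#!/usr/bin/env Rscript

# Thin command-line wrapper over the graftquant package.
#
#   Rscript scripts/graftquant.R simulate --out DIR [--seed N] [--fraction F]
#   Rscript scripts/graftquant.R register FIXED MOVING --out transform.json
#   Rscript scripts/graftquant.R segment VOLUME --out mask.mha [--roi MASK]
#       [--low 300] [--high 600] [--curvature 0.6] [--report report.json]
#   Rscript scripts/graftquant.R measure SEG --out components.json
#       [--roi ROI] [--connectivity 26]
#   Rscript scripts/graftquant.R stats MEASUREMENTS.csv --out report.json
#   Rscript scripts/graftquant.R run --config config.yaml
#
# Every subcommand delegates to the exported package functions.

suppressPackageStartupMessages(library(graftquant))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: graftquant.R <simulate|register|segment|measure|stats|run> ...")
cmd <- args[1L]
args <- args[-1L]

take_opt <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (length(i) == 0L) return(list(value = default, args = args))
  list(value = args[i + 1L], args = args[-c(i, i + 1L)])
}
positional <- function(args) args[!grepl("^--", args) &
                                   !seq_along(args) %in%
                                     (which(grepl("^--", args)) + 1L)]

if (cmd == "simulate") {
  o <- take_opt(args, "out"); out <- o$value; args <- o$args
  o <- take_opt(args, "seed", "1"); seed <- as.integer(o$value); args <- o$args
  o <- take_opt(args, "fraction", "0.5"); frac <- as.numeric(o$value)
  if (is.null(out)) stop("simulate needs --out DIR")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_spec(followup_volume_fraction = frac, seed = seed)
  pair <- generate_pair(spec)
  write_volume(pair$baseline, file.path(out, "baseline.mha"))
  write_volume(pair$followup, file.path(out, "followup.mha"))
  write_mask(pair$roi, file.path(out, "roi.mha"))
  jsonlite::write_json(list(
    graft_volume_baseline = pair$truth$graft_volume_baseline,
    graft_volume_followup = pair$truth$graft_volume_followup,
    applied_rotation_deg = spec$misalignment$rotation_deg,
    applied_translation_mm = spec$misalignment$translation_mm,
    followup_volume_fraction = frac, seed = seed),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  cat("wrote phantom pair to", out, "\n")
} else if (cmd == "register") {
  o <- take_opt(args, "out"); out <- o$value; args <- o$args
  o <- take_opt(args, "init"); init <- o$value; args <- o$args
  pos <- positional(args)
  if (length(pos) != 2L || is.null(out))
    stop("register needs FIXED MOVING --out FILE")
  fixed <- normalize_intensity(read_volume(pos[1]))
  moving <- normalize_intensity(read_volume(pos[2]))
  init_tr <- if (is.null(init)) rigid_transform() else read_transform(init)
  reg <- register_rigid(moving, fixed, init = init_tr)
  write_transform(reg$transform, out)
  cat(sprintf("loss %.4g -> %.4g; wrote %s\n", reg$loss_init,
              reg$loss_final, out))
} else if (cmd == "segment") {
  o <- take_opt(args, "out"); out <- o$value; args <- o$args
  o <- take_opt(args, "roi"); roi <- o$value; args <- o$args
  o <- take_opt(args, "low", "300"); low <- as.numeric(o$value); args <- o$args
  o <- take_opt(args, "high", "600"); high <- as.numeric(o$value); args <- o$args
  o <- take_opt(args, "curvature", "0.6"); cw <- as.numeric(o$value)
  args <- o$args
  o <- take_opt(args, "report"); report <- o$value; args <- o$args
  pos <- positional(args)
  if (length(pos) != 1L || is.null(out))
    stop("segment needs VOLUME --out MASK")
  vol <- read_volume(pos[1])
  if (!identical(vol$unit_state, "normalized"))
    vol <- normalize_intensity(vol)
  roi_mask <- if (is.null(roi)) NULL else read_mask(roi)
  seg <- segment_bone(vol, roi_mask,
                      level_set_params(low = low, high = high,
                                       curvature_weight = cw))
  write_mask(seg$mask, out)
  if (!is.null(report))
    jsonlite::write_json(seg$report, report, auto_unbox = TRUE, digits = NA)
  cat("segmentation:", sum(seg$mask$values), "voxels;",
      seg$report$iterations, "iterations\n")
} else if (cmd == "measure") {
  o <- take_opt(args, "out"); out <- o$value; args <- o$args
  o <- take_opt(args, "roi"); roi <- o$value; args <- o$args
  o <- take_opt(args, "connectivity", "26"); conn <- as.integer(o$value)
  args <- o$args
  pos <- positional(args)
  if (length(pos) != 1L || is.null(out))
    stop("measure needs SEG --out FILE")
  seg <- read_mask(pos[1])
  roi_mask <- if (is.null(roi)) NULL else read_mask(roi)
  res <- largest_component_within(seg, roi_mask, conn)
  jsonlite::write_json(list(volume_mm3 = measure_volume(res$mask),
                            components = res$report),
                       out, auto_unbox = TRUE, digits = NA)
  cat(sprintf("largest component: %.2f mm^3; wrote %s\n",
              measure_volume(res$mask), out))
} else if (cmd == "stats") {
  o <- take_opt(args, "out"); out <- o$value; args <- o$args
  o <- take_opt(args, "table"); table_out <- o$value; args <- o$args
  pos <- positional(args)
  if (length(pos) != 1L) stop("stats needs MEASUREMENTS.csv")
  records <- build_records(read_measurements(pos[1]))
  summ <- summarize_records(records)
  print(summ)
  if (!is.null(out))
    writeLines(render_report(records, summ, format = "json"), out)
  if (!is.null(table_out))
    writeLines(render_report(records, summ, format = "csv"), table_out)
} else if (cmd == "run") {
  o <- take_opt(args, "config"); cfg <- o$value
  if (is.null(cfg)) stop("run needs --config FILE")
  res <- run_side(read_run_config(cfg))
  cat(sprintf("baseline %.1f mm^3, follow-up %.1f mm^3, change %+.1f mm^3 (%+.1f%%)\n",
              res$volume_baseline, res$volume_followup, res$change,
              res$pct_change))
} else {
  stop("unknown subcommand: ", cmd)
}
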