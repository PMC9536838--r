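#' Assemble a study-level report from pipeline outputs
#'
#' Reads a study directory (`droplets.csv` and `samples.csv`, as produced
#' by [write_study()] or by the individual pipeline steps), runs
#' quantification, copy-number and — when deletion/wild-type targets are
#' present — heteroplasmy analysis, aggregates every measure as a
#' superplot over biological replicates, and runs the conventional tests:
#' an unpaired two-tailed t test on per-cell copy number between the
#' earliest and latest stage, and a paired two-tailed t test on
#' heteroplasmy between stages (stages always derive from the same adult
#' populations in these designs). Results are written as one
#' machine-readable JSON plus per-table CSVs; the output is a pure
#' function of the inputs, so re-running on identical inputs yields
#' byte-identical JSON.
#'
#' @param study_dir directory containing `droplets.csv` and `samples.csv`.
#' @param out_dir output directory (default `file.path(study_dir,
#'   "report")`).
#' @param ploidy scalar or named-by-sample ploidy for copy-number math.
#' @param mean_nuclei optional named-by-stage average nuclei counts for
#'   per-germline totals.
#' @return the report, invisibly (a list mirroring the JSON).
#' @export
build_report <- function(study_dir, out_dir = file.path(study_dir, "report"),
                         ploidy = 4, mean_nuclei = NULL) {
  dpath <- file.path(study_dir, "droplets.csv")
  spath <- file.path(study_dir, "samples.csv")
  for (p in c(dpath, spath))
    if (!file.exists(p))
      stop("missing pipeline input: ", p,
           " — run the simulate/quantify steps first")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  droplets <- read_droplet_table(dpath)
  samples <- read.csv(spath, stringsAsFactors = FALSE)
  report <- list()

  if (nrow(samples) == 0 || nrow(droplets) == 0) {
    report$status <- "no samples"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report$status <- "ok"
  report$n_samples <- nrow(samples)

  quant <- quantify_droplet_table(droplets)
  write_quant_table(quant, file.path(out_dir, "quantification.csv"))

  stage_order <- intersect(.pgc_stages, unique(samples$stage))

  # --- copy number ---------------------------------------------------------
  cn <- copy_number_results(quant, samples, ploidy = ploidy,
                            mean_nuclei = mean_nuclei)
  write.csv(cn, file.path(out_dir, "copy_number.csv"), row.names = FALSE)
  sp <- aggregate_superplot(data.frame(
    value = cn$mt_per_cell, technical_rep = "merged",
    biological_rep = cn$biological_rep, group = cn$stage))
  report$copy_number <- lapply(split(sp$summary, sp$summary$group),
                               function(g) list(mean = g$mean_of_means,
                                                sem = g$sem,
                                                n_bio = g$n_bio))
  if (length(stage_order) >= 2) {
    first <- stage_order[1]; last <- stage_order[length(stage_order)]
    prop <- proportion_inherited(
      report$copy_number[[last]]$mean, report$copy_number[[first]]$mean)
    report$proportion_inherited <- list(
      descendant = last, ancestor = first,
      percent = prop$percent, percent_rounded = prop$percent_rounded)
    tt <- t_test(sp$bio_means$mean[sp$bio_means$group == first],
                 sp$bio_means$mean[sp$bio_means$group == last],
                 paired = FALSE)
    report$copy_number_test <- list(
      comparison = paste(first, "vs", last), type = "unpaired two-tailed t",
      statistic = unname(tt$statistic), p_value = tt$p.value)
  }

  # --- heteroplasmy --------------------------------------------------------
  if (all(c("del", "wt") %in% quant$target)) {
    het <- heteroplasmy_results(quant, samples)
    write.csv(het, file.path(out_dir, "heteroplasmy.csv"),
              row.names = FALSE)
    report$heteroplasmy <- lapply(
      split(het, het$stage),
      function(g) list(mean = mean(g$percent),
                       sem = if (nrow(g) >= 2)
                         sd(g$percent) / sqrt(nrow(g)) else NA,
                       n_bio = nrow(g)))
    if (length(stage_order) >= 2) {
      first <- stage_order[1]; last <- stage_order[length(stage_order)]
      sh <- heteroplasmy_shift(het[het$stage == first, ],
                               het[het$stage == last, ])
      write.csv(sh$shifts, file.path(out_dir, "heteroplasmy_shifts.csv"),
                row.names = FALSE)
      tt <- t_test(sh$shifts$early_percent, sh$shifts$late_percent,
                   paired = TRUE)
      report$heteroplasmy_shift <- list(
        early = first, late = last, mean_shift = sh$mean_shift,
        sem = sh$sem, paired_t_statistic = unname(tt$statistic),
        p_value = tt$p.value)
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
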