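#' Turn a lysate table into triplicate droplet wells
#'
#' Generates `n_technical` synthetic ddPCR wells per target from the
#' concentrations in a [build_lysate()] table. When `auto_dilute` is set,
#' each target is first diluted with [tune_dilution()] so its droplet
#' occupancy is quantifiable, mirroring the per-sample-type dilutions used
#' at the bench.
#'
#' @param lysate a data frame from [build_lysate()].
#' @param sample_id,biological_rep identifiers stamped on every well.
#' @param n_technical wells per target (assays are conventionally run in
#'   triplicate).
#' @param n_droplets,droplet_volume_nl droplet generator constants.
#' @param targets subset of targets to assay (default: all with non-`NA`
#'   concentration).
#' @param auto_dilute tune each target's dilution into quantifiable range.
#' @return a droplet-table data frame (see [generate_droplet_assay()]).
#' @export
droplets_from_lysate <- function(lysate, sample_id = "S1",
                                 biological_rep = "b1", n_technical = 3,
                                 n_droplets = 20000,
                                 droplet_volume_nl = 0.85,
                                 targets = NULL, auto_dilute = TRUE) {
  if (is.null(targets)) targets <- lysate$target
  rows <- list()
  for (tg in targets) {
    i <- match(tg, lysate$target)
    if (is.na(i)) stop("target not present in lysate: ", tg)
    dil <- lysate$dilution_factor[i]
    conc <- lysate$concentration[i]
    if (auto_dilute) {
      dil <- tune_dilution(lysate$concentration_undiluted[i],
                           droplet_volume_nl)
      conc <- lysate$concentration_undiluted[i] / dil
    }
    for (t in seq_len(n_technical)) {
      rows[[length(rows) + 1]] <- generate_droplet_assay(
        conc, n_droplets, droplet_volume_nl, dilution_factor = dil,
        target = tg, sample_id = sample_id,
        well_id = sprintf("%s_%s_t%d", sample_id, tg, t),
        technical_rep = paste0("t", t), biological_rep = biological_rep)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a sorted-cell copy-number study with known truth
#'
#' Generates one biological sample of `n_cells` cells whose per-cell totals
#' are Poisson around `mean_mt` (split binomially into deletion and
#' wild-type classes at heteroplasmy `h`), sorts them into lysis buffer,
#' and reads out triplicate droplet wells for the total-mtDNA and nuclear
#' targets (plus the deletion/wild-type pair when `h > 0`). The lysate
#' volume defaults to a value scaled with cell number so the nuclear assay
#' lands at the droplet occupancy achieved by published sorts of 20,000
#' cells into 500 microliters.
#'
#' @param seed RNG seed for this study.
#' @param n_cells cells sorted.
#' @param mean_mt true mean mtDNA copies per cell.
#' @param h true deletion heteroplasmy fraction.
#' @param ploidy nuclear genome copies per cell.
#' @param lysate_volume microliters of lysis buffer.
#' @param gdna_efficiency nuclear-assay detection efficiency.
#' @param sample_id,biological_rep,stage,genotype metadata for the sample
#'   table.
#' @param n_technical,n_droplets,droplet_volume_nl droplet plumbing.
#' @return list with `droplets` (droplet table), `samples` (one-row
#'   metadata: `sample_id`, `stage`, `genotype`, `cells_sorted`,
#'   `biological_rep`) and `truth` (realized `mt_total`, `gdna_total`,
#'   `mean_mt_per_cell`, `heteroplasmy_percent`).
#' @export
#' @examples
#' st <- simulate_copy_number_study(seed = 1, n_cells = 500)
#' head(st$droplets)
simulate_copy_number_study <- function(seed, n_cells = 5000, mean_mt = 200,
                                       h = 0, ploidy = 4,
                                       lysate_volume = n_cells * ploidy / 160,
                                       gdna_efficiency = 1,
                                       sample_id = "S1",
                                       biological_rep = "b1",
                                       stage = "L1_PGC",
                                       genotype = "wild_type",
                                       n_technical = 3, n_droplets = 20000,
                                       droplet_volume_nl = 0.85) {
  with_seed(derive_seed(seed, "copy_number_study"), {
    totals <- rpois(n_cells, mean_mt)
    muts <- rbinom(n_cells, totals, h)
    cells <- mapply(function(w, m) genome_pool(w, m), totals - muts, muts,
                    SIMPLIFY = FALSE)
    lys <- build_lysate(cells, ploidy_per_cell = ploidy,
                        reaction_volume = lysate_volume,
                        gdna_efficiency = gdna_efficiency)
    targets <- if (h > 0) c("nd1", "cox4", "del", "wt") else c("nd1", "cox4")
    drops <- droplets_from_lysate(lys, sample_id = sample_id,
                                  biological_rep = biological_rep,
                                  n_technical = n_technical,
                                  n_droplets = n_droplets,
                                  droplet_volume_nl = droplet_volume_nl,
                                  targets = targets)
    list(
      droplets = drops,
      samples = data.frame(sample_id = sample_id, stage = stage,
                           genotype = genotype, cells_sorted = n_cells,
                           biological_rep = biological_rep,
                           stringsAsFactors = FALSE),
      truth = list(mt_total = sum(totals),
                   gdna_total = n_cells * ploidy * gdna_efficiency,
                   mean_mt_per_cell = sum(totals) / n_cells,
                   heteroplasmy_percent = 100 * sum(muts) / sum(totals))
    )
  })
}

#' Simulate a full sorted-PGC study from the germline model
#'
#' Runs the whole-worm germline simulation [simulate_germline()] for
#' `n_worms` worms per biological replicate, pools the PGCs of each
#' requested stage into one sorted sample per replicate, and reads out
#' triplicate droplet wells per target. This is the generator behind
#' end-to-end validation: the configuration fixes the biology, and the
#' returned truth carries the realized per-cell means the analysis layers
#' should recover.
#'
#' @param config a [sim_config()]; its `seed` drives everything.
#' @param n_worms worms (germline simulations) pooled per biological
#'   replicate and stage.
#' @param n_bio number of biological replicates.
#' @param stages developmental stages to sort, a subset of
#'   `c("embryonic_PGC", "late_embryonic_PGC", "L1_PGC", "GSC")`.
#' @param ploidy nuclear genome copies per sorted cell (4 for G2-arrested
#'   PGCs).
#' @param n_technical wells per target.
#' @param genotype label recorded in the sample table.
#' @return list with `droplets`, `samples` and `truth` (data frame of
#'   realized per-stage, per-replicate mean copy number and heteroplasmy).
#' @export
simulate_pgc_study <- function(config, n_worms = 200, n_bio = 3,
                               stages = c("embryonic_PGC", "L1_PGC"),
                               ploidy = 4, n_technical = 3,
                               genotype = "wild_type") {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, .pgc_stages[-1], several.ok = TRUE)
  drops <- list(); samples <- list(); truth <- list()
  for (b in seq_len(n_bio)) {
    worms <- lapply(seq_len(n_worms), function(w) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, sprintf("bio%d_worm%d", b, w))
      simulate_germline(cfg)
    })
    for (st in stages) {
      cells <- unlist(lapply(worms, function(s) s$stages[[st]]),
                      recursive = FALSE)
      cells <- Filter(function(c) !is.null(c), cells)
      n_cells <- length(cells)
      lys <- build_lysate(cells, ploidy_per_cell = ploidy,
                          reaction_volume = n_cells * ploidy / 160,
                          nd1_detects_deletion = config$nd1_detects_deletion,
                          gdna_efficiency = config$gdna_efficiency)
      sid <- sprintf("%s_b%d", st, b)
      targets <- if (config$h0 > 0) c("nd1", "cox4", "del", "wt")
                 else c("nd1", "cox4")
      drops[[sid]] <- with_seed(
        derive_seed(config$seed, paste0("droplets_", sid)),
        droplets_from_lysate(lys, sample_id = sid,
                             biological_rep = paste0("b", b),
                             n_technical = n_technical,
                             n_droplets = config$n_droplets,
                             droplet_volume_nl = config$droplet_volume_nl,
                             targets = targets))
      samples[[sid]] <- data.frame(
        sample_id = sid, stage = st, genotype = genotype,
        cells_sorted = n_cells, biological_rep = paste0("b", b),
        stringsAsFactors = FALSE)
      cen <- census(cells)
      truth[[sid]] <- data.frame(
        sample_id = sid, stage = st, biological_rep = paste0("b", b),
        mean_mt_per_cell = mean(cen$total),
        heteroplasmy_percent =
          100 * sum(cen$mut_count) / max(1, sum(cen$total)),
        stringsAsFactors = FALSE)
    }
  }
  list(droplets = do.call(rbind, c(drops, list(make.row.names = FALSE))),
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Vectorized batch of paired heteroplasmy-shift studies
#'
#' Generates many independent studies of the embryo-to-L1 heteroplasmy
#' design at once, for calibration checks that need thousands of studies
#' (e.g. type-I error of the paired test under a selection-free null). Each
#' study has `n_bio` paired biological replicates; each replicate pools
#' `n_cells` cells at `per_cell` genomes and heteroplasmy `h`, measures the
#' early stage, applies the non-selective survival fraction
#' `(1 - f_lobe)(1 - f_auto)(1 - f_select)` (the `w_select = 1` null, where
#' selective removal collapses to proportional removal), and measures the
#' late stage. Measurements go through the droplet layer: deletion and
#' wild-type template counts are read as triplicate wells and inverted from
#' positive-droplet fractions, so technical noise is realistic.
#'
#' @param n_studies number of studies.
#' @param seed RNG seed.
#' @param n_bio paired biological replicates per study.
#' @param n_cells cells pooled per sample.
#' @param per_cell mean genomes per cell at the early stage.
#' @param h true heteroplasmy fraction.
#' @param f_lobe,f_auto,f_select removal fractions (applied neutrally).
#' @param n_droplets,droplet_volume_nl droplet plumbing.
#' @return list of two `n_studies x n_bio` matrices, `early` and `late`,
#'   of measured heteroplasmy percentages.
#' @export
simulate_shift_studies <- function(n_studies, seed, n_bio = 3,
                                   n_cells = 1000, per_cell = 400,
                                   h = 0.48, f_lobe = 0.32, f_auto = 0.19,
                                   f_select = 0.2, n_droplets = 20000,
                                   droplet_volume_nl = 0.85) {
  with_seed(derive_seed(seed, "shift_studies"), {
    n <- n_studies * n_bio
    m0 <- rpois(n, n_cells * per_cell * h)
    w0 <- rpois(n, n_cells * per_cell * (1 - h))
    s <- (1 - f_lobe) * (1 - f_auto) * (1 - f_select)
    m1 <- rbinom(n, m0, s)
    w1 <- rbinom(n, w0, s)
    vol <- n_cells * per_cell / 800   # lysate volume scaled with pool size
    measure <- function(mut, wt) {
      h_meas <- numeric(length(mut))
      for (cls in 1:2) {
        counts <- if (cls == 1) mut else wt
        conc <- counts / vol
        dil <- pmax(1, conc * droplet_volume_nl / 1000 / 0.35)
        lam <- conc / dil * droplet_volume_nl / 1000
        p <- 1 - exp(-lam)
        # triplicate wells, merged by the mean of per-well concentrations
        est <- 0
        for (t in 1:3) {
          pos <- rbinom(length(p), n_droplets, p)
          est <- est - log(1 - pos / n_droplets) / 3
        }
        est <- est / (droplet_volume_nl / 1000) * dil
        if (cls == 1) del_c <- est else wt_c <- est
      }
      100 * del_c / (del_c + wt_c)
    }
    list(early = matrix(measure(m0, w0), n_studies, n_bio),
         late = matrix(measure(m1, w1), n_studies, n_bio))
  })
}

#' Write a complete synthetic study directory
#'
#' Produces every input the analysis pipeline consumes: the configuration
#' (`config.yaml`), a genome census over all stages (`census.csv`), sorted
#' sample metadata (`samples.csv`), the droplet table (`droplets.csv`), and
#' optionally a pair of synthetic image stacks with truth sidecars under
#' `images/`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_worms,n_bio,stages passed to [simulate_pgc_study()].
#' @param images also write synthetic focus and acidification stacks.
#' @return `dir`, invisibly.
#' @export
write_study <- function(config, dir, n_worms = 50, n_bio = 3,
                        stages = c("embryonic_PGC", "L1_PGC"),
                        images = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sim_config(config, file.path(dir, "config.yaml"))
  one <- simulate_germline(config)
  write_census(one, file.path(dir, "census.csv"))
  study <- simulate_pgc_study(config, n_worms = n_worms, n_bio = n_bio,
                              stages = stages,
                              genotype = if (config$h0 > 0) "uaDf5"
                                         else "wild_type")
  write.csv(study$droplets, file.path(dir, "droplets.csv"),
            row.names = FALSE)
  write.csv(study$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (images) {
    imdir <- file.path(dir, "images")
    dir.create(imdir, showWarnings = FALSE)
    foci <- with_seed(derive_seed(config$seed, "foci_image"),
                      generate_foci_image(n_foci = 25))
    write_image_stack(foci, file.path(imdir, "foci"))
    acid <- with_seed(derive_seed(config$seed, "acid_image"),
                      generate_acidified_image())
    write_image_stack(acid, file.path(imdir, "acidified"))
  }
  invisible(dir)
}
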