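#' Pool sorted cells into a lysate and compute per-target concentrations
#'
#' Models sorting a population of cells into lysis buffer: template counts
#' are exact sums over the cells, and concentrations follow from the lysate
#' volume and a per-target dilution. Targets follow the assay panel used for
#' worm germline work: a total-mtDNA target (`nd1`), a deletion-specific
#' target (`del`), a wild-type-specific target (`wt`), and a single-copy
#' nuclear target (`cox4`) whose template count is `cells x ploidy` scaled
#' by an empirical detection efficiency.
#'
#' Whether the total-mtDNA amplicon also detects deletion genomes is
#' configurable (`nd1_detects_deletion`); the deletion lies outside the
#' nd-1 amplicon in the published genome schematic, so the default is
#' `TRUE`.
#'
#' @param cells list of [cell_state()]s or [genome_pool()]s.
#' @param ploidy_per_cell nuclear genome copies per cell.
#' @param reaction_volume lysate volume in microliters the cells are sorted
#'   into.
#' @param dilution_factor scalar or named vector (names among the targets)
#'   of fold-dilutions applied before droplet generation; >= 1.
#' @param nd1_detects_deletion logical, see above.
#' @param gdna_efficiency detection efficiency of the nuclear target in
#'   `(0, 1]` (expected detected copies are `cells * ploidy * efficiency`).
#' @return data frame with one row per target: `target`, `template_count`,
#'   `dilution_factor`, `concentration` (copies per microliter of the
#'   diluted sample) and `concentration_undiluted`.
#' @export
#' @examples
#' cells <- replicate(100, genome_pool(300, 100), simplify = FALSE)
#' build_lysate(cells, ploidy_per_cell = 4, reaction_volume = 500)
build_lysate <- function(cells, ploidy_per_cell = 4, reaction_volume = 500,
                         dilution_factor = 1, nd1_detects_deletion = TRUE,
                         gdna_efficiency = 1) {
  if (length(cells) == 0) stop("empty cell list: nothing was sorted")
  if (reaction_volume <= 0) stop("'reaction_volume' must be > 0")
  pools <- lapply(cells, function(c)
    if (inherits(c, "cell_state")) c$pool else c)
  stopifnot(all(vapply(pools, inherits, logical(1), "genome_pool")))
  wt <- sum(vapply(pools, function(p) p$wt, integer(1)))
  mut <- sum(vapply(pools, function(p) p$mut, integer(1)))
  counts <- c(
    nd1 = if (nd1_detects_deletion) wt + mut else wt,
    del = mut,
    wt = wt,
    cox4 = length(pools) * ploidy_per_cell * gdna_efficiency
  )
  dil <- rep(1, 4); names(dil) <- names(counts)
  if (is.null(names(dilution_factor))) {
    dil[] <- dilution_factor
  } else {
    dil[names(dilution_factor)] <- dilution_factor
  }
  if (any(dil < 1)) stop("dilution factors must be >= 1")
  data.frame(
    target = names(counts),
    template_count = as.numeric(counts),
    dilution_factor = as.numeric(dil),
    concentration = as.numeric(counts) / (reaction_volume * dil),
    concentration_undiluted = as.numeric(counts) / reaction_volume,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Generate one synthetic ddPCR well from a known concentration
#'
#' Stand-in for a droplet generator and reader: templates partition into
#' droplets as a Poisson process, so with mean occupancy
#' `lambda = concentration x droplet volume` each droplet is positive with
#' probability `1 - exp(-lambda)`, and the positive count is
#' Binomial(`n_droplets`, `1 - exp(-lambda)`).
#'
#' @param concentration template copies per microliter of the (diluted)
#'   sample loaded into droplets; must be >= 0.
#' @param n_droplets accepted droplets in the well.
#' @param droplet_volume_nl droplet volume in nanoliters.
#' @param dilution_factor fold-dilution applied to the sample before droplet
#'   generation (recorded so quantification can back-multiply).
#' @param target assay target label.
#' @param sample_id,well_id,technical_rep,biological_rep identifiers carried
#'   into the droplet table.
#' @return a one-row data frame in the droplet-table dialect: `sample_id`,
#'   `target`, `accepted_droplets`, `positive_droplets`,
#'   `droplet_volume_nl`, `dilution_factor`, `well_id`, `technical_rep`,
#'   `biological_rep`.
#' @export
#' @examples
#' set.seed(1)
#' generate_droplet_assay(500, target = "nd1")
generate_droplet_assay <- function(concentration, n_droplets = 20000,
                                   droplet_volume_nl = 0.85,
                                   dilution_factor = 1,
                                   target = "nd1", sample_id = "S1",
                                   well_id = "A01", technical_rep = "t1",
                                   biological_rep = "b1") {
  if (!is.numeric(concentration) || concentration < 0)
    stop("'concentration' must be >= 0")
  if (n_droplets < 1) stop("'n_droplets' must be >= 1")
  lambda <- concentration * droplet_volume_nl / 1000  # nL -> uL
  p_pos <- 1 - exp(-lambda)
  data.frame(
    sample_id = sample_id, target = target,
    accepted_droplets = as.integer(n_droplets),
    positive_droplets = rbinom(1, n_droplets, p_pos),
    droplet_volume_nl = droplet_volume_nl,
    dilution_factor = dilution_factor,
    well_id = well_id, technical_rep = technical_rep,
    biological_rep = biological_rep,
    stringsAsFactors = FALSE
  )
}

#' Choose a dilution bringing droplet occupancy into the quantifiable range
#'
#' ddPCR quantifies best when mean copies per droplet sits well away from
#' both zero and saturation; samples are therefore diluted to taste before
#' droplet generation. Returns the smallest fold-dilution (>= 1) that brings
#' `lambda` at or below `target_lambda`.
#'
#' @param concentration copies per microliter of the undiluted sample.
#' @param droplet_volume_nl droplet volume in nanoliters.
#' @param target_lambda desired mean copies per droplet (default 0.35).
#' @return a dilution factor >= 1.
#' @export
tune_dilution <- function(concentration, droplet_volume_nl = 0.85,
                          target_lambda = 0.35) {
  lambda <- concentration * droplet_volume_nl / 1000
  max(1, lambda / target_lambda)
}
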