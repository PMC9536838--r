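#' Ploidy-corrected mtDNA copies per cell
#'
#' The per-cell mtDNA copy number from paired quantifications of a
#' mitochondrial target and a single-copy nuclear target on the same
#' lysate: `mt_total / (gdna_total / N)`, where N is the nuclear ploidy.
#' The nuclear count divided by ploidy counts cells, so the quotient is
#' genomes per cell. Both totals may be on any common scale
#' (copies per microliter, copies per reaction): the ratio cancels it.
#'
#' The default ploidy is 4 because quiescent PGCs are arrested in G2 with a
#' replicated (4N) genome; use [estimate_ploidy()] for cycling stem cells.
#'
#' @param mt_total mitochondrial template copies detected.
#' @param gdna_total nuclear template copies detected (> 0).
#' @param ploidy nuclear genome copies per cell (> 0).
#' @return mtDNA copies per cell.
#' @export
#' @examples
#' per_cell_copy_number(40000, 400, ploidy = 4)  # 400 mtDNAs/cell
per_cell_copy_number <- function(mt_total, gdna_total, ploidy = 4) {
  if (!is.numeric(gdna_total) || any(gdna_total <= 0))
    stop("undefined cell count: 'gdna_total' must be > 0")
  if (!is.numeric(ploidy) || any(ploidy <= 0))
    stop("'ploidy' must be > 0")
  if (any(mt_total < 0)) stop("'mt_total' must be >= 0")
  mt_total * ploidy / gdna_total
}

#' Empirical ploidy estimate for cycling germline stem cells
#'
#' Quiescent starved-L1 PGCs have a fixed 4N ploidy, which anchors an
#' expected nuclear copy yield per sorted cell. Once fed larvae resume the
#' cell cycle, ploidy varies; it is estimated by scaling the reference
#' ploidy by the ratio of actually detected to expected nuclear copies:
#' `(actual / expected) * reference_ploidy`. With the published worked
#' numbers (46 detected against 61 expected per 5000 sorted cells) this
#' gives approximately 3.
#'
#' The unrounded value is what downstream per-cell arithmetic should use —
#' per-cell copy numbers are continuous and rounding the ploidy first can
#' inject up to ~17% bias; [estimate_ploidy_integer()] reports the nearest
#' integer for description.
#'
#' @param actual_gdna nuclear copies detected in the sample (>= 0).
#' @param expected_gdna nuclear copies expected at the reference ploidy for
#'   the same number of sorted cells (> 0).
#' @param reference_ploidy ploidy of the reference condition (default 4).
#' @return the unrounded ploidy estimate.
#' @export
#' @examples
#' estimate_ploidy(46, 61)            # 3.016...
#' estimate_ploidy_integer(46, 61)    # 3
estimate_ploidy <- function(actual_gdna, expected_gdna,
                            reference_ploidy = 4) {
  if (!is.numeric(expected_gdna) || any(expected_gdna <= 0))
    stop("'expected_gdna' must be > 0")
  if (!is.numeric(actual_gdna) || any(actual_gdna < 0))
    stop("'actual_gdna' must be >= 0")
  if (any(actual_gdna == 0))
    warning("0 nuclear copies detected: ploidy estimate of 0 is implausible")
  (actual_gdna / expected_gdna) * reference_ploidy
}

#' @rdname estimate_ploidy
#' @export
estimate_ploidy_integer <- function(actual_gdna, expected_gdna,
                                    reference_ploidy = 4) {
  as.integer(round(estimate_ploidy(actual_gdna, expected_gdna,
                                   reference_ploidy)))
}

#' Total mtDNA copies per germ line
#'
#' Scales the per-cell copy number by the average number of germ cell
#' nuclei observed at that stage. The nuclei count is a population average
#' and need not be an integer (e.g. an average of 18 stem cells per L2
#' germ line).
#'
#' @param mt_per_cell mtDNA copies per cell (>= 0).
#' @param mean_nuclei average germ cell nuclei per animal (> 0).
#' @return mtDNA copies per germ line.
#' @export
#' @examples
#' per_germline(220, 2)  # two quiescent PGCs -> 440 per germ line
per_germline <- function(mt_per_cell, mean_nuclei) {
  if (!is.numeric(mean_nuclei) || any(mean_nuclei <= 0))
    stop("'mean_nuclei' must be > 0")
  if (any(mt_per_cell < 0)) stop("'mt_per_cell' must be >= 0")
  mt_per_cell * mean_nuclei
}

#' Proportion of ancestor-stage mtDNAs inherited by a descendant stage
#'
#' The descendant-to-ancestor ratio of per-cell copy numbers, in percent:
#' e.g. the share of embryonic PGC mtDNAs still present in L1 PGCs. Both
#' the unrounded value and the nearest-integer percent are returned, since
#' summaries are conventionally quoted as whole percentages (220/401 is
#' 54.9%, quoted as 55%).
#'
#' @param descendant_per_cell per-cell copy number at the later stage.
#' @param ancestor_per_cell per-cell copy number at the earlier stage (> 0).
#' @return list with `percent` (unrounded) and `percent_rounded`.
#' @export
#' @examples
#' proportion_inherited(220, 401)
proportion_inherited <- function(descendant_per_cell, ancestor_per_cell) {
  if (!is.numeric(ancestor_per_cell) || any(ancestor_per_cell <= 0))
    stop("'ancestor_per_cell' must be > 0")
  pct <- 100 * descendant_per_cell / ancestor_per_cell
  list(percent = pct, percent_rounded = round(pct))
}

#' Per-sample copy-number results from quantification output
#'
#' Joins a quantification table (one row per sample and target, from
#' [quantify_droplet_table()]) with sample metadata and computes the
#' ploidy-corrected per-cell copy number for every sample with both the
#' total-mtDNA (`nd1`) and nuclear (`cox4`) targets.
#'
#' @param quant quantification data frame.
#' @param samples metadata data frame with `sample_id`, `stage`,
#'   `genotype`, `cells_sorted`, `biological_rep`.
#' @param ploidy scalar ploidy, or a named vector keyed by `sample_id` for
#'   mixed quiescent/cycling studies (e.g. from [estimate_ploidy()]).
#' @param mean_nuclei optional named vector (by stage) of average germ cell
#'   nuclei, to also report per-germline totals.
#' @return data frame: `sample_id`, `stage`, `genotype`, `biological_rep`,
#'   `mt_per_cell`, `ploidy_used`, and `germline_total` when `mean_nuclei`
#'   covers the stage.
#' @export
copy_number_results <- function(quant, samples, ploidy = 4,
                                mean_nuclei = NULL) {
  rows <- lapply(unique(samples$sample_id), function(sid) {
    q <- quant[quant$sample_id == sid, ]
    mt <- q$concentration[q$target == "nd1"]
    gd <- q$concentration[q$target == "cox4"]
    if (length(mt) != 1 || length(gd) != 1) return(NULL)
    meta <- samples[samples$sample_id == sid, ][1, ]
    pl <- if (length(ploidy) > 1 || !is.null(names(ploidy))) {
      if (!sid %in% names(ploidy))
        stop("no ploidy supplied for sample ", sid)
      unname(ploidy[sid])
    } else ploidy
    res <- data.frame(
      sample_id = sid, stage = meta$stage, genotype = meta$genotype,
      biological_rep = meta$biological_rep,
      mt_per_cell = per_cell_copy_number(mt, gd, pl),
      ploidy_used = pl, germline_total = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(mean_nuclei) && meta$stage %in% names(mean_nuclei))
      res$germline_total <- per_germline(res$mt_per_cell,
                                         mean_nuclei[[meta$stage]])
    res
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), rows),
                          list(make.row.names = FALSE)))
  if (is.null(out)) stop("no sample had both 'nd1' and 'cox4' quantifications")
  out
}

#' Per-technical-replicate copy numbers as a superplot table
#'
#' Computes the per-cell copy number separately for each technical
#' replicate (pairing the mitochondrial and nuclear wells by
#' `technical_rep` within a sample) rather than once from merged copies.
#' This preserves the replicate hierarchy the superplot layer needs:
#' technical replicates are displayed, biological replicates are tested.
#'
#' @param droplets droplet-table data frame.
#' @param samples sample metadata (see [copy_number_results()]).
#' @param ploidy scalar or named-by-sample ploidy.
#' @return a superplot data frame: `value` (mt per cell), `technical_rep`,
#'   `biological_rep`, `group` (stage), `sample_id`.
#' @export
copy_number_superplot <- function(droplets, samples, ploidy = 4) {
  rows <- list()
  for (sid in unique(samples$sample_id)) {
    d <- droplets[droplets$sample_id == sid, ]
    meta <- samples[samples$sample_id == sid, ][1, ]
    pl <- if (length(ploidy) > 1 || !is.null(names(ploidy)))
      unname(ploidy[sid]) else ploidy
    for (tr in unique(d$technical_rep)) {
      mt <- d[d$technical_rep == tr & d$target == "nd1", ]
      gd <- d[d$technical_rep == tr & d$target == "cox4", ]
      if (nrow(mt) != 1 || nrow(gd) != 1) next
      mt_c <- estimate_concentration(mt)$concentration
      gd_c <- estimate_concentration(gd)$concentration
      rows[[length(rows) + 1]] <- data.frame(
        value = per_cell_copy_number(mt_c, gd_c, pl),
        technical_rep = tr, biological_rep = meta$biological_rep,
        group = meta$stage, sample_id = sid, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no technical replicate had a paired nd1/cox4 well")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
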