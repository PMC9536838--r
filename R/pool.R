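#' Genome pool: wild-type and deletion mtDNA counts in one cell
#'
#' The simulator's unit of state: the number of intact (wild-type) and
#' deletion-bearing mtDNA genomes carried by a single cell.
#'
#' @param wt non-negative integer count of wild-type genomes.
#' @param mut non-negative integer count of deletion genomes.
#' @return an object of class `genome_pool` with fields `wt` and `mut`.
#' @export
#' @examples
#' p <- genome_pool(110, 103)
#' pool_total(p)
#' pool_heteroplasmy(p)
genome_pool <- function(wt, mut = 0) {
  wt <- as.integer(round(wt)); mut <- as.integer(round(mut))
  if (is.na(wt) || is.na(mut) || wt < 0 || mut < 0)
    stop("genome counts must be non-negative integers")
  structure(list(wt = wt, mut = mut), class = "genome_pool")
}

#' @rdname genome_pool
#' @param pool a `genome_pool`.
#' @export
pool_total <- function(pool) pool$wt + pool$mut

#' @rdname genome_pool
#' @details `pool_heteroplasmy()` returns the mutant fraction
#'   `mut / (wt + mut)`, or `NA` for an empty pool (heteroplasmy is
#'   undefined when no genomes remain).
#' @export
pool_heteroplasmy <- function(pool) {
  n <- pool_total(pool)
  if (n == 0) return(NA_real_)
  pool$mut / n
}

#' @export
print.genome_pool <- function(x, ...) {
  h <- pool_heteroplasmy(x)
  cat(sprintf("<genome_pool> wt=%d mut=%d total=%d heteroplasmy=%s\n",
              x$wt, x$mut, pool_total(x),
              if (is.na(h)) "undefined" else sprintf("%.1f%%", 100 * h)))
  invisible(x)
}

# Developmental stages, in the only order transitions may occur.
.pgc_stages <- c("zygote", "embryonic_PGC", "late_embryonic_PGC",
                 "L1_PGC", "GSC")

#' Cell state: a genome pool at a developmental stage
#'
#' @param pool a [genome_pool()].
#' @param stage one of `"zygote"`, `"embryonic_PGC"`, `"late_embryonic_PGC"`,
#'   `"L1_PGC"`, `"GSC"` — the order in which transitions are allowed.
#' @param lineage_id identifier of the cell lineage.
#' @return an object of class `cell_state`.
#' @export
cell_state <- function(pool, stage = "zygote", lineage_id = "Z") {
  stopifnot(inherits(pool, "genome_pool"))
  stage <- match.arg(stage, .pgc_stages)
  structure(list(pool = pool, stage = stage, lineage_id = lineage_id),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> %s [%s] ", x$stage, x$lineage_id))
  print(x$pool)
  invisible(x)
}

# Advance a cell to `stage`, enforcing forward-only transitions.
advance_stage <- function(cell, stage) {
  stage <- match.arg(stage, .pgc_stages)
  if (match(stage, .pgc_stages) < match(cell$stage, .pgc_stages))
    stop(sprintf("stage transition %s -> %s runs backwards", cell$stage, stage))
  cell$stage <- stage
  cell
}

#' Tabulate a list of cells as a census data frame
#'
#' @param cells list of [cell_state()] objects.
#' @return a data frame with columns `stage`, `lineage_id`, `wt_count`,
#'   `mut_count`, `total`, `heteroplasmy_percent` (NA for empty pools).
#' @export
census <- function(cells) {
  if (inherits(cells, "cell_state")) cells <- list(cells)
  data.frame(
    stage = vapply(cells, function(c) c$stage, character(1)),
    lineage_id = vapply(cells, function(c) as.character(c$lineage_id),
                        character(1)),
    wt_count = vapply(cells, function(c) c$pool$wt, integer(1)),
    mut_count = vapply(cells, function(c) c$pool$mut, integer(1)),
    total = vapply(cells, function(c) pool_total(c$pool), integer(1)),
    heteroplasmy_percent = vapply(cells, function(c) {
      h <- pool_heteroplasmy(c$pool)
      if (is.na(h)) NA_real_ else 100 * h
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
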