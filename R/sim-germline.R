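#' Binomial partition of a genome pool into two daughters
#'
#' Models stochastic organelle segregation at cell division: every genome is
#' assigned independently to one daughter with probability 1/2, so each
#' class count splits as an independent Binomial(n, 1/2). Totals are exactly
#' conserved across the two daughters.
#'
#' @param pool a [genome_pool()].
#' @return list of two `genome_pool`s.
#' @export
partition_pool <- function(pool) {
  stopifnot(inherits(pool, "genome_pool"))
  wt1 <- rbinom(1, pool$wt, 0.5)
  mut1 <- rbinom(1, pool$mut, 0.5)
  list(genome_pool(wt1, mut1),
       genome_pool(pool$wt - wt1, pool$mut - mut1))
}

#' Dilute the zygote mtDNA pool into two embryonic PGCs
#'
#' Embryonic PGCs inherit their mtDNAs from the pool present at
#' fertilization through reductive embryonic cell divisions: no replication
#' occurs, so each division halves the expected pool. Starting from the
#' zygote pool (optionally thinned once by the calibration factor in the
#' configuration), the followed lineage undergoes
#' `n_embryonic_divisions` binomial partitions, and the final cell divides
#' once more into the two PGCs. The expected per-PGC count is
#' `n0 * thinning / 2^(n_embryonic_divisions + 1)`.
#'
#' @param config a [sim_config()].
#' @return list of two [cell_state()]s at stage `"embryonic_PGC"`.
#' @export
#' @examples
#' cfg <- sim_config(n0 = 400, h0 = 0.5, n_embryonic_divisions = 1, seed = 7)
#' set.seed(7)
#' simulate_embryonic_dilution(cfg)
simulate_embryonic_dilution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$h0 < 0 || config$h0 > 1) stop("'h0' must lie in [0, 1]")
  if (config$n0 < 2) stop("'n0' must be at least 2")
  mut0 <- as.integer(round(config$n0 * config$h0))
  pool <- genome_pool(config$n0 - mut0, mut0)
  if (config$zygote_thinning < 1) {
    pool <- genome_pool(rbinom(1, pool$wt, config$zygote_thinning),
                        rbinom(1, pool$mut, config$zygote_thinning))
  }
  for (i in seq_len(config$n_embryonic_divisions)) {
    pool <- partition_pool(pool)[[1]]   # follow one daughter lineage
  }
  halves <- partition_pool(pool)
  list(cell_state(halves[[1]], "embryonic_PGC", "PGC_a"),
       cell_state(halves[[2]], "embryonic_PGC", "PGC_b"))
}

#' Remove a fixed proportion of genomes, regardless of class
#'
#' Models the bulk elimination mechanisms (lobe cannibalism, autophagy) that
#' remove a fixed proportion of the mtDNAs present within PGCs regardless of
#' how many are present. Every genome is removed independently with
#' probability `f`, so each class count survives as Binomial(n, 1 - f):
#' expected heteroplasmy is unchanged and the expected total is scaled by
#' `1 - f`.
#'
#' @param cell a [cell_state()] (or bare [genome_pool()]).
#' @param f removal fraction in `[0, 1]`.
#' @return the input with its pool thinned (same class as the input).
#' @export
apply_proportional_removal <- function(cell, f) {
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1)
    stop("'f' must be a fraction in [0, 1]")
  pool <- if (inherits(cell, "cell_state")) cell$pool else cell
  stopifnot(inherits(pool, "genome_pool"))
  out <- genome_pool(rbinom(1, pool$wt, 1 - f),
                     rbinom(1, pool$mut, 1 - f))
  if (inherits(cell, "cell_state")) { cell$pool <- out; cell } else out
}

#' Selectively remove genomes with a bias against the deletion class
#'
#' Models purifying selection (the PINK-1-dependent, autophagy-independent
#' reduction of mutant heteroplasmy) as a two-stage draw that separates "how
#' many" from "which": the removal budget `k` is Binomial(total, f_select)
#' exactly as in the non-selective mechanisms, and the `k` victims are then
#' drawn without replacement with each deletion genome weighted `w_select`
#' relative to weight 1 for wild type. With `w_select = 1` the step is
#' statistically identical to [apply_proportional_removal()]; with
#' `w_select > 1` expected heteroplasmy strictly decreases.
#'
#' Weighted sampling without replacement is drawn by an exponential race:
#' each genome receives an independent Exponential(weight) lifetime and the
#' `k` shortest-lived genomes are removed. Sequential draws proportional to
#' weight and the exponential race define the same distribution, but the
#' race vectorizes.
#'
#' @inheritParams apply_proportional_removal
#' @param f_select fraction of genomes subject to removal, in `[0, 1]`.
#' @param w_select relative elimination weight of a deletion genome (>= 1).
#' @return the input with its pool reduced (same class as the input).
#' @export
apply_selective_removal <- function(cell, f_select, w_select) {
  if (!is.numeric(f_select) || f_select < 0 || f_select > 1)
    stop("'f_select' must be a fraction in [0, 1]")
  if (!is.numeric(w_select) || w_select < 1)
    stop("'w_select' must be >= 1")
  pool <- if (inherits(cell, "cell_state")) cell$pool else cell
  stopifnot(inherits(pool, "genome_pool"))
  n <- pool_total(pool)
  k <- rbinom(1, n, f_select)
  wt <- pool$wt; mut <- pool$mut
  if (k > 0) {
    e_wt <- rexp(wt, rate = 1)
    e_mut <- rexp(mut, rate = w_select)
    thr <- sort(c(e_wt, e_mut), partial = k)[k]
    mut_removed <- sum(e_mut <= thr)
    mut <- mut - mut_removed
    wt <- wt - (k - mut_removed)
  }
  out <- genome_pool(wt, mut)
  if (inherits(cell, "cell_state")) { cell$pool <- out; cell } else out
}

#' Expand germline stem cells to an mtDNA set point
#'
#' Models the larval germline expansion in which stem cells balance mtDNA
#' replication with cell division to maintain a per-cell set point: in each
#' of `n_larval_divisions` rounds every cell partitions its pool binomially
#' into two daughters, and each daughter then replicates genomes one at a
#' time — each replication event copies a genome chosen with probability
#' proportional to its class weight (1 for wild type, `alpha_rep` for the
#' deletion, capturing the deletion haplotype's replicative advantage) —
#' until its total reaches `set_point`. Cells already at or above the set
#' point do not replicate, and no cell ever culls genomes here.
#'
#' @param cells list of [cell_state()]s with positive totals.
#' @param config a [sim_config()] supplying `set_point`, `alpha_rep` and
#'   `n_larval_divisions`.
#' @return list of `2^n_larval_divisions * length(cells)` cells at stage
#'   `"GSC"`.
#' @export
simulate_larval_expansion <- function(cells, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(cells, "cell_state")) cells <- list(cells)
  if (config$set_point < 1) stop("'set_point' must be >= 1")
  if (any(vapply(cells, function(c) pool_total(c$pool), integer(1)) == 0))
    stop("every input cell must carry at least one genome")
  for (div in seq_len(config$n_larval_divisions)) {
    nxt <- vector("list", 2 * length(cells))
    for (i in seq_along(cells)) {
      halves <- partition_pool(cells[[i]]$pool)
      for (j in 1:2) {
        pool <- replicate_to_set_point(halves[[j]], config$set_point,
                                       config$alpha_rep)
        nxt[[2 * (i - 1) + j]] <- cell_state(
          pool, "GSC",
          paste0(cells[[i]]$lineage_id, c(".1", ".2")[j]))
      }
    }
    cells <- nxt
  }
  lapply(cells, advance_stage, stage = "GSC")
}

# Replicate genomes one at a time, class chosen with weight alpha for the
# deletion class, until the pool total reaches T. An empty pool cannot
# replicate and is returned as is.
replicate_to_set_point <- function(pool, set_point, alpha) {
  wt <- pool$wt; mut <- pool$mut
  if (wt + mut == 0) return(pool)
  while (wt + mut < set_point) {
    p_mut <- alpha * mut / (alpha * mut + wt)
    if (runif(1) < p_mut) mut <- mut + 1 else wt <- wt + 1
  }
  genome_pool(wt, mut)
}

#' Run the full germline mtDNA simulation across developmental stages
#'
#' Chains the stage models: zygote pool, reductive dilution into two
#' embryonic PGCs, lobe cannibalism (`f_lobe`), autophagy (`f_auto`),
#' purifying selection (`f_select`, `w_select`) yielding L1 PGCs, then
#' larval expansion to germline stem cells. Each stage draws from its own
#' RNG stream derived from the master seed, so any stage is reproducible
#' independently of the others.
#'
#' @param config a [sim_config()].
#' @return an object of class `germline_sim`: a list with `config`,
#'   `stages` (named list of cell lists per stage) and `census` (one data
#'   frame over all stages, see [census()]).
#' @export
#' @examples
#' sim <- simulate_germline(sim_config(seed = 42))
#' subset(sim$census, stage == "L1_PGC")
simulate_germline <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mut0 <- as.integer(round(config$n0 * config$h0))
  zygote <- list(cell_state(genome_pool(config$n0 - mut0, mut0),
                            "zygote", "Z"))

  pgc <- with_seed(derive_seed(config$seed, "dilution"),
                   simulate_embryonic_dilution(config))

  late <- with_seed(derive_seed(config$seed, "lobe"), {
    lapply(pgc, function(c)
      advance_stage(apply_proportional_removal(c, config$f_lobe),
                    "late_embryonic_PGC"))
  })

  l1 <- with_seed(derive_seed(config$seed, "autophagy_selection"), {
    lapply(late, function(c) {
      c <- apply_proportional_removal(c, config$f_auto)
      c <- apply_selective_removal(c, config$f_select, config$w_select)
      advance_stage(c, "L1_PGC")
    })
  })

  gsc <- with_seed(derive_seed(config$seed, "expansion"), {
    alive <- Filter(function(c) pool_total(c$pool) > 0, l1)
    if (length(alive)) simulate_larval_expansion(alive, config) else list()
  })

  stages <- list(zygote = zygote, embryonic_PGC = pgc,
                 late_embryonic_PGC = late, L1_PGC = l1, GSC = gsc)
  structure(list(config = config, stages = stages,
                 census = do.call(rbind, lapply(stages, census))),
            class = "germline_sim")
}

#' @export
print.germline_sim <- function(x, ...) {
  cat("<germline_sim>\n")
  agg <- aggregate(total ~ stage, data = x$census, FUN = mean)
  agg <- agg[order(match(agg$stage, .pgc_stages)), ]
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-20s n=%d, mean total=%.1f\n", agg$stage[i],
                sum(x$census$stage == agg$stage[i]), agg$total[i]))
  invisible(x)
}

#' Write a simulated census to CSV
#'
#' @param sim a `germline_sim` (or any data frame shaped like its census).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(sim, path) {
  df <- if (inherits(sim, "germline_sim")) sim$census else sim
  write.csv(df[, c("stage", "lineage_id", "wt_count", "mut_count")],
            path, row.names = FALSE)
  invisible(path)
}
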