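#' Simulation configuration for germline mtDNA dynamics
#'
#' Bundles every parameter of the germline simulator. The defaults describe a
#' wild-type worm: a zygote pool the size measured in whole early embryos,
#' reductive embryonic divisions diluting that pool down to the ~1.2% share
#' each embryonic PGC receives, proportional genome elimination by lobe
#' cannibalism and by autophagy (calibrated so that roughly 55% of embryonic
#' PGC genomes survive to the L1 stage), no purifying selection (there are no
#' deletion genomes to select against), and larval expansion in which each
#' germline stem cell replicates its genomes back up to a set point of ~200.
#'
#' @param n0 zygote mtDNA genome count. Default 33840, the mean copy number
#'   of whole early embryos.
#' @param h0 initial deletion heteroplasmy fraction in `[0, 1]`.
#' @param n_embryonic_divisions number of reductive binary partitions between
#'   zygote and the PGC-founding cell, or `NULL` to calibrate it (plus a
#'   residual Bernoulli thinning of the zygote pool) so the expected per-PGC
#'   count equals `target_per_pgc`; see Details.
#' @param target_per_pgc expected genomes per embryonic PGC used when
#'   calibrating divisions. Default `0.012 * n0`, the measured per-PGC share
#'   of the whole-embryo pool.
#' @param f_lobe fraction of PGC genomes removed by lobe cannibalism
#'   (embryonic PGC to late embryonic PGC). Default 0.32, matching the
#'   observed 401 to 272 drop.
#' @param f_auto fraction removed by autophagy (late embryonic PGC to L1
#'   PGC). Default 0.19, matching the observed 272 to 220 drop.
#' @param f_select fraction of genomes subject to the selective-removal step
#'   (purifying selection); 0 disables it.
#' @param w_select relative elimination weight of a deletion genome in the
#'   selective step; must be >= 1, and 1 makes the step statistically
#'   identical to proportional removal.
#' @param set_point target genomes per germline stem cell; replication after
#'   each larval division proceeds until this total is reached. Default 200.
#' @param alpha_rep relative replication weight of a deletion genome during
#'   larval expansion; >= 1, and 1 is neutral.
#' @param n_larval_divisions number of stem-cell division rounds simulated.
#' @param seed master RNG seed; each stochastic stage derives its own stream
#'   with [derive_seed()].
#' @param genotype_flags character vector of loss-of-function switches, any
#'   of `"nop_1"` (no lobe cannibalism: zeroes `f_lobe`), `"atg"`
#'   (autophagy-defective: zeroes `f_auto`), `"pink_1"` (no purifying
#'   selection: forces `w_select = 1`). Flags only ever disable a mechanism.
#' @param n_droplets accepted droplets generated per synthetic ddPCR well.
#' @param droplet_volume_nl droplet volume in nanoliters (QX200 convention).
#' @param nd1_detects_deletion whether the total-mtDNA assay (nd-1) also
#'   amplifies deletion genomes. The deletion lies outside the nd-1 amplicon
#'   in the published schematic, so the default is `TRUE`.
#' @param gdna_efficiency detection efficiency of the nuclear (cox-4) assay
#'   relative to template molecules present; a single empirical constant with
#'   no mechanistic claim (sorted-cell lysates yield far fewer detectable
#'   nuclear copies than ploidy times cell count).
#'
#' @details When `n_embryonic_divisions` is `NULL`, the number of halvings is
#' the nearest integer to `log2(n0 / target_per_pgc) - 1`, and the remaining
#' fractional factor is applied as one Bernoulli thinning of the zygote pool
#' before partitioning, so the expectation lands exactly on
#' `target_per_pgc`. With an explicit division count no thinning is applied
#' and the expected per-PGC count is `n0 / 2^(n_embryonic_divisions + 1)`.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [sim_config_uadf5()] for a deletion-heteroplasmy preset,
#'   [simulate_germline()] to run the model.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_embryonic_divisions      # calibrated halving count
sim_config <- function(n0 = 33840,
                       h0 = 0,
                       n_embryonic_divisions = NULL,
                       target_per_pgc = 0.012 * n0,
                       f_lobe = 0.32,
                       f_auto = 0.19,
                       f_select = 0,
                       w_select = 1,
                       set_point = 200,
                       alpha_rep = 1,
                       n_larval_divisions = 3,
                       seed = 1,
                       genotype_flags = character(0),
                       n_droplets = 20000,
                       droplet_volume_nl = 0.85,
                       nd1_detects_deletion = TRUE,
                       gdna_efficiency = 1) {
  flags <- if (length(genotype_flags) == 0) character(0)
           else match.arg(genotype_flags, c("nop_1", "atg", "pink_1"),
                          several.ok = TRUE)
  if ("nop_1" %in% flags) f_lobe <- 0
  if ("atg" %in% flags) f_auto <- 0
  if ("pink_1" %in% flags) w_select <- 1

  thinning <- 1
  if (is.null(n_embryonic_divisions)) {
    if (target_per_pgc <= 0 || target_per_pgc > n0 / 2)
      stop("'target_per_pgc' must be in (0, n0/2]")
    n_embryonic_divisions <- max(0L, as.integer(round(
      log2(n0 / target_per_pgc) - 1)))
    thinning <- target_per_pgc * 2^(n_embryonic_divisions + 1) / n0
    if (thinning > 1) {  # rounding pushed divisions one too deep
      n_embryonic_divisions <- n_embryonic_divisions + 1L
      thinning <- target_per_pgc * 2^(n_embryonic_divisions + 1) / n0
    }
  }

  cfg <- structure(list(
    n0 = as.integer(n0), h0 = h0,
    n_embryonic_divisions = as.integer(n_embryonic_divisions),
    zygote_thinning = thinning,
    f_lobe = f_lobe, f_auto = f_auto,
    f_select = f_select, w_select = w_select,
    set_point = as.integer(set_point), alpha_rep = alpha_rep,
    n_larval_divisions = as.integer(n_larval_divisions),
    seed = as.integer(seed), genotype_flags = flags,
    n_droplets = as.integer(n_droplets),
    droplet_volume_nl = droplet_volume_nl,
    nd1_detects_deletion = isTRUE(nd1_detects_deletion),
    gdna_efficiency = gdna_efficiency
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @details `sim_config_uadf5()` presets a deletion-bearing (uaDf5-like)
#' worm: ~48% starting heteroplasmy, a selective-removal step calibrated to
#' drop PGC heteroplasmy by about 4.5 points between the embryonic and L1
#' stages, and a replicative advantage for the deletion genome during larval
#' expansion (the deletion haplotype is preferentially replicated once bulk
#' mtDNA synthesis resumes).
#' @export
sim_config_uadf5 <- function(...) {
  defaults <- list(h0 = 0.48, f_select = 0.2,
                   w_select = calibrate_w_select(0.48, 0.435, 0.2),
                   alpha_rep = 1.3)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Calibrate the selective-removal weight for a target heteroplasmy drop
#'
#' Solves, to first order, for the deletion-genome elimination weight
#' `w_select` that takes expected heteroplasmy from `h_pre` to `h_post` when
#' a fraction `f_select` of genomes is removed by weighted sampling. Under
#' the first-order approximation each deletion genome is removed with
#' probability `f w / wbar` and each wild-type genome with probability
#' `f / wbar`, where `wbar = h w + (1 - h)` is the mean weight.
#'
#' @param h_pre,h_post heteroplasmy fractions before/after the step.
#' @param f_select fraction of genomes removed.
#' @return the calibrated weight (>= 1).
#' @export
#' @examples
#' calibrate_w_select(0.48, 0.435, 0.2)  # ~2.1
calibrate_w_select <- function(h_pre, h_post, f_select) {
  stopifnot(h_post <= h_pre, h_pre > 0, h_pre < 1,
            f_select > 0, f_select < 1)
  a <- (h_post / h_pre) * (1 - f_select)   # mutant survival fraction
  denom <- f_select - h_pre * (1 - a)
  if (denom <= 0)
    stop("target drop is not reachable at this 'f_select'")
  w <- (1 - h_pre) * (1 - a) / denom
  max(1, w)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg,
                                         call. = FALSE)
  frac <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= 0 && x <= 1
  chk(is.numeric(cfg$n0) && cfg$n0 >= 2, "'n0' must be an integer >= 2")
  chk(frac(cfg$h0), "'h0' must be a fraction in [0, 1]")
  chk(cfg$n_embryonic_divisions >= 0, "'n_embryonic_divisions' must be >= 0")
  chk(frac(cfg$zygote_thinning) && cfg$zygote_thinning > 0,
      "internal thinning factor out of range")
  chk(frac(cfg$f_lobe), "'f_lobe' must be a fraction in [0, 1]")
  chk(frac(cfg$f_auto), "'f_auto' must be a fraction in [0, 1]")
  chk(frac(cfg$f_select), "'f_select' must be a fraction in [0, 1]")
  chk(is.numeric(cfg$w_select) && cfg$w_select >= 1, "'w_select' must be >= 1")
  chk(cfg$set_point >= 1, "'set_point' must be a positive integer")
  chk(is.numeric(cfg$alpha_rep) && cfg$alpha_rep >= 1, "'alpha_rep' must be >= 1")
  chk(cfg$n_larval_divisions >= 0, "'n_larval_divisions' must be >= 0")
  chk(cfg$n_droplets >= 1, "'n_droplets' must be >= 1")
  chk(cfg$droplet_volume_nl > 0, "'droplet_volume_nl' must be > 0")
  chk(frac(cfg$gdna_efficiency) && cfg$gdna_efficiency > 0,
      "'gdna_efficiency' must be in (0, 1]")
  cfg
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  known <- setdiff(known, "...")
  extra <- setdiff(names(raw), c(known, "zygote_thinning"))
  if (length(extra))
    stop("unknown sim_config field(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  thinning <- raw$zygote_thinning
  raw$zygote_thinning <- NULL
  if (!is.null(raw$genotype_flags))
    raw$genotype_flags <- as.character(unlist(raw$genotype_flags))
  cfg <- do.call(sim_config, raw)
  if (!is.null(thinning)) cfg$zygote_thinning <- thinning
  validate_sim_config(cfg)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  out$genotype_flags <- as.list(out$genotype_flags)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  zygote: n0=%d, h0=%.3f; %d embryonic divisions (thinning %.3f)\n",
              x$n0, x$h0, x$n_embryonic_divisions, x$zygote_thinning))
  cat(sprintf("  removal: f_lobe=%.2f, f_auto=%.2f, f_select=%.2f (w=%.2f)\n",
              x$f_lobe, x$f_auto, x$f_select, x$w_select))
  cat(sprintf("  expansion: set_point=%d, alpha_rep=%.2f, %d divisions\n",
              x$set_point, x$alpha_rep, x$n_larval_divisions))
  if (length(x$genotype_flags))
    cat("  genotype flags:", paste(x$genotype_flags, collapse = ", "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
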