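#' Poisson inversion of a positive-droplet fraction
#'
#' Droplet digital PCR partitions a reaction into ~20,000 droplets; template
#' molecules land in droplets as a Poisson process, so the fraction of
#' negative droplets estimates `exp(-lambda)` and the mean copies per
#' droplet is recovered as `lambda = -ln(1 - positives/accepted)`.
#'
#' A fully positive well is a saturation error rather than a clipped
#' estimate: the workflow dilutes samples specifically to avoid saturation,
#' so a saturated well signals a mis-specified dilution and carries no
#' usable concentration.
#'
#' @param positives positive droplet count.
#' @param accepted accepted droplet count (>= 1).
#' @return `lambda_hat`, mean template copies per droplet.
#' @export
#' @examples
#' estimate_lambda(10000, 20000)  # log(2)
estimate_lambda <- function(positives, accepted) {
  if (!is.numeric(accepted) || accepted < 1)
    stop("invalid assay: 'accepted' must be >= 1")
  if (!is.numeric(positives) || positives < 0 || positives > accepted)
    stop("'positives' must lie in [0, accepted]")
  if (positives == accepted)
    stop("saturated well: every droplet positive; concentration is ",
         "unquantifiable — increase the dilution")
  -log(1 - positives / accepted)
}

#' Absolute concentration of one ddPCR well, with confidence interval
#'
#' Converts a droplet-count record into an absolute template concentration
#' per microliter of the *undiluted* sample:
#' `concentration = lambda_hat / droplet_volume * dilution_factor`. The
#' confidence interval comes from the normal approximation to the positive
#' fraction propagated through the log transform (delta method):
#' `SE(lambda_hat) = sqrt(p(1-p)/n) / (1-p)`. Reporting on the undiluted
#' scale keeps dilution handled in exactly one place, so downstream
#' per-cell arithmetic never sees it.
#'
#' @param assay a one-row data frame (or list) with fields
#'   `positive_droplets`, `accepted_droplets`, `droplet_volume_nl`,
#'   `dilution_factor`, and optionally `target` and `sample_id`.
#' @param conf confidence level (default 0.95).
#' @param nominal_droplets nominal droplets per reaction used to scale
#'   `copies_per_reaction` (`lambda_hat * nominal_droplets`).
#' @return object of class `quant_result`: a list with `lambda_hat`,
#'   `concentration` (copies/uL undiluted), `ci_low`, `ci_high`,
#'   `copies_per_reaction`, `positives`, `accepted`, `target`, `sample_id`.
#' @export
#' @examples
#' a <- data.frame(positive_droplets = 10000, accepted_droplets = 20000,
#'                 droplet_volume_nl = 0.85, dilution_factor = 1)
#' estimate_concentration(a)$concentration  # ~815.4 copies/uL
estimate_concentration <- function(assay, conf = 0.95,
                                   nominal_droplets = 20000) {
  pos <- assay$positive_droplets; acc <- assay$accepted_droplets
  vol_ul <- assay$droplet_volume_nl / 1000
  dil <- assay$dilution_factor
  if (is.null(vol_ul) || vol_ul <= 0) stop("'droplet_volume_nl' must be > 0")
  if (is.null(dil) || dil < 1) stop("'dilution_factor' must be >= 1")
  lam <- estimate_lambda(pos, acc)
  p <- pos / acc
  se_lam <- sqrt(p * (1 - p) / acc) / (1 - p)
  z <- qnorm(1 - (1 - conf) / 2)
  scale <- dil / vol_ul
  structure(list(
    lambda_hat = lam,
    concentration = lam * scale,
    ci_low = max(0, (lam - z * se_lam)) * scale,
    ci_high = (lam + z * se_lam) * scale,
    copies_per_reaction = lam * nominal_droplets,
    positives = as.integer(pos), accepted = as.integer(acc),
    target = if (!is.null(assay$target)) as.character(assay$target) else NA_character_,
    sample_id = if (!is.null(assay$sample_id)) as.character(assay$sample_id) else NA_character_
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> %s/%s: %.4g copies/uL [%.4g, %.4g], lambda=%.4f (%d/%d)\n",
    x$sample_id, x$target, x$concentration, x$ci_low, x$ci_high,
    x$lambda_hat, x$positives, x$accepted))
  invisible(x)
}

#' Merge technical replicates of one target into a single estimate
#'
#' Assays are run in triplicate; the merged concentration is the arithmetic
#' mean of the per-well concentrations, with a t-based interval on the
#' replicate spread when two or more wells are available. The per-well
#' values are retained (`replicates`) for the superplot layer, which plots
#' technical replicates but tests only across biological replicates.
#'
#' @param results list of `quant_result`s for the same sample and target.
#' @param conf confidence level for the replicate-spread interval.
#' @return a `quant_result` with the merged concentration, plus fields
#'   `n_technical` and `replicates`.
#' @export
merge_technical_replicates <- function(results, conf = 0.95) {
  if (inherits(results, "quant_result")) results <- list(results)
  if (length(results) == 0) stop("no technical replicates to merge")
  stopifnot(all(vapply(results, inherits, logical(1), "quant_result")))
  tg <- unique(vapply(results, function(r) r$target, character(1)))
  if (length(tg) > 1)
    stop("technical replicates mix targets: ", paste(tg, collapse = ", "))
  conc <- vapply(results, function(r) r$concentration, numeric(1))
  n <- length(conc)
  est <- mean(conc)
  if (n >= 2) {
    half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(conc) / sqrt(n)
    ci <- c(max(0, est - half), est + half)
  } else {
    ci <- c(results[[1]]$ci_low, results[[1]]$ci_high)
  }
  out <- results[[1]]
  out$lambda_hat <- mean(vapply(results, function(r) r$lambda_hat, numeric(1)))
  out$concentration <- est
  out$ci_low <- ci[1]; out$ci_high <- ci[2]
  out$copies_per_reaction <-
    mean(vapply(results, function(r) r$copies_per_reaction, numeric(1)))
  out$positives <- sum(vapply(results, function(r) r$positives, integer(1)))
  out$accepted <- sum(vapply(results, function(r) r$accepted, integer(1)))
  out$n_technical <- n
  out$replicates <- conc
  out
}

#' Quantify a droplet table into per-well and per-sample concentrations
#'
#' Applies [estimate_concentration()] to every row of a droplet table and
#' merges technical replicates within each `(sample_id, target)` with
#' [merge_technical_replicates()].
#'
#' @param droplets droplet-table data frame (see
#'   [generate_droplet_assay()] for the dialect). Read from CSV with
#'   [read_droplet_table()].
#' @param conf confidence level.
#' @return data frame with one row per sample and target: `sample_id`,
#'   `target`, `concentration`, `ci_low`, `ci_high`, `copies_per_reaction`,
#'   `n_technical`, plus `biological_rep` carried from the table.
#' @export
quantify_droplet_table <- function(droplets, conf = 0.95) {
  needed <- c("sample_id", "target", "accepted_droplets",
              "positive_droplets", "droplet_volume_nl", "dilution_factor")
  miss <- setdiff(needed, names(droplets))
  if (length(miss))
    stop("droplet table lacks column(s): ", paste(miss, collapse = ", "))
  key <- interaction(droplets$sample_id, droplets$target, drop = TRUE)
  rows <- lapply(split(droplets, key), function(d) {
    merged <- merge_technical_replicates(
      lapply(seq_len(nrow(d)), function(i) estimate_concentration(d[i, ], conf)),
      conf)
    data.frame(sample_id = d$sample_id[1], target = d$target[1],
               concentration = merged$concentration,
               ci_low = merged$ci_low, ci_high = merged$ci_high,
               copies_per_reaction = merged$copies_per_reaction,
               n_technical = merged$n_technical,
               biological_rep = if ("biological_rep" %in% names(d))
                 d$biological_rep[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$sample_id, out$target), , drop = FALSE]
}

#' Read and write the droplet and quantification CSV dialects
#'
#' @param path CSV file path.
#' @return `read_droplet_table()` returns the droplet data frame after
#'   validating required columns and droplet-count sanity.
#' @export
read_droplet_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "target", "accepted_droplets",
              "positive_droplets", "droplet_volume_nl", "dilution_factor")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- d$positive_droplets < 0 | d$positive_droplets > d$accepted_droplets
  if (any(bad))
    stop(path, ": positive_droplets outside [0, accepted_droplets] in row(s) ",
         paste(which(bad), collapse = ", "))
  d
}

#' @rdname read_droplet_table
#' @param quant quantification data frame from [quantify_droplet_table()].
#' @export
write_quant_table <- function(quant, path) {
  write.csv(quant, path, row.names = FALSE)
  invisible(path)
}
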