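#' Deletion heteroplasmy from paired deletion/wild-type quantifications
#'
#' Percent heteroplasmy of a deletion haplotype measured with two
#' single-target assays on the same sample:
#' `100 * del / (del + wt)`. Defined only when at least one class was
#' detected.
#'
#' @param del_copies deletion-genome copies (any consistent scale).
#' @param wt_copies wild-type-genome copies on the same scale.
#' @return percent heteroplasmy in `[0, 100]`.
#' @export
#' @examples
#' heteroplasmy_percent(435, 565)  # 43.5
heteroplasmy_percent <- function(del_copies, wt_copies) {
  if (any(del_copies < 0) || any(wt_copies < 0))
    stop("copy values must be >= 0")
  tot <- del_copies + wt_copies
  if (any(tot == 0))
    stop("undefined heteroplasmy: no template of either class detected")
  100 * del_copies / tot
}

#' Per-sample heteroplasmy from a quantification table
#'
#' @param quant quantification data frame from [quantify_droplet_table()]
#'   containing `del` and `wt` targets.
#' @param samples sample metadata with `sample_id`, `stage`,
#'   `biological_rep`.
#' @return data frame: `sample_id`, `stage`, `biological_rep`, `percent`,
#'   `del_copies`, `wt_copies`.
#' @export
heteroplasmy_results <- function(quant, samples) {
  rows <- lapply(unique(samples$sample_id), function(sid) {
    q <- quant[quant$sample_id == sid, ]
    del <- q$concentration[q$target == "del"]
    wt <- q$concentration[q$target == "wt"]
    if (length(del) != 1 || length(wt) != 1) return(NULL)
    meta <- samples[samples$sample_id == sid, ][1, ]
    data.frame(sample_id = sid, stage = meta$stage,
               biological_rep = meta$biological_rep,
               percent = heteroplasmy_percent(del, wt),
               del_copies = del, wt_copies = wt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), rows),
                          list(make.row.names = FALSE)))
  if (is.null(out))
    stop("no sample had both 'del' and 'wt' quantifications")
  out
}

#' Stage-to-stage heteroplasmy shift with paired replicates
#'
#' Heteroplasmy at the early (embryonic PGC) and late (L1 PGC) stages is
#' measured on paired biological replicates — both stages always derive
#' from the same adult population — so shifts are computed within each
#' replicate pair. The sign convention is fixed:
#' `shift = early - late`, so a positive shift means heteroplasmy dropped,
#' i.e. purifying selection acted; reversing the two stages negates every
#' shift. Hypothesis testing (a paired t test across replicate pairs) is
#' delegated to [t_test()].
#'
#' @param early,late data frames with columns `biological_rep` and
#'   `percent` (e.g. rows of [heteroplasmy_results()] for the two stages);
#'   each biological replicate must appear exactly once in both.
#' @return list with `shifts` (data frame `biological_rep`,
#'   `early_percent`, `late_percent`, `shift`), `mean_shift`, and `sem`
#'   (NA with fewer than two pairs).
#' @export
#' @examples
#' early <- data.frame(biological_rep = c("b1", "b2"), percent = c(48, 48.4))
#' late  <- data.frame(biological_rep = c("b1", "b2"), percent = c(43.5, 44))
#' heteroplasmy_shift(early, late)$mean_shift
heteroplasmy_shift <- function(early, late) {
  for (d in list(early, late))
    if (!all(c("biological_rep", "percent") %in% names(d)))
      stop("'early' and 'late' need columns 'biological_rep' and 'percent'")
  if (anyDuplicated(early$biological_rep) ||
      anyDuplicated(late$biological_rep))
    stop("each biological replicate must appear exactly once per stage")
  if (!setequal(early$biological_rep, late$biological_rep))
    stop("unmatched biological replicates: ",
         paste(union(setdiff(early$biological_rep, late$biological_rep),
                     setdiff(late$biological_rep, early$biological_rep)),
               collapse = ", "))
  reps <- sort(unique(as.character(early$biological_rep)))
  e <- early$percent[match(reps, early$biological_rep)]
  l <- late$percent[match(reps, late$biological_rep)]
  shifts <- data.frame(biological_rep = reps, early_percent = e,
                       late_percent = l, shift = e - l,
                       stringsAsFactors = FALSE)
  list(shifts = shifts,
       mean_shift = mean(shifts$shift),
       sem = if (nrow(shifts) >= 2)
         sd(shifts$shift) / sqrt(nrow(shifts)) else NA_real_)
}
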