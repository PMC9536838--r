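#' Superplot aggregation: technical to biological replicates
#'
#' Implements the superplot discipline for nested replicates: technical
#' replicates are averaged within each biological replicate, the group
#' summary is the mean of those biological-replicate means, and the error
#' bar is the SEM of the biological means. Technical replicates are
#' displayed but never inflate n. Biological replicates are weighted
#' equally regardless of how many technical replicates each contributed.
#'
#' SEM requires at least two biological replicates; with fewer it is
#' reported as `NA` rather than silently pooling technical replicates.
#'
#' @param table data frame with columns `value`, `technical_rep`,
#'   `biological_rep`, `group`.
#' @return list with `bio_means` (data frame `group`, `biological_rep`,
#'   `mean`, `n_technical`) and `summary` (data frame `group`,
#'   `mean_of_means`, `sem`, `n_bio`).
#' @export
#' @examples
#' tb <- data.frame(value = c(9, 11, 19, 21, 29, 31),
#'                  technical_rep = rep(c("t1", "t2"), 3),
#'                  biological_rep = rep(c("b1", "b2", "b3"), each = 2),
#'                  group = "L1")
#' aggregate_superplot(tb)$summary
aggregate_superplot <- function(table) {
  needed <- c("value", "technical_rep", "biological_rep", "group")
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("superplot table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("empty superplot table")
  bio <- aggregate(value ~ group + biological_rep, data = table, FUN = mean)
  names(bio)[names(bio) == "value"] <- "mean"
  cnt <- aggregate(value ~ group + biological_rep, data = table,
                   FUN = length)
  bio$n_technical <- cnt$value[match(
    paste(bio$group, bio$biological_rep),
    paste(cnt$group, cnt$biological_rep))]
  bio <- bio[order(bio$group, bio$biological_rep), , drop = FALSE]
  rownames(bio) <- NULL
  summ <- do.call(rbind, lapply(split(bio, bio$group), function(g) {
    data.frame(group = g$group[1],
               mean_of_means = mean(g$mean),
               sem = if (nrow(g) >= 2) sd(g$mean) / sqrt(nrow(g))
                     else NA_real_,
               n_bio = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(bio_means = bio[, c("group", "biological_rep", "mean",
                           "n_technical")],
       summary = summ)
}

#' Student's t test on biological-replicate means
#'
#' Hypothesis tests always operate on biological-replicate means, never on
#' technical replicates — pooling technical replicates would overstate n.
#' Paired tests match replicates by `pairing_key` (used when the two
#' stages of a comparison derive from the same adult population, as in
#' heteroplasmy designs); copy-number comparisons are conventionally
#' unpaired. One-tailed tests must declare their direction explicitly via
#' `alternative`.
#'
#' `log_ratio = TRUE` gives the paired-ratio flavor: a paired t test on
#' the log of the values, testing whether the ratio between conditions
#' differs from 1.
#'
#' @param group_a,group_b numeric vectors of biological-replicate means,
#'   or data frames with columns `value` and (for pairing) `pairing_key`.
#' @param paired logical.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction of
#'   `group_a` relative to `group_b`).
#' @param log_ratio run the paired test on log-transformed values.
#' @return an object of class `htest` (see [stats::t.test()]) with the
#'   comparison recorded in `data.name`.
#' @export
#' @examples
#' t_test(c(48.2, 47.9, 48.1), c(43.3, 43.8, 43.5), paired = TRUE)
t_test <- function(group_a, group_b, paired = FALSE,
                   alternative = c("two.sided", "less", "greater"),
                   log_ratio = FALSE) {
  alternative <- match.arg(alternative)
  get_vals <- function(g) {
    if (is.data.frame(g)) {
      if (!"value" %in% names(g)) stop("data frame groups need a 'value' column")
      if (paired && "pairing_key" %in% names(g)) {
        g <- g[order(g$pairing_key), ]
        if (anyDuplicated(g$pairing_key))
          stop("duplicated pairing keys within a group")
        return(setNames(g$value, g$pairing_key))
      }
      return(g$value)
    }
    g
  }
  a <- get_vals(group_a); b <- get_vals(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two biological replicates per group")
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must match in length")
    if (!is.null(names(a)) && !is.null(names(b))) {
      if (!setequal(names(a), names(b)))
        stop("unmatched pairing keys: ",
             paste(union(setdiff(names(a), names(b)),
                         setdiff(names(b), names(a))), collapse = ", "))
      b <- b[names(a)]
    }
  }
  if (log_ratio) {
    if (!paired) stop("'log_ratio' is a paired-ratio test; set paired = TRUE")
    if (any(c(a, b) <= 0)) stop("log-ratio test requires positive values")
    a <- log(a); b <- log(b)
  }
  if (paired && sd(a - b) == 0) {
    # degenerate pairs (all differences identical): stats::t.test refuses;
    # report the limit instead — t = 0 for identical groups, +/-Inf for a
    # constant non-zero difference
    d <- mean(a - b)
    stat <- if (d == 0) 0 else sign(d) * Inf
    df <- length(a) - 1
    p <- switch(alternative,
                two.sided = if (d == 0) 1 else 0,
                less = stats::pt(stat, df),
                greater = stats::pt(stat, df, lower.tail = FALSE))
    out <- structure(list(
      statistic = c(t = stat), parameter = c(df = df), p.value = p,
      estimate = c(`mean difference` = d), alternative = alternative,
      method = "Paired t-test (degenerate: constant differences)",
      data.name = ""), class = "htest")
  } else {
    out <- t.test(a, b, paired = paired, alternative = alternative)
  }
  out$data.name <- sprintf("%s t test on biological-replicate means%s",
                           if (paired) "paired" else "unpaired",
                           if (log_ratio) " (log-ratio)" else "")
  out
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test for categorical scores (e.g. embryos scored
#' as containing or lacking acidified mitochondria, by genotype). The
#' two-sided p-value sums all tables as or less probable than the
#' observed one; the odds ratio is the conditional maximum-likelihood
#' estimate, reported as `Inf`/0 when a zero cell makes it unbounded
#' (see [stats::fisher.test()]).
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return list with `p_value` and `odds_ratio`.
#' @export
#' @examples
#' fisher_exact(matrix(c(16, 0, 0, 16), 2))
fisher_exact <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2)))
    stop("'table' must be a 2x2 matrix")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("all-zero contingency table")
  ft <- fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Optional multiple-testing adjustment for report p-values
#'
#' The default workflow applies no multiple-comparison correction (the
#' cost of type II errors is judged to outweigh family-wise control in
#' these small, hypothesis-driven panels); users who want control can
#' switch on Benjamini-Hochberg here.
#'
#' @param p numeric vector of p-values.
#' @param method `"none"` (default) or `"BH"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("none", "BH")) {
  method <- match.arg(method)
  if (method == "none") p else stats::p.adjust(p, method = "BH")
}
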