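test_that("superplot aggregation matches hand computation and weights
           biological replicates equally", {
  tb <- data.frame(
    value = c(9, 11, 19, 21, 29, 31),
    technical_rep = rep(c("t1", "t2"), 3),
    biological_rep = rep(c("b1", "b2", "b3"), each = 2),
    group = "g")
  agg <- aggregate_superplot(tb)
  expect_equal(agg$bio_means$mean, c(10, 20, 30))
  expect_equal(agg$summary$mean_of_means, 20)
  expect_equal(agg$summary$sem, 10 / sqrt(3))
  expect_equal(agg$summary$n_bio, 3L)
  # identical values: SEM exactly zero
  same <- tb; same$value <- 5
  expect_equal(aggregate_superplot(same)$summary$sem, 0)
  # unbalanced technical replicates do not reweight biological replicates
  unb <- rbind(tb, data.frame(value = 10, technical_rep = "t3",
                              biological_rep = "b1", group = "g"))
  expect_equal(aggregate_superplot(unb)$summary$mean_of_means, 20)
  # permutation invariance over rows
  perm <- tb[sample(nrow(tb)), ]
  expect_equal(aggregate_superplot(perm), agg)
  expect_error(aggregate_superplot(tb[0, ]), "empty")
})

test_that("SEM refuses a single biological replicate instead of pooling
           technical replicates", {
  tb <- data.frame(value = c(1, 2, 3), technical_rep = c("t1", "t2", "t3"),
                   biological_rep = "b1", group = "g")
  agg <- aggregate_superplot(tb)
  expect_equal(agg$summary$mean_of_means, 2)
  expect_true(is.na(agg$summary$sem))
})

test_that("t tests run on biological-replicate means with explicit pairing
           and direction", {
  a <- c(10, 12, 14); b <- c(11, 13, 18)
  # hand-computed Welch t as the oracle
  tt <- t_test(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(unname(tt$statistic), (mean(a) - mean(b)) / se)
  # identical paired groups: t = 0, p = 1
  same <- t_test(a, a, paired = TRUE)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # paired beats unpaired when pairs share noise
  expect_lt(t_test(c(48, 50, 52), c(43, 45, 47), paired = TRUE)$p.value,
            t_test(c(48, 50, 52), c(43, 45, 47))$p.value)
  # pairing keys align rows regardless of order
  ga <- data.frame(value = a, pairing_key = c("r1", "r2", "r3"))
  gb <- data.frame(value = rev(b), pairing_key = c("r3", "r2", "r1"))
  keyed <- t_test(ga, gb, paired = TRUE)
  expect_equal(unname(keyed$statistic),
               unname(t_test(a, b, paired = TRUE)$statistic))
  gb_bad <- data.frame(value = b, pairing_key = c("r1", "r2", "r9"))
  expect_error(t_test(ga, gb_bad, paired = TRUE), "unmatched")
  expect_error(t_test(1, c(1, 2)), "at least two")
  # one-tailed halves the two-tailed p when the direction is right
  one <- t_test(c(43, 45, 47), c(48, 50, 52), paired = TRUE,
                alternative = "less")
  two <- t_test(c(43, 45, 47), c(48, 50, 52), paired = TRUE)
  expect_equal(one$p.value, two$p.value / 2)
  # paired-ratio flavor: t test on log ratios
  lr <- t_test(c(0.25, 0.3, 0.2), c(1, 1.1, 0.9), paired = TRUE,
               log_ratio = TRUE)
  expect_lt(lr$p.value, 0.01)
  expect_error(t_test(a, b, log_ratio = TRUE), "paired")
})

test_that("the paired test holds its nominal size on null shift studies", {
  ss <- simulate_shift_studies(2000, seed = 314)
  pv <- vapply(seq_len(nrow(ss$early)), function(i)
    t_test(ss$early[i, ], ss$late[i, ], paired = TRUE)$p.value, numeric(1))
  rate <- mean(pv < 0.05)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.075)
  # and the mean shift itself is centered on zero
  shifts <- rowMeans(ss$early - ss$late)
  expect_lt(abs(mean(shifts)), 3 * mc_se(shifts))
})

test_that("SEM shrinks as biological replicates accumulate", {
  set.seed(31)
  sem_at <- function(n_bio) {
    mean(replicate(200, {
      tb <- data.frame(value = rnorm(n_bio * 3, 100, 10),
                       technical_rep = rep(c("t1", "t2", "t3"), n_bio),
                       biological_rep = rep(paste0("b", 1:n_bio), each = 3),
                       group = "g")
      aggregate_superplot(tb)$summary$sem
    }))
  }
  sems <- vapply(c(3, 6, 12), sem_at, numeric(1))
  expect_true(all(diff(sems) < 0))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  flat <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p_value, 1)
  # perfectly discordant 10/10 table: the two extreme tables only
  sep <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sep$odds_ratio, Inf)
  # acidification-style scoring fixture (N >= 16 per replicate)
  acid <- fisher_exact(matrix(c(16, 0, 0, 16), 2))
  expect_equal(acid$p_value, 2 / choose(32, 16), tolerance = 1e-12)
  # direct enumeration oracle for an asymmetric table
  tab <- matrix(c(7, 2, 3, 8), 2)
  enum <- {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    probs <- dhyper(0:k, m, n, k)
    sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(tab)$p_value, enum, tolerance = 1e-9)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
  expect_error(fisher_exact(matrix(1, 3, 3)), "2x2")
})

test_that("p-value adjustment is off by default with an optional BH switch", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(adjust_pvalues(p), p)
  expect_equal(adjust_pvalues(p, "BH"), p.adjust(p, "BH"))
})
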