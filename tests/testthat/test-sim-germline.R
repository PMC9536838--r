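test_that("partitioning conserves genomes exactly and dilution follows it", {
  set.seed(11)
  for (i in 1:20) {
    p <- genome_pool(sample(0:50, 1), sample(0:50, 1))
    halves <- partition_pool(p)
    expect_equal(pool_total(halves[[1]]) + pool_total(halves[[2]]),
                 pool_total(p))
    expect_equal(halves[[1]]$mut + halves[[2]]$mut, p$mut)
  }
  # n0=4, h0=0.5, no divisions: the two PGCs hold exactly (2,2) pooled
  cfg <- sim_config(n0 = 4, h0 = 0.5, n_embryonic_divisions = 0,
                    n_larval_divisions = 0)
  set.seed(1)
  pgc <- simulate_embryonic_dilution(cfg)
  expect_equal(pgc[[1]]$pool$wt + pgc[[2]]$pool$wt, 2L)
  expect_equal(pgc[[1]]$pool$mut + pgc[[2]]$pool$mut, 2L)
})

test_that("dilution expectation matches n0 / 2^(divisions+1)", {
  cfg <- sim_config(n0 = 33840, n_embryonic_divisions = 5,
                    n_larval_divisions = 0)
  set.seed(2)
  per_pgc <- replicate(400, {
    pgc <- simulate_embryonic_dilution(cfg)
    mean(c(pool_total(pgc[[1]]$pool), pool_total(pgc[[2]]$pool)))
  })
  expect_equal(mean(per_pgc), 33840 / 64, tolerance = 0.02)
})

test_that("partition heteroplasmy variance matches the enumeration oracle", {
  # exact enumeration for small pools
  for (pool in list(c(2, 2), c(6, 6), c(4, 8))) {
    orc <- partition_heteroplasmy_oracle(pool[1], pool[2])
    set.seed(pool[1] * 100 + pool[2])
    h <- replicate(6000, pool_heteroplasmy(
      partition_pool(genome_pool(pool[1], pool[2]))[[1]]))
    h <- h[!is.na(h)]
    expect_equal(mean(h), orc$mean, tolerance = 4 * mc_se(h) / orc$mean)
    # variance of the sample variance approximated by batching
    batches <- split(h, rep(1:30, length.out = length(h)))
    v <- vapply(batches, var, numeric(1))
    expect_lt(abs(mean(v) - orc$var), 3 * mc_se(v))
  }
  # large pool: n = 400 at h = 0.5
  orc <- partition_heteroplasmy_oracle(200, 200)
  set.seed(400)
  h <- replicate(4000, pool_heteroplasmy(
    partition_pool(genome_pool(200, 200))[[1]]))
  expect_lt(abs(mean(h) - 0.5), 3 * mc_se(h))
  batches <- split(h, rep(1:40, length.out = length(h)))
  v <- vapply(batches, var, numeric(1))
  expect_lt(abs(mean(v) - orc$var), 3 * mc_se(v))
})

test_that("proportional removal is neutral in heteroplasmy and scales totals", {
  expect_error(apply_proportional_removal(genome_pool(5, 5), 1.5), "fraction")
  set.seed(3)
  # identity and annihilation
  expect_equal(apply_proportional_removal(genome_pool(7, 3), 0),
               genome_pool(7, 3))
  expect_equal(pool_total(apply_proportional_removal(genome_pool(7, 3), 1)), 0L)
  # (200,200) at f = 0.45: retained total ~220, heteroplasmy unmoved
  out <- replicate(2000, {
    p <- apply_proportional_removal(genome_pool(200, 200), 0.45)
    c(pool_total(p), pool_heteroplasmy(p))
  })
  expect_lt(abs(mean(out[1, ]) - 220), 3 * mc_se(out[1, ]))
  expect_lt(abs(mean(out[2, ]) - 0.5), 3 * mc_se(out[2, ]))
})

test_that("selective removal matches the sequential-draw enumeration oracle", {
  # k = 1 on (2,2) with weight 3: P(victim is mutant) = 6/8
  pmf <- weighted_removal_pmf(2, 2, k = 1, w = 3)
  expect_equal(unname(pmf[["1"]]), 0.75)
  # joint check against the implementation on a small pool, f = 0.5
  wt <- 2; mut <- 2; f <- 0.5; w <- 3
  exact <- numeric(mut + 1)  # P(mutants removed = 0..mut)
  for (k in 0:(wt + mut)) {
    pk <- dbinom(k, wt + mut, f)
    pmf_k <- weighted_removal_pmf(wt, mut, k, w)
    for (nm in names(pmf_k)) {
      i <- as.integer(nm)
      if (i <= mut) exact[i + 1] <- exact[i + 1] + pk * pmf_k[[nm]]
    }
  }
  set.seed(4)
  reps <- replicate(20000, mut - apply_selective_removal(
    genome_pool(wt, mut), f, w)$mut)
  for (i in 0:mut) {
    p_hat <- mean(reps == i)
    se <- sqrt(exact[i + 1] * (1 - exact[i + 1]) / length(reps))
    expect_lt(abs(p_hat - exact[i + 1]), 4 * se + 1e-9)
  }
})

test_that("selective removal reduces to the neutral case at w = 1 and is
           monotone in w", {
  set.seed(5)
  h1 <- replicate(1500, pool_heteroplasmy(
    apply_selective_removal(genome_pool(200, 200), 0.45, 1)))
  expect_lt(abs(mean(h1) - 0.5), 3 * mc_se(h1))
  means <- vapply(c(1, 1.5, 2.5, 4), function(w) {
    set.seed(50 + w * 10)
    mean(replicate(1200, pool_heteroplasmy(
      apply_selective_removal(genome_pool(200, 200), 0.45, w))))
  }, numeric(1))
  expect_true(all(diff(means) < 0))   # heteroplasmy falls as w rises
  expect_true(all(means[-1] < 0.5))   # and any w > 1 selects
})

test_that("calibrated selection drops ~48% pools to ~43.5% heteroplasmy", {
  w <- calibrate_w_select(0.48, 0.435, 0.2)
  set.seed(6)
  h <- replicate(3000, pool_heteroplasmy(
    apply_selective_removal(genome_pool(208, 192), 0.2, w)))
  expect_equal(100 * mean(h), 43.5, tolerance = 1 / 43.5)  # within 1 point
})

test_that("larval expansion reaches the set point and neutral replication
           keeps heteroplasmy at 1/2", {
  cfg <- sim_config(set_point = 200, alpha_rep = 1, n_larval_divisions = 1)
  # pure wild type: every daughter ends with exactly T genomes
  set.seed(7)
  out <- simulate_larval_expansion(
    list(cell_state(genome_pool(150, 0), "L1_PGC", "a")), cfg)
  expect_length(out, 2)
  expect_true(all(vapply(out, function(c) pool_total(c$pool), integer(1)) ==
                    200L))
  # (110,110): daughters end at exactly 200 and mean heteroplasmy ~0.5
  set.seed(8)
  h <- replicate(600, {
    gs <- simulate_larval_expansion(
      list(cell_state(genome_pool(110, 110), "L1_PGC", "a")), cfg)
    mean(vapply(gs, function(c) pool_heteroplasmy(c$pool), numeric(1)))
  })
  expect_lt(abs(mean(h) - 0.5), 3 * mc_se(h))
})

test_that("a replicative advantage drives heteroplasmy up across divisions", {
  base <- sim_config(set_point = 200, alpha_rep = 1.3)
  set.seed(9)
  h_by_div <- vapply(1:3, function(nd) {
    cfg <- base; cfg$n_larval_divisions <- nd
    mean(replicate(80, {
      gs <- simulate_larval_expansion(
        list(cell_state(genome_pool(113, 87), "L1_PGC", "a")), cfg)
      mean(vapply(gs, function(c) pool_heteroplasmy(c$pool), numeric(1)))
    }))
  }, numeric(1))
  expect_true(all(diff(h_by_div) > 0))
  expect_gt(h_by_div[3], 87 / 200)
})

test_that("with all removal off and no replication, genomes are conserved
           through every stage", {
  cfg <- sim_config(n0 = 512, h0 = 0.25, n_embryonic_divisions = 2,
                    f_lobe = 0, f_auto = 0, f_select = 0,
                    n_larval_divisions = 0, seed = 99)
  sim <- simulate_germline(cfg)
  for (st in c("embryonic_PGC", "late_embryonic_PGC", "L1_PGC")) {
    cen <- sim$census[sim$census$stage == st, ]
    # both PGCs carry exactly what the followed lineage carried
    expect_equal(sum(cen$total),
                 sum(sim$census$total[sim$census$stage == "embryonic_PGC"]))
  }
})

test_that("simulations are reproducible bit-for-bit from the master seed", {
  cfg <- sim_config_uadf5(seed = 123, n_larval_divisions = 2)
  s1 <- simulate_germline(cfg)
  s2 <- simulate_germline(cfg)
  expect_identical(s1$census, s2$census)
  cfg2 <- sim_config_uadf5(seed = 124, n_larval_divisions = 2)
  expect_false(identical(simulate_germline(cfg2)$census, s1$census))
  # child streams are label-stable
  expect_identical(derive_seed(123, "dilution"), derive_seed(123, "dilution"))
  expect_false(derive_seed(123, "dilution") == derive_seed(123, "lobe"))
})
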