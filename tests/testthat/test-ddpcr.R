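test_that("lambda inversion has the right closed forms and error modes", {
  expect_equal(estimate_lambda(0, 20000), 0)
  expect_equal(estimate_lambda(10000, 20000), log(2))
  expect_error(estimate_lambda(20000, 20000), "saturated")
  expect_error(estimate_lambda(5, 0), "invalid assay")
  expect_error(estimate_lambda(-1, 100), "positives")
})

test_that("concentration math reconciles droplet volume and dilution", {
  a <- data.frame(positive_droplets = 10000, accepted_droplets = 20000,
                  droplet_volume_nl = 0.85, dilution_factor = 1)
  q <- estimate_concentration(a)
  expect_equal(q$concentration, log(2) / 0.00085, tolerance = 1e-10)
  expect_true(q$ci_low <= q$concentration && q$concentration <= q$ci_high)
  # zero positives: concentration and lower bound are both zero
  a0 <- a; a0$positive_droplets <- 0
  q0 <- estimate_concentration(a0)
  expect_equal(q0$concentration, 0)
  expect_equal(q0$ci_low, 0)
  # dilution is a pure multiplier at identical droplet counts
  a3000 <- a; a3000$dilution_factor <- 3000
  expect_equal(estimate_concentration(a3000)$concentration,
               3000 * q$concentration)
})

test_that("concentration is strictly monotone in positives", {
  conc <- vapply(c(1, 10, 500, 5000, 19000, 19999), function(p)
    estimate_concentration(data.frame(
      positive_droplets = p, accepted_droplets = 20000,
      droplet_volume_nl = 0.85, dilution_factor = 1))$concentration,
    numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("droplet generation saturates and empties at the extremes", {
  set.seed(1)
  expect_equal(generate_droplet_assay(0)$positive_droplets, 0L)
  hot <- generate_droplet_assay(1e6, n_droplets = 5000)
  expect_equal(hot$positive_droplets, 5000L)
  # lambda = 1: positive fraction ~ 1 - exp(-1)
  conc1 <- 1 / 0.00085
  pos <- replicate(200, generate_droplet_assay(conc1)$positive_droplets)
  frac <- pos / 20000
  expect_lt(abs(mean(frac) - (1 - exp(-1))), 3 * mc_se(frac))
})

test_that("the inversion is unbiased within 1% over the working range", {
  vol <- 0.00085
  set.seed(2)
  for (lam in c(0.05, 0.2, 0.5, 1, 2)) {
    pos <- rbinom(500, 20000, 1 - exp(-lam))
    lam_hat <- -log(1 - pos / 20000)
    expect_lt(abs(mean(lam_hat) - lam) / lam, 0.01)
  }
})

test_that("the 95% interval covers the true concentration in >=90% of assays", {
  set.seed(3)
  lam <- 0.5; vol <- 0.00085
  truth <- lam / vol
  pos <- rbinom(1000, 20000, 1 - exp(-lam))
  covered <- vapply(pos, function(p) {
    q <- estimate_concentration(data.frame(
      positive_droplets = p, accepted_droplets = 20000,
      droplet_volume_nl = 0.85, dilution_factor = 1))
    q$ci_low <= truth && truth <= q$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("round-tripping through the generator recovers the concentration", {
  set.seed(4)
  truth <- 400   # copies/uL, lambda = 0.34
  hits <- replicate(200, {
    a <- generate_droplet_assay(truth)
    q <- estimate_concentration(a)
    q$ci_low <= truth && truth <= q$ci_high
  })
  expect_gte(mean(hits), 0.90)
})

test_that("technical replicates merge by the mean and shrink the error", {
  mk <- function(conc) {
    q <- estimate_concentration(data.frame(
      positive_droplets = 100, accepted_droplets = 20000,
      droplet_volume_nl = 0.85, dilution_factor = 1))
    q$concentration <- conc
    q
  }
  expect_equal(merge_technical_replicates(list(mk(100)))$concentration, 100)
  m <- merge_technical_replicates(list(mk(100), mk(110), mk(120)))
  expect_equal(m$concentration, 110)
  expect_equal(m$n_technical, 3L)
  expect_error(merge_technical_replicates(list()), "no technical")
  bad <- mk(100); bad$target <- "cox4"
  good <- mk(100); good$target <- "nd1"
  expect_error(merge_technical_replicates(list(good, bad)), "mix targets")
  # the merged estimate beats any single replicate in RMSE
  set.seed(5)
  truth <- 400
  err <- replicate(300, {
    qs <- lapply(1:3, function(i)
      estimate_concentration(generate_droplet_assay(truth)))
    c(merged = merge_technical_replicates(qs)$concentration - truth,
      single = qs[[1]]$concentration - truth)
  })
  expect_lt(sqrt(mean(err["merged", ]^2)), sqrt(mean(err["single", ]^2)))
})

test_that("droplet tables quantify per sample and survive a CSV round trip", {
  set.seed(6)
  cells <- replicate(100, genome_pool(300, 100), simplify = FALSE)
  lys <- build_lysate(cells, ploidy_per_cell = 4, reaction_volume = 5)
  expect_equal(lys$template_count[lys$target == "nd1"], 100 * 400)
  expect_equal(lys$template_count[lys$target == "del"], 100 * 100)
  expect_equal(lys$template_count[lys$target == "cox4"], 400)
  # deletion genomes can be excluded from the total-mtDNA assay
  lys2 <- build_lysate(cells, 4, 5, nd1_detects_deletion = FALSE)
  expect_equal(lys2$template_count[lys2$target == "nd1"], 100 * 300)
  drops <- droplets_from_lysate(lys, sample_id = "S1")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(drops, f, row.names = FALSE)
  back <- read_droplet_table(f)
  q <- quantify_droplet_table(back)
  expect_setequal(q$target, c("nd1", "del", "wt", "cox4"))
  expect_equal(q$n_technical, rep(3L, 4))
  # recovered heteroplasmy ~25%
  h <- heteroplasmy_percent(q$concentration[q$target == "del"],
                            q$concentration[q$target == "wt"])
  expect_equal(h, 25, tolerance = 0.05)
})
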