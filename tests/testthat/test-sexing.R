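round4 <- function(x) sign(x) * floor(abs(x) * 1e4 + 0.5) / 1e4

test_that("R_Y reproduces published confidence bounds from raw counts", {
  e1 <- compute_ry(11512, 1133)
  expect_equal(round4(e1$estimate), 0.0896)
  expect_equal(round4(e1$ci_low), 0.0846)
  expect_equal(round4(e1$ci_high), 0.0946)
  expect_equal(e1$call, "male")

  e2 <- compute_ry(6688, 637)
  expect_equal(round4(e2$ci_low), 0.0805)
  expect_equal(round4(e2$ci_high), 0.0934)
  expect_equal(e2$call, "male")
})

test_that("R_Y basic properties hold", {
  expect_error(compute_ry(0, 0), "no sex-chromosome reads")
  z <- compute_ry(1000, 0)
  expect_equal(z$estimate, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  expect_equal(z$call, "female")
  # symmetry: swapping X and Y counts mirrors the estimate
  a <- compute_ry(900, 100); b <- compute_ry(100, 900)
  expect_equal(a$estimate + b$estimate, 1)
  # Wald CI width scales as 1 / sqrt(n)
  w1 <- with(compute_ry(900, 100), ci_high - ci_low)
  w4 <- with(compute_ry(3600, 400), ci_high - ci_low)
  expect_equal(w1 / w4, 2, tolerance = 1e-12)
  # the CI never escapes [0, 1]
  tight <- compute_ry(2, 2)
  expect_gte(tight$ci_low, 0)
  expect_lte(tight$ci_high, 1)
})

test_that("R_X hits the XX and XY expectations on noiseless tables", {
  lengths <- stats::setNames(rep(1e6, 23), c(paste0("chr", 1:22), "chrX"))
  xx <- chrom_count_table(stats::setNames(rep(100, 23), names(lengths)),
                          lengths)
  exx <- compute_rx(xx)
  expect_equal(exx$estimate, 1)
  expect_equal(exx$se, 0)
  expect_equal(exx$call, "female")

  counts <- stats::setNames(c(rep(100, 22), 50), names(lengths))
  exy <- compute_rx(chrom_count_table(counts, lengths))
  expect_equal(exy$estimate, 0.5)
  expect_equal(exy$call, "male")
})

test_that("R_X matches an independent spreadsheet-style computation", {
  set.seed(42)
  chroms <- c(paste0("chr", 1:22), "chrX")
  counts <- stats::setNames(sample(50:500, 23), chroms)
  lengths <- stats::setNames(sample(1e5:1e6, 23), chroms)
  est <- compute_rx(chrom_count_table(counts, lengths))
  # oracle: explicit per-autosome arithmetic
  dx <- counts[["chrX"]] / lengths[["chrX"]]
  r <- vapply(paste0("chr", 1:22), function(ch)
    dx / (counts[[ch]] / lengths[[ch]]), numeric(1))
  expect_equal(est$estimate, mean(r), tolerance = 1e-12)
  expect_equal(est$se, stats::sd(r) / sqrt(22), tolerance = 1e-12)
  expect_equal(est$ci_low, mean(r) - 1.96 * stats::sd(r) / sqrt(22),
               tolerance = 1e-12)
  expect_equal(est$ci_high, mean(r) + 1.96 * stats::sd(r) / sqrt(22),
               tolerance = 1e-12)
})

test_that("R_X excludes empty autosomes and demands enough of them", {
  chroms <- c(paste0("chr", 1:22), "chrX")
  lengths <- stats::setNames(rep(1e6, 23), chroms)
  counts <- stats::setNames(rep(100, 23), chroms)
  counts["chr7"] <- 0
  expect_warning(est <- compute_rx(chrom_count_table(counts, lengths)),
                 "chr7")
  expect_equal(est$n_autosomes, 21L)
  counts[paste0("chr", 1:21)] <- 0
  expect_error(suppressWarnings(compute_rx(chrom_count_table(counts, lengths))),
               "fewer than 2")
  expect_error(compute_rx(chrom_count_table(c(chrX = 5), c(chrX = 1e6))),
               "autosome")
})

test_that("threshold calls follow the published CI rules", {
  mk <- function(method, lo, hi)
    structure(list(method = method, estimate = (lo + hi) / 2, se = NA,
                   ci_low = lo, ci_high = hi, n_used = 1L,
                   call = "indeterminate"), class = "sex_estimate")
  expect_equal(assign_sex(mk("RY", 0.0846, 0.0946)), "male")
  expect_equal(assign_sex(mk("RY", 0.001, 0.010)), "female")
  expect_equal(assign_sex(mk("RY", 0.010, 0.020)), "indeterminate")
  expect_equal(assign_sex(mk("RY", 0.050, 0.080)), "indeterminate")
  expect_equal(assign_sex(mk("RX", 0.33, 0.40)), "male")
  expect_equal(assign_sex(mk("RX", 0.85, 0.95)), "female")
  expect_equal(assign_sex(mk("RX", 0.70, 0.90)), "indeterminate")
  # boundaries are strict inequalities
  expect_equal(assign_sex(mk("RY", 0.0, 0.016)), "indeterminate")
  expect_equal(assign_sex(mk("RX", 0.5, 0.60)), "indeterminate")
})

test_that("paired sex reports call simulated karyotypes correctly", {
  pars <- damage_params(delta = 0.27, phi = 0.5, epsilon = 0.001)
  run <- function(seed, karyotype) {
    cfg <- small_cfg(seed = seed, karyotype = karyotype, n_reads = 100000,
                     udg = "none")
    sim <- simulate_reads(cfg, simulate_reference(cfg))
    list(rep = sex_report(filter_reads(sim$reads), cfg$chrom_lengths, pars),
         cfg = cfg)
  }
  xy <- run(51, "XY")$rep
  expect_equal(xy$all$ry$call, "male")
  expect_equal(xy$all$rx$call, "male")
  expect_equal(xy$damaged$ry$call, "male")
  expect_equal(xy$damaged$rx$call, "male")

  xx <- run(52, "XX")$rep
  expect_equal(xx$all$ry$call, "female")
  expect_equal(xx$all$rx$call, "female")
  expect_equal(xx$damaged$ry$call, "female")
  expect_equal(xx$damaged$rx$call, "female")
  # report accounting: damage-selected reads are a subset
  expect_lte(xx$damaged$n_reads, xx$all$n_reads)
})

test_that("damage selection suppresses undamaged contaminant Y signal", {
  # XX individual contaminated by an undamaged XY modern source
  pars <- damage_params(delta = 0.27, phi = 0.5, epsilon = 0.001)
  cfg <- small_cfg(seed = 53, karyotype = "XX", n_reads = 30000,
                   udg = "none", contam_fraction = 0.3,
                   contam_karyotype = "XY")
  sim <- simulate_reads(cfg, simulate_reference(cfg))
  reads <- filter_reads(sim$reads)
  rep <- sex_report(reads, cfg$chrom_lengths, pars)
  expect_gt(rep$all$ry$estimate, 0)
  expect_lt(rep$damaged$ry$estimate, rep$all$ry$estimate)
})
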