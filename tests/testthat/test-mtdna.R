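test_that("pileup assigns every aligned base to one circular position", {
  ref <- strrep("ACGT", 25)  # 100 bp circular reference
  one <- make_reads(strrep("A", 40), chrom = "chrM", start = 10L)
  pu <- build_pileup(one, ref)
  expect_equal(sum(pu$depth), 40)
  expect_equal(unname(pu$depth[11:50]), rep(1L, 40))
  expect_equal(sum(pu$depth[-(11:50)]), 0)

  # a read spanning the origin wraps: last 10 and first 30 positions
  wrap <- make_reads(strrep("A", 40), chrom = "chrM", start = 90L)
  pw <- build_pileup(wrap, ref)
  expect_equal(unname(pw$depth[91:100]), rep(1L, 10))
  expect_equal(unname(pw$depth[1:30]), rep(1L, 30))
  expect_equal(sum(pw$depth), 40)

  expect_error(build_pileup(wrap, ref, circular = FALSE), "beyond")

  # conservation on simulator output
  cfg <- small_cfg(seed = 61, n_reads = 1500, mt = 3000)
  sim <- simulate_reads(cfg, simulate_reference(cfg), chroms = "chrM")
  pu2 <- build_pileup(sim$reads, simulate_reference(cfg)$genome[["chrM"]])
  expect_equal(sum(pu2$depth), sum(sim$reads$length))
})

test_that("consensus calling applies the depth-5 / 80% rule at boundaries", {
  p <- pileup_from_counts(rbind(
    c(0, 1, 0, 4),    # T at 4/5 = 0.8 -> called T
    c(0, 0, 0, 4),    # depth 4 -> low_depth
    c(0, 3, 0, 7),    # 7/10 = 0.7 -> low_frequency
    c(5, 0, 0, 5),    # exact tie -> never called
    c(0, 0, 12, 0)))  # clean G
  cons <- call_consensus(p, min_depth = 5, min_freq = 0.8)
  expect_equal(cons$sequence, "TNNNG")
  expect_equal(cons$status,
               c("called", "low_depth", "low_frequency", "low_frequency",
                 "called"))
})

test_that("tightening consensus thresholds never converts N into a call", {
  cfg <- small_cfg(seed = 62, n_reads = 700, mt = 2000, udg = "none")
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, ref, chroms = "chrM")
  pu <- build_pileup(sim$reads, ref$genome[["chrM"]])
  loose <- call_consensus(pu, min_depth = 5, min_freq = 0.8)
  strict <- call_consensus(pu, min_depth = 8, min_freq = 0.9)
  loose_called <- strsplit(loose$sequence, "")[[1]] != "N"
  strict_called <- strsplit(strict$sequence, "")[[1]] != "N"
  expect_true(all(which(strict_called) %in% which(loose_called)))
  # strict callable positions agree with loose calls where both called
  ls <- strsplit(loose$sequence, "")[[1]]
  ss <- strsplit(strict$sequence, "")[[1]]
  both <- strict_called & loose_called
  expect_equal(ss[both], ls[both])
})

test_that("coverage statistics summarise the pileup", {
  p <- pileup_from_counts(matrix(c(0, 0, 0, 7), nrow = 16, ncol = 4,
                                 byrow = TRUE))
  expect_equal(coverage_stats(p), c(min = 7, max = 7, mean = 7))
  # 1,800,033 bases over a 16,569 bp mitogenome average to 108.6x
  depth <- rep(108L, 16569)
  depth[seq_len(1800033 - 108 * 16569)] <- 109L
  p2 <- structure(list(ref_length = 16569, depth = depth), class = "pileup")
  expect_equal(coverage_stats(p2)[["mean"]], 108.6)
})

test_that("contamination-free mitochondrial consensus recovers the haplotype", {
  cfg <- small_cfg(seed = 63, n_reads = 2200, mt = 3000, udg = "none")
  cfg$endo_mt_variants <- 0  # helper default; explicit here for clarity
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, ref, chroms = "chrM")
  pu <- build_pileup(sim$reads, ref$genome[["chrM"]])
  cons <- call_consensus(pu)
  expect_equal(cons$sequence, ref$endo_mt)
  expect_true(all(cons$status == "called"))
})

test_that("mixture limits: pure endogenous gives ~0, pure contaminant ~1", {
  pars <- damage_params(delta = 0.27, phi = 0.5, epsilon = 0.001)
  set.seed(64)
  cons <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  panel <- adnasex:::mutate_sites(cons, seq(10, 990, by = 40))
  # every read matches the consensus exactly and covers diagnostic sites
  starts <- as.integer(seq(0, 950, by = 20))
  endo_reads <- make_reads(substring(cons, starts + 1, starts + 50),
                           chrom = "chrM", start = starts)
  e0 <- estimate_contamination(endo_reads, cons, panel, pars, n_boot = 0)
  expect_lte(e0$proportion, 1e-6)
  # reads generated verbatim from a panel haplotype instead
  cont_reads <- make_reads(substring(panel, starts + 1, starts + 50),
                           chrom = "chrM", start = starts)
  e1 <- estimate_contamination(cont_reads, cons, panel, pars, n_boot = 0)
  expect_gte(e1$proportion, 1 - 1e-6)
})

test_that("contamination estimation is order-invariant and panel-stable", {
  pars <- damage_params(delta = 0.27, phi = 0.5, epsilon = 0.001)
  cfg <- sim_config(seed = 66, n_reads = 6000, contam_fraction = 0.15,
                    chrom_lengths = small_sim_lengths(3000),
                    endo_mt_variants = 0)
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, ref, chroms = "chrM")
  pu <- build_pileup(sim$reads, ref$genome[["chrM"]])
  cons <- call_consensus(pu)
  e <- estimate_contamination(sim$reads, cons, ref$mito_contaminants, pars,
                              n_boot = 0)
  shuf <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  es <- estimate_contamination(shuf, cons, ref$mito_contaminants, pars,
                               n_boot = 0)
  expect_equal(es$proportion, e$proportion, tolerance = 1e-9)
  # duplicating the source haplotype in the panel barely moves the estimate
  dup_panel <- c(ref$mito_contaminants, ref$mito_contaminants[1])
  ed <- estimate_contamination(sim$reads, cons, dup_panel, pars, n_boot = 0)
  expect_lt(abs(ed$proportion - e$proportion), 0.01)
  # CI invariants
  eb <- estimate_contamination(sim$reads, cons, ref$mito_contaminants, pars,
                               n_boot = 50, seed = 7)
  expect_lte(eb$ci_low, eb$proportion)
  expect_gte(eb$ci_high, eb$proportion)
  expect_gte(eb$ci_low, 0)
  expect_lte(eb$ci_high, 1)
})

test_that("contamination is unidentifiable without diagnostic overlap", {
  pars <- damage_params(delta = 0.27, phi = 0.5, epsilon = 0.001)
  ref <- strrep("ACGT", 250)
  reads <- make_reads(rep(substr(ref, 1, 40), 5), chrom = "chrM",
                      start = 0L)
  # panel identical to the consensus -> no diagnostic sites anywhere
  expect_error(estimate_contamination(reads, ref, ref, pars, n_boot = 0),
               "unidentifiable")
})
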