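test_that("terminal substitution frequencies are counted per molecule end", {
  reads <- make_reads(seq = c("TA", "CA", "AA", "TG"),
                      ref = c("CA", "CA", "AA", "TG"))
  prof <- damage_profile(reads, max_offset = 4)
  # one C->T among two reference-C opportunities at 5' offset 0
  expect_equal(prof$five_prime$opportunities[1], 2L)
  expect_equal(prof$five_prime$events[1], 1L)
  expect_equal(prof$five_prime$frequency[1], 0.5)
  # the TG read has a reference G at 3' offset 0, intact
  expect_equal(prof$three_prime$opportunities[1], 1L)
  expect_equal(prof$three_prime$events[1], 0L)
  # offsets beyond the longest read are undefined, not zero
  expect_true(all(is.na(prof$five_prime$frequency[3:4])))

  nomm <- make_reads(seq = c("CAGT", "GTCA"))
  p2 <- damage_profile(nomm, max_offset = 4)
  expect_true(all(p2$five_prime$frequency[p2$five_prime$opportunities > 0] == 0))
})

test_that("minus-strand reads are re-oriented to the molecule 5' end", {
  # molecule: ref CAA -> read TAA (C->T at molecule offset 0); stored in
  # reference orientation as ref TTG, seq TTA on the minus strand
  rd <- make_reads(seq = "TTA", ref = "TTG", strand = "-")
  prof <- damage_profile(rd, max_offset = 3)
  expect_equal(prof$five_prime$events[1], 1L)
  expect_equal(prof$five_prime$frequency[1], 1)
  expect_equal(prof$three_prime$opportunities[1], 0L)
})

test_that("reads without reference bases are skipped with a warning", {
  rd <- make_reads(seq = c("CA", "CA"), ref = c("CA", NA))
  expect_warning(prof <- damage_profile(rd, max_offset = 2), "skipped")
  expect_equal(prof$five_prime$opportunities[1], 1L)
})

test_that("profile frequencies converge to the simulated damage curve", {
  cfg <- small_cfg(seed = 31, n_reads = 20000, udg = "none")
  sim <- simulate_reads(cfg, simulate_reference(cfg))
  prof <- damage_profile(sim$reads)
  for (z in 0:2) {
    expected <- cfg$delta * cfg$phi^z + cfg$epsilon
    row <- prof$five_prime[z + 1, ]
    se <- sqrt(expected * (1 - expected) / row$opportunities)
    expect_lt(abs(row$frequency - expected), 3 * se)
    row3 <- prof$three_prime[z + 1, ]
    se3 <- sqrt(expected * (1 - expected) / row3$opportunities)
    expect_lt(abs(row3$frequency - expected), 3 * se3)
  }
})

test_that("the geometric damage model is recovered from profiles", {
  z <- 0:9
  exact <- structure(list(
    five_prime = data.frame(offset = z, opportunities = 1000L,
                            events = NA_integer_,
                            frequency = 0.3 * 0.5^z + 0.01),
    three_prime = data.frame(offset = z, opportunities = 1000L,
                             events = NA_integer_,
                             frequency = 0.3 * 0.5^z + 0.01),
    max_offset = 10L, n_reads = 1000L), class = "damage_profile")
  fit <- fit_damage_params(exact)
  expect_equal(fit$delta, 0.3, tolerance = 1e-6)
  expect_equal(fit$phi, 0.5, tolerance = 1e-6)
  expect_equal(fit$epsilon, 0.01, tolerance = 1e-6)

  flat <- exact
  flat$five_prime$frequency <- 0.01
  ffit <- fit_damage_params(flat)
  expect_lt(ffit$delta, 1e-3)
  expect_equal(ffit$epsilon, 0.01, tolerance = 1e-3)

  few <- exact
  few$five_prime$frequency <- NA_real_
  expect_error(fit_damage_params(few), "3 defined")

  # simulation recovery at realistic scale
  cfg <- small_cfg(seed = 32, n_reads = 50000, udg = "none")
  sim <- simulate_reads(cfg, simulate_reference(cfg))
  sfit <- fit_damage_params(damage_profile(sim$reads))
  expect_lt(abs(sfit$delta - cfg$delta) / cfg$delta, 0.2)
})

test_that("PMD scores match the likelihood-ratio definition", {
  pars <- damage_params(delta = 0.3, phi = 0.5, epsilon = 0.01)
  # no C or G anywhere in the reference span -> exactly 0
  expect_equal(pmd_score(make_reads("ATTA"), pars), 0)
  # single C->T at offset 0: ln(0.31 / 0.01)
  one <- make_reads(seq = "TAAAA", ref = "CAAAA")
  expect_equal(pmd_score(one, pars), log(0.31 / 0.01), tolerance = 1e-12)
  # an intact C-rich read scores negative
  intact <- make_reads(seq = strrep("C", 20))
  expect_lt(pmd_score(intact, pars), 0)
  # reads without reference bases score 0
  expect_equal(pmd_score(make_reads("TTTT", ref = NA), pars), 0)
})

test_that("PMD scores equal brute-force per-column summation", {
  # independent oracle: walk every matched column of the molecule once
  oracle <- function(seq, ref, strand, pars, max_offset = 25) {
    if (strand == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    }
    s <- strsplit(seq, "")[[1]]; r <- strsplit(ref, "")[[1]]
    L <- length(s); total <- 0
    for (i in seq_len(L)) {
      z5 <- i - 1L; z3 <- L - i
      if (r[i] == "C" && z5 < max_offset) {
        D <- pars$delta * pars$phi^z5 + pars$epsilon
        if (s[i] == "T") total <- total + log(D / pars$epsilon)
        if (s[i] == "C") total <- total + log((1 - D) / (1 - pars$epsilon))
      }
      if (r[i] == "G" && z3 < max_offset) {
        D <- pars$delta * pars$phi^z3 + pars$epsilon
        if (s[i] == "A") total <- total + log(D / pars$epsilon)
        if (s[i] == "G") total <- total + log((1 - D) / (1 - pars$epsilon))
      }
    }
    total
  }
  pars <- damage_params(delta = 0.25, phi = 0.4, epsilon = 0.02)
  set.seed(99)
  for (i in 1:25) {
    L <- sample(1:10, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    strand <- sample(c("+", "-"), 1)
    rd <- make_reads(seq = seq, ref = ref, strand = strand)
    expect_equal(pmd_score(rd, pars), oracle(seq, ref, strand, pars),
                 tolerance = 1e-12)
  }
})

test_that("damage filtering thresholds behave monotonically", {
  pars <- damage_params(delta = 0.3, phi = 0.5, epsilon = 0.01)
  one <- make_reads(seq = "TAAAA", ref = "CAAAA")   # score ~3.43
  zero <- make_reads("ATTA")                        # score 0
  both <- merge_datasets(one, zero)
  expect_equal(filter_damaged(both, pars, 3)$seq, "TAAAA")
  expect_equal(nrow(filter_damaged(zero, pars, 3)), 0L)
  # -Inf threshold is the identity; raising the threshold never adds reads
  cfg <- small_cfg(seed = 33, n_reads = 2000, udg = "none")
  sim <- simulate_reads(cfg, simulate_reference(cfg))
  expect_equal(nrow(filter_damaged(sim$reads, pars, -Inf)), 2000L)
  kept <- vapply(c(0, 1, 3, 5), function(th)
    nrow(filter_damaged(sim$reads, pars, th)), numeric(1))
  expect_true(all(diff(kept) <= 0))
  ids3 <- filter_damaged(sim$reads, pars, 3)$read_id
  ids1 <- filter_damaged(sim$reads, pars, 1)$read_id
  expect_true(all(ids3 %in% ids1))
})

test_that("damage filtering enriches for genuinely damaged molecules", {
  pars <- damage_params(delta = 0.27, phi = 0.5, epsilon = 0.001)
  ancient <- small_cfg(seed = 34, n_reads = 5000, udg = "none")
  modern <- small_cfg(seed = 35, n_reads = 5000, udg = "full")
  a <- simulate_reads(ancient, simulate_reference(ancient))$reads
  m <- simulate_reads(modern, simulate_reference(modern))$reads
  m$read_id <- paste0("modern_", m$read_id)
  mix <- merge_datasets(a, m)
  kept <- filter_damaged(mix, pars, 3)
  frac_in <- 0.5
  frac_kept <- mean(!grepl("^modern_", kept$read_id))
  expect_gt(frac_kept, frac_in)
})
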