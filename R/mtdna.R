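# mitochondrial pileup over a circular reference, consensus calling,
# coverage summary and two-component EM contamination estimation

#' Build a base pileup over a (circular) mitochondrial reference
#'
#' Assigns every aligned base of every read to exactly one reference
#' position. On a circular reference, reads may overhang the declared length
#' and wrap around the origin (position arithmetic is modulo the reference
#' length); on a linear reference an overhanging read is an error.
#'
#' @param reads [aligned_reads()] mapped to the mitochondrial reference
#'   (a single chromosome; mixed chromosomes are an error).
#' @param ref The reference: a single sequence as character string, a
#'   1-sequence `DNAStringSet`/FASTA path, or a named character vector.
#' @param circular Is the reference circular (default `TRUE`)?
#' @return A `pileup`: list with `ref_length`, `counts` (5 x L matrix with
#'   rows A, C, G, T, other), `depth` (length-L vector) and `ref` (reference
#'   as character vector of bases).
#' @export
build_pileup <- function(reads, ref, circular = TRUE) {
  if (is.character(ref) && length(ref) == 1L && is.null(names(ref)) &&
      !file.exists(ref)) {
    refseq <- toupper(ref)
  } else {
    r <- load_reference(ref)
    if (length(r) != 1L) stop("pileup reference must contain exactly one sequence")
    refseq <- r[[1]]
  }
  L <- nchar(refseq)
  if (nrow(reads) && length(unique(reads$chrom)) > 1L)
    stop("pileup reads must all map to one chromosome; got: ",
         paste(unique(reads$chrom), collapse = ", "))
  if (!circular && nrow(reads) && any(reads$start + reads$length > L))
    stop("read extends beyond the reference end; set circular = TRUE to wrap")
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "other"), NULL))
  if (nrow(reads)) {
    pos0 <- (rep(reads$start, reads$length) + sequence(reads$length) - 1L) %% L
    chars <- unlist(strsplit(reads$seq, ""), use.names = FALSE)
    bi <- match(chars, c("A", "C", "G", "T"))
    bi[is.na(bi)] <- 5L
    counts <- matrix(tabulate(pos0 * 5L + bi, nbins = 5L * L), nrow = 5L,
                     dimnames = dimnames(counts))
  }
  structure(list(ref_length = L, counts = counts, depth = colSums(counts),
                 ref = strsplit(refseq, "")[[1]]),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d bp reference, depth min/mean/max = %d/%.1f/%d\n",
              x$ref_length, min(x$depth), mean(x$depth), max(x$depth)))
  invisible(x)
}

#' Plot per-position coverage
#'
#' @param x A `pileup`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pileup <- function(x, ...) {
  graphics::plot(seq_len(x$ref_length), x$depth, type = "h", col = "grey40",
                 xlab = "reference position (bp)", ylab = "coverage", ...)
  invisible(x)
}

#' Call a consensus sequence from a pileup
#'
#' A position is called to its majority base only when depth is at least
#' `min_depth` and the majority base's frequency (relative to total depth)
#' is at least `min_freq`; otherwise it is reported as `N` with the failing
#' criterion recorded. A tie between top bases is never called (with
#' `min_freq > 0.5` a tie always fails the frequency rule).
#'
#' @param pileup A [build_pileup()] result.
#' @param min_depth Minimum read depth for a call (default 5).
#' @param min_freq Minimum majority-base frequency for a call (default 0.80);
#'   must be in `(0.5, 1]`.
#' @return A `consensus_call`: list with `sequence` (single string over
#'   ACGTN), `status` (per-position: `called`, `low_depth`, `low_frequency`),
#'   `min_depth`, `min_freq`.
#' @export
call_consensus <- function(pileup, min_depth = 5, min_freq = 0.80) {
  stopifnot(inherits(pileup, "pileup"), min_depth >= 1,
            min_freq > 0.5, min_freq <= 1)
  acgt <- pileup$counts[1:4, , drop = FALSE]
  top_i <- max.col(t(acgt), ties.method = "first")
  top_n <- acgt[cbind(top_i, seq_len(pileup$ref_length))]
  n_at_top <- colSums(acgt == rep(top_n, each = 4L) & acgt > 0L)
  tie <- n_at_top > 1L
  depth <- pileup$depth
  freq <- ifelse(depth > 0, top_n / depth, 0)
  ok_depth <- depth >= min_depth
  ok_freq <- freq >= min_freq & !tie
  called <- ok_depth & ok_freq
  status <- ifelse(called, "called", ifelse(!ok_depth, "low_depth",
                                            "low_frequency"))
  base <- ifelse(called, c("A", "C", "G", "T")[top_i], "N")
  structure(list(sequence = paste(base, collapse = ""),
                 status = status, min_depth = min_depth, min_freq = min_freq),
            class = "consensus_call")
}

#' @export
print.consensus_call <- function(x, ...) {
  tab <- table(factor(x$status, c("called", "low_depth", "low_frequency")))
  cat(sprintf(paste0("Consensus over %d bp (min depth %g, min frequency ",
                     "%g): %d called, %d low-depth, %d low-frequency\n"),
              nchar(x$sequence), x$min_depth, x$min_freq,
              tab[["called"]], tab[["low_depth"]], tab[["low_frequency"]]))
  invisible(x)
}

#' Coverage summary of a pileup
#'
#' @param pileup A [build_pileup()] result.
#' @return Named vector `min`, `max`, `mean` (mean depth = total aligned
#'   bases / reference length, reported to 1 decimal).
#' @export
coverage_stats <- function(pileup) {
  stopifnot(inherits(pileup, "pileup"))
  c(min = min(pileup$depth), max = max(pileup$depth),
    mean = round(sum(pileup$depth) / pileup$ref_length, 1))
}

# mixture EM over per-read log-likelihoods. `ll` is an n x (K+1) matrix:
# column 1 the endogenous component, columns 2..K+1 the contaminant panel
# haplotypes. Component weights are all fitted; the contamination proportion
# is the total weight off component 1. Fitting per-haplotype weights (rather
# than an equal-weight panel average) avoids the -log(K) dilution penalty an
# averaged contaminant component imposes on reads from the true contaminant.
# The component log-likelihoods are fixed across iterations, so they are
# row-rescaled and exponentiated once; each EM step is then one
# matrix-vector product. `counts` supports the multinomial form of the
# non-parametric bootstrap (resampled read multiplicities) without copying
# the likelihood matrix.
contam_em <- function(ll, tol = 1e-10, max_iter = 10000L, init = NULL,
                      counts = NULL) {
  K1 <- ncol(ll)
  n <- nrow(ll)
  M <- ll[, 1L]
  for (k in seq_len(K1)[-1L]) M <- pmax(M, ll[, k])
  P <- exp(ll - M)
  if (is.null(counts)) counts <- rep(1, n)
  ntot <- sum(counts)
  v <- if (is.null(init)) c(0.5, rep(0.5 / (K1 - 1L), K1 - 1L)) else init
  obj_old <- NA_real_
  base <- sum(counts * M)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(P %*% v)
    obj <- sum(counts * log(denom)) + base
    if (!is.na(obj_old))
      stopifnot(obj >= obj_old - 1e-9 * abs(obj_old) - 1e-12)  # EM monotone
    cd <- counts / denom
    v_new <- v * as.numeric(crossprod(P, cd)) / ntot
    done <- !is.na(obj_old) &&
      (max(abs(v_new - v)) < 1e-9 ||
         abs(obj - obj_old) <= tol * (abs(obj_old) + 1e-12))
    v <- v_new
    obj_old <- obj
    if (done) break
  }
  list(w = 1 - v[1L], weights = v, loglik = obj_old, iters = it)
}

# per-column endogenous mismatch probability in molecule orientation:
# D(z5) at consensus C, D(z3) at consensus G, epsilon elsewhere
endo_mismatch_prob <- function(mol_cons, z5, z3, params, max_offset) {
  p <- rep(params$epsilon, length(mol_cons))
  cidx <- mol_cons == "C"
  gidx <- mol_cons == "G"
  p[cidx] <- damage_prob(z5[cidx], params, max_offset)
  p[gidx] <- damage_prob(z3[gidx], params, max_offset)
  p
}

#' Estimate the modern contamination fraction of mitochondrial reads
#'
#' Maximum-likelihood mixture: each read is modelled as either endogenous -
#' matching the sample consensus, with mismatch probability given by the
#' damage model at terminal C/G positions and `epsilon` elsewhere - or
#' contaminant, drawn from one of a panel of candidate modern haplotypes
#' with mismatch probability `epsilon` everywhere. Per-haplotype panel
#' weights are fitted alongside the endogenous weight; the contamination
#' proportion is the total weight off the endogenous component. The mixture
#' is fitted by EM (relative tolerance
#' 1e-8; the log-likelihood is asserted non-decreasing at every iteration)
#' and its 95% CI obtained by non-parametric bootstrap over reads.
#'
#' Likelihoods are computed on per-column match/mismatch indicators, so base
#' qualities are not required. Positions where the consensus is `N` are
#' ignored. If no read overlaps any site at which the consensus differs from
#' a panel sequence, the mixture is unidentifiable and an error is raised.
#'
#' @param reads [aligned_reads()] mapped to the mitochondrial reference.
#' @param consensus A [call_consensus()] result or a plain sequence string
#'   of the endogenous haplotype.
#' @param panel Candidate contaminant haplotypes: FASTA path,
#'   `DNAStringSet`, or character vector of full-length sequences.
#' @param params A [damage_params()] object describing the endogenous
#'   library's damage; its `epsilon` is also the contaminant mismatch rate.
#' @param n_boot Bootstrap replicates for the CI (default 200).
#' @param seed Optional integer seed for the bootstrap.
#' @param max_offset Terminal window of the damage model.
#' @return A `contam_estimate`: list with `proportion`, `ci_low`, `ci_high`,
#'   `n_reads`, `n_informative`, `panel_size`, `loglik`, `em_iters`.
#' @export
estimate_contamination <- function(reads, consensus, panel, params,
                                   n_boot = 200, seed = NULL,
                                   max_offset = 25) {
  stopifnot(inherits(params, "damage_params"))
  cons <- if (inherits(consensus, "consensus_call")) consensus$sequence
          else as.character(consensus)
  cons <- strsplit(toupper(cons), "")[[1]]
  L <- length(cons)
  if (is.character(panel) && length(panel) == 1L && file.exists(panel))
    panel <- Biostrings::readDNAStringSet(panel)
  panel <- toupper(as.character(panel))
  if (length(panel) < 1L) stop("contaminant panel is empty")
  if (any(nchar(panel) != L))
    stop("panel sequences must match the consensus length (", L, " bp)")
  if (nrow(reads) == 0L) stop("no reads supplied")
  eps <- params$epsilon
  if (eps <= 0) stop("params$epsilon must be > 0 for likelihood computation")

  # flatten reads to one row per aligned base
  n <- nrow(reads)
  ri <- rep(seq_len(n), reads$length)
  j <- sequence(reads$length) - 1L           # 0-based column within read
  pos <- (rep(reads$start, reads$length) + j) %% L
  len <- rep(reads$length, reads$length)
  plus <- rep(reads$strand == "+", reads$length)
  z5 <- ifelse(plus, j, len - 1L - j)        # molecule 5' offset
  z3 <- len - 1L - z5
  obs <- unlist(strsplit(reads$seq, ""), use.names = FALSE)
  cc <- cons[pos + 1L]
  known <- cc != "N"
  # consensus base in molecule orientation decides damage eligibility
  mol_cons <- ifelse(plus, cc, chartr("ACGT", "TGCA", cc))

  p_endo <- endo_mismatch_prob(mol_cons, z5, z3, params, max_offset)
  mm_endo <- obs != cc
  ll_endo_flat <- ifelse(known, log(ifelse(mm_endo, p_endo, 1 - p_endo)), 0)
  ll_endo <- as.numeric(rowsum(ll_endo_flat, ri, reorder = TRUE))

  # one contaminant component per panel haplotype, weights fitted by EM
  panel_mat <- matrix(unlist(strsplit(panel, ""), use.names = FALSE),
                      nrow = L)
  K <- ncol(panel_mat)
  ll_k <- matrix(NA_real_, n, K)
  informative <- logical(n)
  for (k in seq_len(K)) {
    pc <- panel_mat[pos + 1L, k]
    mm <- obs != pc
    llk_flat <- ifelse(known, ifelse(mm, log(eps), log1p(-eps)), 0)
    ll_k[, k] <- as.numeric(rowsum(llk_flat, ri, reorder = TRUE))
    diag_flat <- known & pc != cc
    informative <- informative |
      as.numeric(rowsum(as.numeric(diag_flat), ri, reorder = TRUE)) > 0
  }
  if (!any(informative))
    stop("contamination unidentifiable: no read overlaps a site where the ",
         "consensus differs from the panel")

  ll_all <- cbind(ll_endo, ll_k)
  em <- contam_em(ll_all)
  # non-parametric bootstrap over reads in multinomial form: each replicate
  # refits the full mixture (the weight likelihood is concave, so the
  # warm start only saves iterations, it cannot change the optimum)
  boot <- if (n_boot > 0) {
    init <- pmax(em$weights, 1e-8)   # keep boundary components revivable
    init <- init / sum(init)
    run_boot <- function() {
      vapply(seq_len(n_boot), function(b) {
        m <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
        contam_em(ll_all, init = init, counts = m)$w
      }, numeric(1))
    }
    if (!is.null(seed)) {
      withr_seed <- function(code) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
        code()
      }
      withr_seed(run_boot)
    } else run_boot()
  } else numeric(0)
  ci <- if (length(boot)) stats::quantile(boot, c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(proportion = em$w,
                 ci_low = min(ci[1], em$w, na.rm = TRUE),
                 ci_high = max(ci[2], em$w, na.rm = TRUE),
                 n_reads = n, n_informative = sum(informative),
                 panel_size = length(panel),
                 panel_weights = stats::setNames(em$weights[-1L],
                                                 names(panel)),
                 loglik = em$loglik, em_iters = em$iters, n_boot = n_boot),
            class = "contam_estimate")
}

#' @export
print.contam_estimate <- function(x, ...) {
  cat(sprintf(paste0("Contamination: %.2f%% (bootstrap 95%% CI ",
                     "%.2f-%.2f%%), %d reads (%d informative), panel of %d\n"),
              100 * x$proportion, 100 * x$ci_low, 100 * x$ci_high,
              x$n_reads, x$n_informative, x$panel_size))
  invisible(x)
}
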