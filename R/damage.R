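# terminal deamination profiling, damage-model fitting and PMD-style
# likelihood-ratio read selection
#
# Model: at a reference C observed z positions from the molecule's own 5'
# end, the probability of reading T is D(z) = delta * phi^z + epsilon;
# symmetrically G->A at z positions from the 3' end (double-stranded library
# geometry). epsilon absorbs sequencing error and polymorphism. Beyond
# max_offset the damage term is treated as fully decayed, leaving epsilon.

#' Damage model parameters
#'
#' @param delta Amplitude of terminal deamination probability in `[0, 1]`
#'   (typical no-UDG libraries: 0.2-0.4; partial-UDG: ~0.05-0.1).
#' @param phi Per-position geometric decay factor in `[0, 1)`.
#' @param epsilon Background mismatch probability (sequencing error plus
#'   polymorphism).
#' @return A `damage_params` list.
#' @export
damage_params <- function(delta = 0.27, phi = 0.5, epsilon = 0.01) {
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  if (epsilon < 0 || delta + epsilon > 1) stop("need 0 <= epsilon and delta + epsilon <= 1")
  structure(list(delta = delta, phi = phi, epsilon = epsilon),
            class = "damage_params")
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf("Damage model D(z) = %.4g * %.4g^z + %.4g\n",
              x$delta, x$phi, x$epsilon))
  rn <- attr(x, "residual_norm")
  if (!is.null(rn)) cat(sprintf("  least-squares residual norm: %.3g\n", rn))
  invisible(x)
}

# orient reads so the molecule's own 5' end is at string position 1:
# minus-strand alignments are reverse-complemented
orient_to_molecule <- function(reads) {
  neg <- reads$strand == "-"
  mol_seq <- reads$seq
  mol_ref <- reads$ref_bases
  if (any(neg)) {
    mol_seq[neg] <- revcomp(mol_seq[neg])
    mol_ref[neg] <- revcomp(mol_ref[neg])
  }
  list(seq = mol_seq, ref = mol_ref, len = reads$length)
}

#' Terminal substitution profile
#'
#' Counts C->T substitutions by distance from the molecule's 5' end and
#' G->A substitutions by distance from the 3' end, over reference-C
#' (respectively reference-G) opportunities. Minus-strand alignments are
#' re-oriented so offsets are measured on the original molecule. Reads
#' without reference bases (indels, missing reference) are skipped with a
#' warning. Offsets with zero opportunities have frequency `NA` (undefined),
#' not 0.
#'
#' @param reads An [aligned_reads()] table with `ref_bases`.
#' @param max_offset Number of terminal positions profiled from each end.
#' @return A `damage_profile`: list with elements `five_prime` and
#'   `three_prime`, each a data frame `offset, opportunities, events,
#'   frequency`, plus `max_offset` and `n_reads`.
#' @export
damage_profile <- function(reads, max_offset = 25) {
  usable <- !is.na(reads$ref_bases)
  if (any(!usable))
    warning(sum(!usable), " read(s) without reference bases skipped")
  reads <- reads[usable, , drop = FALSE]
  m <- orient_to_molecule(reads)
  count_end <- function(ref_target, obs_target, from_three) {
    opp <- ev <- integer(max_offset)
    for (z in 0:(max_offset - 1L)) {
      pos <- if (from_three) m$len - z else rep(z + 1L, length(m$len))
      refc <- substr(m$ref, pos, pos)
      obsc <- substr(m$seq, pos, pos)
      at_ref <- refc == ref_target    # "" past either end never matches
      opp[z + 1L] <- sum(at_ref)
      ev[z + 1L] <- sum(at_ref & obsc == obs_target)
    }
    data.frame(offset = 0:(max_offset - 1L), opportunities = opp, events = ev,
               frequency = ifelse(opp > 0, ev / opp, NA_real_))
  }
  structure(list(five_prime = count_end("C", "T", FALSE),
                 three_prime = count_end("G", "A", TRUE),
                 max_offset = max_offset, n_reads = nrow(reads)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("Terminal substitution profile (%d reads, %d offsets per end)\n",
              x$n_reads, x$max_offset))
  f0 <- x$five_prime$frequency[1]
  t0 <- x$three_prime$frequency[1]
  cat(sprintf("  5' C->T at offset 0: %s   3' G->A at offset 0: %s\n",
              format(f0, digits = 3), format(t0, digits = 3)))
  invisible(x)
}

#' Plot a damage profile
#'
#' Base-graphics misincorporation plot: 5' C->T and 3' G->A frequencies
#' against distance from the respective read end.
#'
#' @param x A `damage_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.damage_profile <- function(x, ...) {
  ylim <- range(0, x$five_prime$frequency, x$three_prime$frequency,
                na.rm = TRUE)
  graphics::plot(x$five_prime$offset, x$five_prime$frequency, type = "b",
                 col = "firebrick", pch = 16, ylim = ylim,
                 xlab = "distance from read end (bp)",
                 ylab = "substitution frequency", ...)
  graphics::lines(x$three_prime$offset, x$three_prime$frequency, type = "b",
                  col = "steelblue", pch = 17)
  graphics::legend("topright", legend = c("5' C>T", "3' G>A"),
                   col = c("firebrick", "steelblue"), pch = c(16, 17),
                   bty = "n")
  invisible(x)
}

#' Fit the geometric damage model to a profile
#'
#' Least-squares fit of `frequency(z) = delta * phi^z + epsilon` over the
#' defined 5' offsets of a [damage_profile()]. Parameters are constrained to
#' their valid ranges; the residual norm is attached as an attribute.
#'
#' @param profile A `damage_profile` with at least 3 defined 5' offsets.
#' @return A [damage_params()] object with attribute `residual_norm`. The
#'   fitted `epsilon` is floored at 1e-6 so downstream likelihood ratios
#'   stay finite.
#' @export
fit_damage_params <- function(profile) {
  stopifnot(inherits(profile, "damage_profile"))
  d <- profile$five_prime[!is.na(profile$five_prime$frequency), ]
  if (nrow(d) < 3L)
    stop("need at least 3 defined 5' offsets to fit the damage model")
  z <- d$offset
  f <- d$frequency
  # moment-style starting values: epsilon from the decayed tail, amplitude
  # from the terminal excess, decay from the first two excesses
  tail_n <- max(3L, ceiling(nrow(d) / 3))
  eps0 <- max(mean(utils::tail(f, tail_n)), 1e-6)
  delta0 <- min(max(f[1] - eps0, 1e-6), 1 - eps0)
  phi0 <- 0.5
  if (length(f) >= 2 && f[1] - eps0 > 1e-8 && f[2] - eps0 > 0)
    phi0 <- min(max((f[2] - eps0) / (f[1] - eps0), 0.05), 0.95)
  fit <- tryCatch({
    m <- stats::nls(f ~ delta * phi^z + epsilon,
                    start = list(delta = delta0, phi = phi0, epsilon = eps0),
                    lower = c(0, 0, 0), upper = c(1, 0.999, 1),
                    algorithm = "port",
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
    list(coef = stats::coef(m), rss = sum(stats::resid(m)^2))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) sum((p[1] * p[2]^z + p[3] - f)^2)
    o <- stats::optim(c(delta0, phi0, eps0), obj, method = "L-BFGS-B",
                      lower = c(0, 0, 0), upper = c(1, 0.999, 1))
    fit <- list(coef = stats::setNames(o$par, c("delta", "phi", "epsilon")),
                rss = o$value)
  }
  co <- fit$coef
  # floor epsilon: a literally zero error rate is never plausible and would
  # degenerate the PMD likelihood ratio
  eps <- min(max(co[["epsilon"]], 1e-6), 1)
  delta <- min(max(co[["delta"]], 0), 1 - eps)
  out <- damage_params(delta = delta, phi = min(max(co[["phi"]], 0), 0.999),
                       epsilon = eps)
  attr(out, "residual_norm") <- sqrt(fit$rss)
  out
}

# per-offset damage probability, decayed to epsilon past max_offset
damage_prob <- function(z, params, max_offset = 25) {
  ifelse(z < max_offset, params$delta * params$phi^z + params$epsilon,
         params$epsilon)
}

#' Post-mortem damage score
#'
#' Per-read log-likelihood ratio (natural log) of the damage model against a
#' null (modern) model. At a reference C at 5' offset `z` the damage model
#' assigns C->T probability `D(z) = delta * phi^z + epsilon` while the null
#' assigns `epsilon`; symmetrically G->A from the 3' end. Columns whose
#' reference base is A or T, or whose observed base is neither the reference
#' base nor the deamination product, contribute 0. Reads with no C/G
#' opportunities (or no reference bases) score 0.
#'
#' @param reads An [aligned_reads()] table with `ref_bases`.
#' @param params A [damage_params()] object.
#' @param max_offset Terminal window within which the damage term applies.
#' @return Numeric vector of scores, in nats.
#' @export
pmd_score <- function(reads, params, max_offset = 25) {
  stopifnot(inherits(params, "damage_params"))
  if (params$epsilon <= 0)
    stop("params$epsilon must be > 0: the null model needs a nonzero error rate")
  n <- nrow(reads)
  score <- numeric(n)
  usable <- !is.na(reads$ref_bases)
  if (!any(usable)) return(score)
  m <- orient_to_molecule(reads[usable, , drop = FALSE])
  s <- numeric(sum(usable))
  eps <- params$epsilon
  add_end <- function(s, ref_target, obs_target, from_three) {
    for (z in 0:(max_offset - 1L)) {
      D <- params$delta * params$phi^z + eps
      pos <- if (from_three) m$len - z else rep(z + 1L, length(m$len))
      refc <- substr(m$ref, pos, pos)
      obsc <- substr(m$seq, pos, pos)
      at_ref <- refc == ref_target
      hit <- at_ref & obsc == obs_target
      intact <- at_ref & obsc == ref_target
      s[hit] <- s[hit] + log(D / eps)
      s[intact] <- s[intact] + log((1 - D) / (1 - eps))
    }
    s
  }
  s <- add_end(s, "C", "T", FALSE)
  s <- add_end(s, "G", "A", TRUE)
  score[usable] <- s
  score
}

#' Select reads showing signs of post-mortem damage
#'
#' Retains reads whose [pmd_score()] is at least `threshold` (default 3, the
#' conventional operating point for restricting analyses to molecules
#' unlikely to be modern contaminants). Reads without reference bases score
#' 0 and are therefore removed at any positive threshold.
#'
#' @param reads An [aligned_reads()] table.
#' @param params A [damage_params()] object.
#' @param threshold Minimum score retained (nats).
#' @param return_scores If `TRUE`, attach the per-read scores of the
#'   *retained* reads as attribute `scores`.
#' @param max_offset Terminal window of the damage model.
#' @return Filtered `aligned_reads`.
#' @export
filter_damaged <- function(reads, params, threshold = 3,
                           return_scores = FALSE, max_offset = 25) {
  stopifnot(is.finite(threshold) || threshold == -Inf)
  s <- pmd_score(reads, params, max_offset = max_offset)
  out <- reads[s >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (return_scores) attr(out, "scores") <- s[s >= threshold]
  out
}
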