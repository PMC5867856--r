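# R_Y and R_X sex-assignment statistics with Wald 95% confidence intervals
# and threshold-based categorical calls

#' Sex-calling thresholds
#'
#' Published operating thresholds for the two read-ratio statistics:
#' R_Y calls female when the CI upper bound is below `ry_female_max` and male
#' when the lower bound exceeds `ry_male_min`; R_X calls male when the CI
#' upper bound is below `rx_male_max` and female when the lower bound
#' exceeds `rx_female_min`. Anything else is indeterminate.
#'
#' @param ry_female_max,ry_male_min,rx_male_max,rx_female_min Numeric bounds.
#' @return A `sex_thresholds` list.
#' @export
sex_thresholds <- function(ry_female_max = 0.016, ry_male_min = 0.075,
                           rx_male_max = 0.60, rx_female_min = 0.80) {
  if (ry_female_max >= ry_male_min) stop("ry_female_max must be < ry_male_min")
  if (rx_male_max >= rx_female_min) stop("rx_male_max must be < rx_female_min")
  structure(list(ry_female_max = ry_female_max, ry_male_min = ry_male_min,
                 rx_male_max = rx_male_max, rx_female_min = rx_female_min),
            class = "sex_thresholds")
}

new_sex_estimate <- function(method, estimate, se, ci_low, ci_high, n_used,
                             extra = list()) {
  structure(c(list(method = method, estimate = estimate, se = se,
                   ci_low = ci_low, ci_high = ci_high, n_used = n_used,
                   call = "indeterminate"), extra),
            class = "sex_estimate")
}

#' Categorical sex call from an estimate's confidence interval
#'
#' Applies the method-specific CI thresholds: for R_Y, female iff the CI
#' upper bound is below the female threshold and male iff the lower bound is
#' above the male threshold; for R_X, male iff the upper bound is below the
#' male threshold and female iff the lower bound is above the female
#' threshold; otherwise indeterminate.
#'
#' @param estimate A `sex_estimate` (from [compute_ry()] or [compute_rx()]).
#' @param thresholds A [sex_thresholds()] object.
#' @return One of `"male"`, `"female"`, `"indeterminate"`.
#' @export
assign_sex <- function(estimate, thresholds = sex_thresholds()) {
  stopifnot(inherits(estimate, "sex_estimate"),
            is.finite(estimate$ci_low), is.finite(estimate$ci_high))
  if (estimate$method == "RY") {
    if (estimate$ci_high < thresholds$ry_female_max) return("female")
    if (estimate$ci_low > thresholds$ry_male_min) return("male")
  } else {
    if (estimate$ci_high < thresholds$rx_male_max) return("male")
    if (estimate$ci_low > thresholds$rx_female_min) return("female")
  }
  "indeterminate"
}

#' R_Y: Y fraction of sex-chromosome reads
#'
#' `R_Y = nY / (nX + nY)`, the fraction of reads mapping to either sex
#' chromosome that map to Y; near 0 for XX individuals and elevated for XY.
#' The 95% CI is the binomial Wald interval `R_Y +/- 1.96 * SE` with
#' `SE = sqrt(R_Y (1 - R_Y) / (nX + nY))`, clipped to `[0, 1]`.
#'
#' @param nx,ny Unique-read counts on X and Y. Alternatively pass a
#'   `chrom_count_table` as `nx` and the counts are taken from its chrX/chrY
#'   rows.
#' @param thresholds A [sex_thresholds()] used for the categorical call.
#' @return A `sex_estimate` with method `"RY"`.
#' @export
#' @examples
#' compute_ry(11512, 1133)  # a male: CI [0.0846, 0.0946]
compute_ry <- function(nx, ny = NULL, thresholds = sex_thresholds()) {
  if (inherits(nx, "chrom_count_table")) {
    tab <- nx
    nx <- tab$count[tab$chrom == "chrX"]
    ny <- tab$count[tab$chrom == "chrY"]
    if (length(nx) != 1L || length(ny) != 1L)
      stop("count table must contain exactly one chrX and one chrY row")
  }
  n <- nx + ny
  if (n <= 0) stop("no sex-chromosome reads: nX + nY must be > 0")
  p <- ny / n
  se <- sqrt(p * (1 - p) / n)
  est <- new_sex_estimate("RY", p, se,
                          ci_low = max(p - 1.96 * se, 0),
                          ci_high = min(p + 1.96 * se, 1),
                          n_used = n, extra = list(nx = nx, ny = ny))
  est$call <- assign_sex(est, thresholds)
  est
}

#' R_X: mean length-normalised X-to-autosome read-density ratio
#'
#' For each autosome i, `r_i = (nX / L_X) / (n_i / L_i)`; the statistic is
#' the mean of the 22 ratios, about 1 for XX and 0.5 for XY individuals.
#' The 95% CI is `mean(r) +/- 1.96 * SD(r) / sqrt(k)` over the k usable
#' autosomes, its lower bound clipped at 0. Autosomes with zero reads are
#' excluded with a warning; fewer than 2 usable autosomes is an error.
#'
#' @param table A `chrom_count_table` containing chrX and the 22 autosomes
#'   with their lengths (see [count_by_chromosome()]).
#' @param thresholds A [sex_thresholds()] used for the categorical call.
#' @return A `sex_estimate` with method `"RX"`, carrying the per-autosome
#'   ratios as element `ratios`.
#' @export
compute_rx <- function(table, thresholds = sex_thresholds()) {
  stopifnot(inherits(table, "chrom_count_table"))
  xrow <- table[table$chrom == "chrX", , drop = FALSE]
  if (nrow(xrow) != 1L) stop("count table must contain exactly one chrX row")
  auto <- table[is_autosome(table$chrom), , drop = FALSE]
  missing <- setdiff(paste0("chr", 1:22), auto$chrom)
  if (length(missing))
    stop("count table lacks autosome(s): ", paste(missing, collapse = ", "))
  usable <- auto$count > 0
  if (any(!usable))
    warning("autosome(s) with zero reads excluded from R_X: ",
            paste(auto$chrom[!usable], collapse = ", "))
  auto <- auto[usable, , drop = FALSE]
  if (nrow(auto) < 2L) stop("fewer than 2 autosomes with reads; cannot compute R_X")
  dx <- xrow$count / xrow$length
  ratios <- dx / (auto$count / auto$length)
  k <- length(ratios)
  est <- mean(ratios)
  se <- stats::sd(ratios) / sqrt(k)
  out <- new_sex_estimate("RX", est, se,
                          ci_low = max(est - 1.96 * se, 0),
                          ci_high = est + 1.96 * se,
                          n_used = sum(auto$count) + xrow$count,
                          extra = list(ratios = stats::setNames(ratios, auto$chrom),
                                       n_autosomes = k))
  out$call <- assign_sex(out, thresholds)
  out
}

#' @export
print.sex_estimate <- function(x, digits = 4, ...) {
  lab <- if (x$method == "RY") "R_Y" else "R_X"
  cat(sprintf("%s = %s (95%% CI %s-%s), n = %d -> %s\n", lab,
              format(round_half_up(x$estimate, digits)),
              format(round_half_up(x$ci_low, digits)),
              format(round_half_up(x$ci_high, digits)),
              x$n_used, x$call))
  invisible(x)
}

#' Paired sex determination on all reads and damage-selected reads
#'
#' Computes R_Y and R_X twice: from all supplied (already quality-filtered)
#' reads, and from the subset showing signs of post-mortem damage
#' ([filter_damaged()] at `pmd_threshold`), mitigating the impact of modern
#' contaminants on the call. The layout mirrors the conventional paired
#' reporting of the two statistics.
#'
#' @param reads Quality-filtered [aligned_reads()].
#' @param lengths Named chromosome length vector covering all read
#'   chromosomes (e.g. [hg19_chrom_lengths()]).
#' @param params A [damage_params()] object for the PMD score.
#' @param thresholds A [sex_thresholds()] object.
#' @param pmd_threshold PMD score cutoff for the damage-restricted set.
#' @return A `sex_report`: list with elements `all` and `damaged`, each
#'   holding `n_reads`, `counts` (a `chrom_count_table`), `ry` and `rx`.
#' @export
sex_report <- function(reads, lengths, params,
                       thresholds = sex_thresholds(), pmd_threshold = 3) {
  block <- function(r) {
    counts <- count_by_chromosome(r, lengths)
    list(n_reads = nrow(r), counts = counts,
         ry = compute_ry(counts, thresholds = thresholds),
         rx = compute_rx(counts, thresholds = thresholds))
  }
  damaged <- filter_damaged(reads, params, threshold = pmd_threshold)
  structure(list(all = block(reads), damaged = block(damaged),
                 pmd_threshold = pmd_threshold, thresholds = thresholds),
            class = "sex_report")
}

#' @export
print.sex_report <- function(x, ...) {
  fmt <- function(e) sprintf("%s  (95%% CI %s-%s)  %s",
                             format(round_half_up(e$estimate, 4)),
                             format(round_half_up(e$ci_low, 4)),
                             format(round_half_up(e$ci_high, 4)), e$call)
  nsex <- function(b, chr) b$counts$count[b$counts$chrom == chr]
  cat("Sex determination report\n")
  for (nm in c("all", "damaged")) {
    b <- x[[nm]]
    cat(sprintf("\n%s reads%s:\n",
                if (nm == "all") "All" else "Damage-selected",
                if (nm == "damaged")
                  sprintf(" (PMD score >= %g)", x$pmd_threshold) else ""))
    cat(sprintf("  Mapped reads  %d\n", b$n_reads))
    cat(sprintf("  Mapped to X   %d\n", as.integer(nsex(b, "chrX"))))
    cat(sprintf("  Mapped to Y   %d\n", as.integer(nsex(b, "chrY"))))
    cat(sprintf("  R_Y           %s\n", fmt(b$ry)))
    cat(sprintf("  R_X           %s\n", fmt(b$rx)))
  }
  invisible(x)
}
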