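# end-to-end pipeline: simulate or load reads -> filter -> damage ->
# sexing -> mitochondrial analysis, with a machine-readable report

#' Run the full authentication and sexing pipeline
#'
#' Chains the package's stages on either simulated or supplied alignments:
#' quality/length filtering with duplicate collapse, terminal damage
#' profiling and damage-model fitting, paired (all-reads / damage-selected)
#' R_Y and R_X sex determination, and - when a mitochondrial reference is
#' available - pileup, consensus, coverage and contamination estimation.
#' Deterministic for a fixed configuration and seed.
#'
#' @param config A named list (or path to a YAML file with the same
#'   structure). Recognised entries:
#'   \describe{
#'     \item{seed}{integer; seeds the simulator and the bootstrap.}
#'     \item{simulate}{list of [sim_config()] arguments (minus `seed`); if
#'       present, input is simulated.}
#'     \item{input}{list with `alignments` (SAM/BAM/TSV path), optional
#'       `reference` (FASTA) and `lengths` (named vector or count-table TSV);
#'       used when `simulate` is absent.}
#'     \item{filter}{list of [filter_config()] arguments; `dedup = FALSE`
#'       disables duplicate collapse.}
#'     \item{damage}{list: `max_offset`, `pmd_threshold`, optionally fixed
#'       `delta`, `phi`, `epsilon` (otherwise fitted from the profile).}
#'     \item{mtdna}{list: `min_depth`, `min_freq`, `panel` (FASTA path; for
#'       simulated input the simulated panel is used), `n_boot`; set
#'       `mtdna = FALSE` to skip the stage.}
#'   }
#' @return An `adnasex_report` list with blocks `provenance`, `input`,
#'   `damage`, `sexing` and `mtdna`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- NULL; ref <- NULL
  if (!is.null(config$simulate)) {
    cfg <- stage("simulate",
                 do.call(sim_config, c(list(seed = seed), config$simulate)))
    ref <- stage("simulate", simulate_reference(cfg))
    sim <- stage("simulate", simulate_reads(cfg, ref))
    reads <- sim$reads
    lengths <- cfg$chrom_lengths
    mito_ref <- ref$genome[["chrM"]]
    panel <- ref$mito_contaminants
  } else {
    inp <- config$input
    if (is.null(inp$alignments)) stop("config needs either $simulate or $input$alignments")
    reads <- stage("input", parse_alignments(inp$alignments,
                                             reference = inp$reference))
    lengths <- if (is.null(inp$lengths)) hg19_chrom_lengths()
               else if (is.character(inp$lengths) && length(inp$lengths) == 1L) {
                 tab <- read_count_table(inp$lengths)
                 stats::setNames(tab$length, tab$chrom)
               } else inp$lengths
    mito_ref <- if (!is.null(inp$reference)) {
      r <- load_reference(inp$reference)
      if ("chrM" %in% names(r)) r[["chrM"]] else NULL
    } else NULL
    panel <- if (is.list(config$mtdna)) config$mtdna$panel else NULL
  }
  n_in <- nrow(reads)

  fargs <- config$filter
  dedup <- !identical(fargs$dedup, FALSE)
  fargs$dedup <- NULL
  fcfg <- stage("filter", do.call(filter_config, fargs %||% list()))
  filtered <- stage("filter", filter_reads(reads, fcfg))
  removed <- attr(filtered, "removed")
  n_dups <- 0L
  if (dedup) {
    before <- nrow(filtered)
    filtered <- stage("filter", remove_duplicates(filtered))
    n_dups <- before - nrow(filtered)
  }

  dargs <- config$damage %||% list()
  max_offset <- dargs$max_offset %||% 25
  pmd_threshold <- dargs$pmd_threshold %||% 3
  profile <- stage("damage", damage_profile(filtered, max_offset = max_offset))
  params <- stage("damage", {
    if (!is.null(dargs$delta))
      damage_params(delta = dargs$delta, phi = dargs$phi %||% 0.5,
                    epsilon = dargs$epsilon %||% 0.01)
    else fit_damage_params(profile)
  })

  sexing <- stage("sexing",
                  sex_report(filtered, lengths, params,
                             pmd_threshold = pmd_threshold))

  margs <- config$mtdna
  mt_block <- NULL
  if (!identical(margs, FALSE) && !is.null(mito_ref)) {
    mt_reads <- filtered[filtered$chrom == "chrM", , drop = FALSE]
    if (nrow(mt_reads) > 0) {
      mt_block <- stage("mtdna", {
        pu <- build_pileup(mt_reads, mito_ref, circular = TRUE)
        cons <- call_consensus(pu, min_depth = margs$min_depth %||% 5,
                               min_freq = margs$min_freq %||% 0.80)
        cov <- coverage_stats(pu)
        contam <- if (!is.null(panel))
          tryCatch(estimate_contamination(mt_reads, cons, panel, params,
                                          n_boot = margs$n_boot %||% 200,
                                          seed = seed),
                   error = function(e) conditionMessage(e))
        else NULL
        list(n_reads = nrow(mt_reads), coverage = cov,
             n_uncalled = sum(strsplit(cons$sequence, "")[[1]] == "N"),
             consensus = cons, contamination = contam)
      })
    }
  }

  structure(list(
    provenance = list(package = "adnasex",
                      version = as.character(utils::packageVersion("adnasex")),
                      seed = seed,
                      config_hash = config_hash(config)),
    input = list(reads_in = n_in, removed = as.list(removed),
                 duplicates_removed = n_dups, reads_used = nrow(filtered),
                 filter = unclass(fcfg)),
    damage = list(profile_head = utils::head(profile$five_prime, 5),
                  five_prime_0 = profile$five_prime$frequency[1],
                  three_prime_0 = profile$three_prime$frequency[1],
                  params = unclass(params), pmd_threshold = pmd_threshold),
    sexing = sexing,
    mtdna = mt_block
  ), class = "adnasex_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  # small polynomial rolling hash: provenance needs a stable fingerprint,
  # not cryptography
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 4294967291
  sprintf("%010.0f", h)
}

report_to_list <- function(x) {
  est <- function(e) list(estimate = e$estimate, se = e$se, ci_low = e$ci_low,
                          ci_high = e$ci_high, n_used = e$n_used,
                          call = e$call)
  sx <- function(b) list(n_reads = b$n_reads,
                         n_x = b$counts$count[b$counts$chrom == "chrX"],
                         n_y = b$counts$count[b$counts$chrom == "chrY"],
                         ry = est(b$ry), rx = est(b$rx))
  out <- list(provenance = x$provenance, input = x$input,
              damage = x$damage[c("five_prime_0", "three_prime_0", "params",
                                  "pmd_threshold")],
              sexing = list(all = sx(x$sexing$all),
                            damaged = sx(x$sexing$damaged),
                            thresholds = unclass(x$sexing$thresholds)))
  if (!is.null(x$mtdna)) {
    ct <- x$mtdna$contamination
    out$mtdna <- list(n_reads = x$mtdna$n_reads,
                      coverage = as.list(x$mtdna$coverage),
                      n_uncalled = x$mtdna$n_uncalled,
                      contamination = if (inherits(ct, "contam_estimate"))
                        unclass(ct)[c("proportion", "ci_low", "ci_high",
                                      "n_reads", "n_informative",
                                      "panel_size")] else ct)
  }
  out
}

#' Serialise a pipeline report to JSON
#'
#' @param report An `adnasex_report` from [run_pipeline()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "adnasex_report"))
  js <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.adnasex_report <- function(x, ...) {
  cat("== adnasex pipeline report ==\n")
  cat(sprintf("seed %d, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  cat(sprintf("reads: %d in, %d used (%d mapq / %d short / %d long / %d dup removed)\n",
              x$input$reads_in, x$input$reads_used, x$input$removed$mapq,
              x$input$removed$too_short, x$input$removed$too_long,
              x$input$duplicates_removed))
  cat(sprintf("damage: 5' C>T(0) = %.3f, 3' G>A(0) = %.3f; fitted D(z) = %.3f * %.2f^z + %.4f\n",
              x$damage$five_prime_0, x$damage$three_prime_0,
              x$damage$params$delta, x$damage$params$phi,
              x$damage$params$epsilon))
  print(x$sexing)
  if (!is.null(x$mtdna)) {
    cat(sprintf("\nmtDNA: %d reads, coverage %g-%g (mean %g), %d uncalled positions\n",
                x$mtdna$n_reads, x$mtdna$coverage[["min"]],
                x$mtdna$coverage[["max"]], x$mtdna$coverage[["mean"]],
                x$mtdna$n_uncalled))
    if (inherits(x$mtdna$contamination, "contam_estimate"))
      print(x$mtdna$contamination)
  }
  invisible(x)
}
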