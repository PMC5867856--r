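# truth-tagged ancient-read simulator: miniature XX/XY nuclear genomes plus
# a full-length circular mitochondrial genome, log-normal fragment lengths,
# terminal deamination under configurable UDG treatment, and optional modern
# contaminant admixture

#' Default miniature genome lengths
#'
#' hg19 chromosome lengths scaled by 1/1000 (rounded), except the
#' mitochondrial genome which is kept at its real 16,569 bp so that
#' mitochondrial coverage and contamination behave realistically.
#'
#' @return Named numeric vector of 25 chromosome lengths.
#' @export
default_sim_lengths <- function() {
  h <- hg19_chrom_lengths()
  out <- round(h / 1000)
  out["chrM"] <- 16569
  out
}

udg_deltas <- c(none = 0.27, partial = 0.084, full = 0.01)

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a miniature human
#' genome (1/1000-scale nuclear chromosomes, full-size mitochondrion),
#' log-normal fragment lengths with a mode near 38 or 47 bp truncated to
#' 20-120 bp, terminal C->T/G->A deamination with 5' amplitude 0.27 (no
#' effective UDG treatment), 0.084 (partial UDG) or 0.01 (full UDG) decaying
#' geometrically into the read, and an optional modern contaminant fraction
#' (typical mitochondrial estimates in degraded-sample work span roughly
#' 0.6-11.6%).
#'
#' @param seed Integer seed; all simulator output is deterministic given the
#'   full configuration.
#' @param karyotype `"XY"` (one X, one Y, two of each autosome) or `"XX"`
#'   (two X, no Y).
#' @param n_reads Number of reads to simulate.
#' @param chrom_lengths Named vector of chromosome lengths (default
#'   [default_sim_lengths()]).
#' @param length_mode Modal fragment length in bp (default 47; use 38 for a
#'   shorter-fragment extraction protocol).
#' @param length_sdlog Log-scale SD of the log-normal length model.
#' @param length_range Truncation window in bp.
#' @param udg UDG treatment mode: `"none"`, `"partial"` or `"full"`,
#'   selecting the 5' terminal amplitude from `c(0.27, 0.084, 0.01)`.
#' @param phi Geometric decay of the damage probability per position.
#' @param epsilon Background per-base substitution probability.
#' @param contam_fraction Fraction of reads drawn from a modern contaminant.
#' @param contam_karyotype Karyotype of the nuclear contaminant individual.
#' @param contam_mt_divergence Number of mitochondrial sites at which each
#'   contaminant haplotype differs from the endogenous haplotype.
#' @param n_contam_haplotypes Number of candidate contaminant mitochondrial
#'   haplotypes generated (reads are drawn from the first; the full set is
#'   the estimation panel).
#' @param endo_mt_variants Number of sites at which the endogenous
#'   mitochondrial haplotype differs from the mapping reference.
#' @param mt_copies Mitochondrial copy number relative to one nuclear
#'   chromosome copy, controlling the mtDNA read share.
#' @param mapq Mapping quality assigned to simulated reads.
#' @param dup_fraction Fraction of additional exact duplicate reads emitted.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, karyotype = c("XY", "XX"), n_reads = 50000,
                       chrom_lengths = default_sim_lengths(),
                       length_mode = 47, length_sdlog = 0.3,
                       length_range = c(20, 120),
                       udg = c("none", "partial", "full"),
                       phi = 0.5, epsilon = 0.001,
                       contam_fraction = 0, contam_karyotype = "XY",
                       contam_mt_divergence = 30, n_contam_haplotypes = 5,
                       endo_mt_variants = 10, mt_copies = 2,
                       mapq = 60L, dup_fraction = 0) {
  karyotype <- match.arg(karyotype)
  udg <- match.arg(udg)
  stopifnot(contam_fraction >= 0, contam_fraction <= 1,
            contam_karyotype %in% c("XY", "XX"),
            length_range[1] <= length_mode, length_mode <= length_range[2],
            phi >= 0, phi < 1, epsilon >= 0, n_reads >= 0,
            dup_fraction >= 0, dup_fraction < 1, mt_copies >= 0,
            seed == as.integer(seed))
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  structure(list(seed = as.integer(seed), karyotype = karyotype,
                 n_reads = n_reads, chrom_lengths = chrom_lengths,
                 length_mode = length_mode, length_sdlog = length_sdlog,
                 length_range = length_range, udg = udg,
                 delta = unname(udg_deltas[udg]), phi = phi,
                 epsilon = epsilon, contam_fraction = contam_fraction,
                 contam_karyotype = contam_karyotype,
                 contam_mt_divergence = contam_mt_divergence,
                 n_contam_haplotypes = n_contam_haplotypes,
                 endo_mt_variants = endo_mt_variants, mt_copies = mt_copies,
                 mapq = as.integer(mapq), dup_fraction = dup_fraction),
            class = "sim_config")
}

# copy number of each chromosome for a karyotype
karyotype_copies <- function(chroms, karyotype, mt_copies) {
  copies <- ifelse(is_autosome(chroms), 2,
                   ifelse(chroms == "chrX", if (karyotype == "XX") 2 else 1,
                   ifelse(chroms == "chrY", if (karyotype == "XY") 1 else 0,
                   ifelse(chroms == "chrM", mt_copies, 2))))
  stats::setNames(copies, chroms)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# substitute the bases at `sites` (1-based) with a different random base
mutate_sites <- function(seq, sites) {
  ch <- strsplit(seq, "")[[1]]
  for (s in sites) {
    ch[s] <- sample(setdiff(c("A", "C", "G", "T"), ch[s]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate reference sequences
#'
#' Generates i.i.d.-uniform nuclear chromosome sequences plus a circular
#' mitochondrial reference, an endogenous mitochondrial haplotype differing
#' from the mapping reference at `endo_mt_variants` sites, and
#' `n_contam_haplotypes` contaminant haplotypes each differing from the
#' endogenous haplotype at exactly `contam_mt_divergence` sites.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_reference`: list with `genome` (named character vector of
#'   mapping-reference sequences), `endo_mt`, `mito_contaminants` (named
#'   character vector), `mt_variant_sites`, `contam_sites` (list).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$contam_mt_divergence > cfg$chrom_lengths[["chrM"]])
    stop("contam_mt_divergence exceeds the mitochondrial length")
  set.seed(cfg$seed)
  genome <- vapply(cfg$chrom_lengths, random_seq, character(1))
  mtL <- cfg$chrom_lengths[["chrM"]]
  mt_sites <- sort(sample.int(mtL, cfg$endo_mt_variants))
  endo_mt <- mutate_sites(genome[["chrM"]], mt_sites)
  contam_sites <- vector("list", cfg$n_contam_haplotypes)
  contams <- character(cfg$n_contam_haplotypes)
  for (k in seq_len(cfg$n_contam_haplotypes)) {
    contam_sites[[k]] <- sort(sample.int(mtL, cfg$contam_mt_divergence))
    contams[k] <- mutate_sites(endo_mt, contam_sites[[k]])
  }
  names(contams) <- paste0("contam", seq_len(cfg$n_contam_haplotypes))
  structure(list(genome = genome, endo_mt = endo_mt,
                 mito_contaminants = contams,
                 mt_variant_sites = mt_sites, contam_sites = contam_sites),
            class = "sim_reference")
}

# truncated log-normal fragment lengths parameterised by the mode:
# mode = exp(meanlog - sdlog^2)
sim_read_lengths <- function(n, mode, sdlog, range) {
  meanlog <- log(mode) + sdlog^2
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(max(n, 1000L), meanlog, sdlog))
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(out[seq_len(n)])
}

# in-place terminal deamination + background error, molecule orientation;
# returns list(seq, dmg5, dmg3) where dmg5/dmg3 are per-read comma strings
# of damaged offsets
apply_damage <- function(mol, delta, phi, epsilon, max_offset = 120L) {
  n <- length(mol)
  len <- nchar(mol)
  ev5 <- vector("list", n)
  ev3 <- vector("list", n)
  maxlen <- if (n) max(len) else 0L
  for (z in seq_len(min(max_offset, maxlen)) - 1L) {
    # 5' frame: C -> T with D(z); background errors at A/T
    ch <- substr(mol, z + 1L, z + 1L)
    isC <- ch == "C"
    if (any(isC)) {
      d <- delta[isC] * phi^z
      p <- d + epsilon
      u <- stats::runif(sum(isC))
      hit <- which(isC)[u < p]
      # attribute each C->T to deamination vs background in proportion
      is_dmg <- (u[u < p] < d[u < p])
      if (length(hit)) {
        substr(mol[hit], z + 1L, z + 1L) <- "T"
        for (i in hit[is_dmg]) ev5[[i]] <- c(ev5[[i]], z)
      }
    }
    isAT <- ch %in% c("A", "T")
    if (any(isAT) && epsilon > 0) {
      hit <- which(isAT)[stats::runif(sum(isAT)) < epsilon]
      for (i in hit) {
        alt <- sample(setdiff(c("A", "C", "G", "T"),
                              substr(mol[i], z + 1L, z + 1L)), 1)
        substr(mol[i], z + 1L, z + 1L) <- alt
      }
    }
    # 3' frame: G -> A with D(z)
    pos <- len - z
    ok <- pos >= 1L
    ch3 <- substr(mol, pos, pos)
    isG <- ok & ch3 == "G"
    if (any(isG)) {
      d <- delta[isG] * phi^z
      p <- d + epsilon
      u <- stats::runif(sum(isG))
      hit <- which(isG)[u < p]
      is_dmg <- (u[u < p] < d[u < p])
      if (length(hit)) {
        substr(mol[hit], pos[hit], pos[hit]) <- "A"
        for (i in hit[is_dmg]) ev3[[i]] <- c(ev3[[i]], z)
      }
    }
  }
  fmt <- function(l) vapply(l, function(v)
    if (is.null(v)) "" else paste(sort(v), collapse = ","), character(1))
  list(seq = mol, dmg5 = fmt(ev5), dmg3 = fmt(ev3))
}

#' Simulate truth-tagged ancient reads
#'
#' Draws fragment positions uniformly over chromosome copies (weighted by
#' copy number x length), fragment lengths from the truncated log-normal
#' model, applies terminal deamination per `D(z) = delta * phi^z + epsilon`
#' at reference-C offsets from the molecule's 5' end and reference-G offsets
#' from its 3' end, and emits alignment records at the true coordinates (no
#' mapping step, hence no mappability artifacts). A `contam_fraction` of
#' reads is drawn undamaged from the contaminant: the first contaminant
#' mitochondrial haplotype for chrM reads, an undamaged genome of
#' `contam_karyotype` for nuclear reads. Mitochondrial fragments may wrap
#' the origin. Deterministic given the configuration.
#'
#' @param cfg A [sim_config()].
#' @param ref A [simulate_reference()] result for the same configuration.
#' @param chroms Optional subset of chromosomes to simulate from (e.g.
#'   `"chrM"` for a mitochondrial capture experiment); weights are
#'   renormalised over the subset.
#' @return List with `reads` (an [aligned_reads()] table) and `truth` (data
#'   frame: `read_id`, `chrom`, `start`, `length`, `strand`, `contaminant`,
#'   `damage5`, `damage3`, `original_seq` in molecule orientation).
#' @export
simulate_reads <- function(cfg, ref, chroms = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ref, "sim_reference"))
  set.seed(cfg$seed + 1L)
  lens <- cfg$chrom_lengths
  if (!is.null(chroms)) {
    chroms <- norm_chrom(chroms)
    missing <- setdiff(chroms, names(lens))
    if (length(missing)) stop("unknown chromosome(s): ",
                              paste(missing, collapse = ", "))
    lens <- lens[chroms]
  }
  n <- cfg$n_reads
  empty_truth <- data.frame(read_id = character(), chrom = character(),
                            start = integer(), length = integer(),
                            strand = character(), contaminant = logical(),
                            damage5 = character(), damage3 = character(),
                            original_seq = character(),
                            stringsAsFactors = FALSE)
  if (n == 0L) return(list(reads = aligned_reads(), truth = empty_truth))

  contam <- stats::runif(n) < cfg$contam_fraction
  w_endo <- karyotype_copies(names(lens), cfg$karyotype, cfg$mt_copies) * lens
  w_cont <- karyotype_copies(names(lens), cfg$contam_karyotype,
                             cfg$mt_copies) * lens
  if (sum(w_endo) <= 0) stop("no chromosome has positive sampling weight")
  chrom <- character(n)
  chrom[!contam] <- sample(names(lens), sum(!contam), TRUE, prob = w_endo)
  if (any(contam)) {
    if (sum(w_cont) <= 0) stop("contaminant karyotype has no sampling weight")
    chrom[contam] <- sample(names(lens), sum(contam), TRUE, prob = w_cont)
  }
  len <- sim_read_lengths(n, cfg$length_mode, cfg$length_sdlog,
                          cfg$length_range)
  L <- unname(lens[chrom])
  is_mt <- chrom == "chrM"
  start <- integer(n)
  start[!is_mt] <- floor(stats::runif(sum(!is_mt)) *
                           (L[!is_mt] - len[!is_mt] + 1))
  start[is_mt] <- floor(stats::runif(sum(is_mt)) * L[is_mt])  # may wrap
  strand <- sample(c("+", "-"), n, TRUE)

  # source haplotype: mapping reference for nuclear reads (endogenous and
  # contaminant individuals share it), endogenous vs contaminant haplotype
  # for chrM
  hap <- ref$genome[chrom]
  hap[is_mt & !contam] <- ref$endo_mt
  if (any(is_mt & contam)) hap[is_mt & contam] <- ref$mito_contaminants[[1]]
  frag <- substring(hap, start + 1L, pmin(start + len, L))
  wrap <- start + len > L
  if (any(wrap)) {
    w <- which(wrap)
    frag[w] <- paste0(frag[w], substring(hap[w], 1L, start[w] + len[w] - L[w]))
  }
  mol <- ifelse(strand == "-", revcomp(frag), frag)
  original <- mol
  dmg <- apply_damage(mol, delta = ifelse(contam, 0, cfg$delta),
                      phi = cfg$phi, epsilon = cfg$epsilon)
  seq_ref_orient <- ifelse(strand == "-", revcomp(dmg$seq), dmg$seq)
  ids <- sprintf("read%07d", seq_len(n))
  reads <- aligned_reads(
    read_id = ids, chrom = chrom, start = start, length = len,
    strand = strand, mapq = cfg$mapq, seq = seq_ref_orient,
    ref_bases = extract_ref_bases(ref$genome, chrom, start, len,
                                  circular = "chrM"))
  truth <- data.frame(read_id = ids, chrom = chrom, start = start,
                      length = len, strand = strand, contaminant = contam,
                      damage5 = dmg$dmg5, damage3 = dmg$dmg3,
                      original_seq = original, stringsAsFactors = FALSE)
  if (cfg$dup_fraction > 0) {
    k <- round(cfg$dup_fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k, replace = FALSE)
      dup_reads <- reads[idx, , drop = FALSE]
      dup_reads$read_id <- paste0(dup_reads$read_id, "_dup")
      dup_truth <- truth[idx, , drop = FALSE]
      dup_truth$read_id <- dup_reads$read_id
      reads <- rbind(reads, dup_reads)
      class(reads) <- c("aligned_reads", "data.frame")
      truth <- rbind(truth, dup_truth)
      rownames(reads) <- rownames(truth) <- NULL
    }
  }
  list(reads = reads, truth = truth)
}

#' Write simulator fixtures to disk
#'
#' Emits everything downstream tools need: `reads.sam` (header lengths from
#' the configuration), `reads.tsv` (the package's alignment TSV), a FASTQ of
#' read sequences, the mapping reference and contaminant-panel FASTAs, the
#' endogenous mitochondrial haplotype FASTA, and the truth table TSV.
#' [parse_alignments()] round-trips the SAM and TSV losslessly.
#'
#' @param sim A [simulate_reads()] result.
#' @param ref The matching [simulate_reference()] result.
#' @param cfg The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(sim, ref, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sam = file.path(dir, "reads.sam"),
             tsv = file.path(dir, "reads.tsv"),
             fastq = file.path(dir, "reads.fastq"),
             reference = file.path(dir, "reference.fasta"),
             panel = file.path(dir, "mito_panel.fasta"),
             endo_mt = file.path(dir, "endogenous_mt.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_sam(sim$reads, cfg$chrom_lengths, paths[["sam"]])
  write_alignment_tsv(sim$reads, paths[["tsv"]])
  writeLines(as.vector(rbind(paste0("@", sim$reads$read_id), sim$reads$seq,
                             "+", strrep("I", sim$reads$length))),
             paths[["fastq"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome),
                              paths[["reference"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$mito_contaminants),
                              paths[["panel"]])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(endogenous_mt = ref$endo_mt)),
    paths[["endo_mt"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
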