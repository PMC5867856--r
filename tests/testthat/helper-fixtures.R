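# shared fixtures: hand-built reads and a fast miniature simulation setup

# 1/20000-scale nuclear genome so reference generation stays cheap in unit
# tests; chrM length is configurable because mito tests want real coverage
small_sim_lengths <- function(mt = 3000) {
  out <- round(hg19_chrom_lengths() / 20000)
  out["chrM"] <- mt
  out
}

small_cfg <- function(..., mt = 3000) {
  sim_config(chrom_lengths = small_sim_lengths(mt), endo_mt_variants = 0, ...)
}

make_reads <- function(seq, ref = seq, chrom = "chr1", start = 0L,
                       strand = "+", mapq = 60L, id = NULL) {
  n <- length(seq)
  aligned_reads(
    read_id = if (is.null(id)) sprintf("r%03d", seq_len(n)) else id,
    chrom = rep_len(chrom, n), start = rep_len(start, n),
    length = nchar(seq), strand = rep_len(strand, n),
    mapq = rep_len(mapq, n), seq = seq, ref_bases = ref
  )
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# build a pileup object directly from per-base counts (positions x ACGT),
# for consensus edge cases where routing through reads adds nothing
pileup_from_counts <- function(acgt, other = 0) {
  counts <- rbind(t(acgt), other = rep_len(other, nrow(acgt)))
  rownames(counts) <- c("A", "C", "G", "T", "other")
  structure(list(ref_length = ncol(counts), counts = counts,
                 depth = colSums(counts),
                 ref = rep("N", ncol(counts))),
            class = "pileup")
}
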