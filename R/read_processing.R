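# quality/length filtering, duplicate collapse, dataset merging and
# per-chromosome counting of unique reads

#' Read filtering configuration
#'
#' Defaults follow the standard ancient-DNA processing chain: discard reads
#' with mapping quality below 30, reads of 35 bp or shorter (spurious
#' microbial alignments) and reads longer than 70 bp (more likely modern
#' contaminants), i.e. a retained window of 36-70 bp.
#'
#' @param min_mapq Minimum mapping quality retained (default 30).
#' @param min_len Minimum fragment length retained, bp (default 36).
#' @param max_len Maximum fragment length retained, bp (default 70); use
#'   `Inf` to disable the upper cutoff, e.g. for nuclear shotgun data where
#'   only the lower cutoff is wanted.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_mapq = 30, min_len = 36, max_len = 70) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (min_mapq < 0) stop("min_mapq must be >= 0")
  structure(list(min_mapq = min_mapq, min_len = min_len, max_len = max_len),
            class = "filter_config")
}

#' Filter reads on mapping quality and fragment length
#'
#' Retains reads with `mapq >= min_mapq` and `min_len <= length <= max_len`,
#' preserving input order. The number of reads removed by each criterion is
#' attached as attribute `removed` (a read failing both counts under `mapq`).
#'
#' @param reads An [aligned_reads()] table.
#' @param cfg A [filter_config()].
#' @return Filtered `aligned_reads` with attribute `removed`.
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  low_q <- reads$mapq < cfg$min_mapq
  short <- !low_q & reads$length < cfg$min_len
  long <- !low_q & reads$length > cfg$max_len
  keep <- !(low_q | short | long)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(mapq = sum(low_q), too_short = sum(short),
                            too_long = sum(long))
  out
}

# duplicate key: 5'-most reference coordinate of the original molecule
# (alignment start on +, alignment end on -), strand, chrom and length
dup_key <- function(reads) {
  five_prime <- ifelse(reads$strand == "+", reads$start,
                       reads$start + reads$length - 1L)
  paste(reads$chrom, reads$strand, five_prime, reads$length, sep = "\r")
}

#' Collapse PCR/optical duplicates
#'
#' Reads sharing chromosome, strand, 5'-most molecule coordinate and fragment
#' length are taken to be copies of one original molecule; the representative
#' kept is the one with highest mapping quality, ties broken by lexicographic
#' `read_id`. Idempotent; output preserves input order.
#'
#' @param reads An [aligned_reads()] table.
#' @return Deduplicated `aligned_reads`.
#' @export
remove_duplicates <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  key <- dup_key(reads)
  ord <- order(key, -reads$mapq, reads$read_id)
  keep_idx <- ord[!duplicated(key[ord])]
  out <- reads[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge read datasets and collapse duplicates across them
#'
#' Concatenates the given read sets and applies [remove_duplicates()], so
#' that a molecule sequenced in several libraries is counted once -
#' duplicates are removed after merging, not per library.
#'
#' @param ... `aligned_reads` tables, or a single list of them.
#' @return Merged, deduplicated `aligned_reads`.
#' @export
merge_datasets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "aligned_reads"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "aligned_reads")))
  combined <- do.call(rbind, lapply(sets, as.data.frame))
  if (is.null(combined)) return(aligned_reads())
  class(combined) <- c("aligned_reads", "data.frame")
  rownames(combined) <- NULL
  remove_duplicates(combined)
}

#' Count unique reads per chromosome
#'
#' Tabulates reads by chromosome against a supplied length table. Every
#' chromosome in `lengths` appears in the output, with count 0 where no read
#' mapped; a read on a chromosome absent from `lengths` is an error.
#'
#' @param reads An [aligned_reads()] table.
#' @param lengths Named vector of chromosome lengths in bp (names normalised
#'   via [norm_chrom()]), e.g. [hg19_chrom_lengths()] or a simulated genome's
#'   own table.
#' @return A `chrom_count_table` data frame with columns `chrom`, `count`,
#'   `length`.
#' @export
count_by_chromosome <- function(reads, lengths) {
  names(lengths) <- norm_chrom(names(lengths))
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  missing <- setdiff(unique(reads$chrom), names(lengths))
  if (length(missing))
    stop("no length entry for chromosome(s): ", paste(missing, collapse = ", "))
  counts <- table(factor(reads$chrom, levels = names(lengths)))
  out <- data.frame(chrom = names(lengths),
                    count = as.integer(counts),
                    length = as.numeric(lengths),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("chrom_count_table", "data.frame")
  out
}

#' Build a count table directly from counts and lengths
#'
#' Convenience constructor for count-only workflows where per-chromosome
#' unique-read counts are already tabulated (e.g. read from a TSV).
#'
#' @param counts Named vector of unique-read counts.
#' @param lengths Named vector of chromosome lengths covering every name in
#'   `counts`.
#' @return A `chrom_count_table`.
#' @export
chrom_count_table <- function(counts, lengths) {
  names(counts) <- norm_chrom(names(counts))
  names(lengths) <- norm_chrom(names(lengths))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  missing <- setdiff(names(counts), names(lengths))
  if (length(missing))
    stop("no length entry for chromosome(s): ", paste(missing, collapse = ", "))
  full <- stats::setNames(numeric(length(lengths)), names(lengths))
  full[names(counts)] <- counts
  out <- data.frame(chrom = names(lengths), count = as.numeric(full),
                    length = as.numeric(lengths), stringsAsFactors = FALSE)
  class(out) <- c("chrom_count_table", "data.frame")
  out
}

#' Read / write a chromosome count table as TSV
#'
#' The on-disk format is a three-column TSV `chrom count length`.
#'
#' @param path File path.
#' @return For `read_count_table`, a `chrom_count_table`.
#' @export
read_count_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "count", "length"), names(x))
  if (length(missing))
    stop("malformed count table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  chrom_count_table(stats::setNames(x$count, x$chrom),
                    stats::setNames(x$length, x$chrom))
}

#' @param table A `chrom_count_table`.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
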