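# aligned-read container and SAM/TSV input-output
#
# Internal coordinate convention: 0-based half-open on the reference strand.
# SAM positions (1-based) are converted on read and write. `seq` and
# `ref_bases` are stored in reference orientation, as in SAM; damage analysis
# re-orients minus-strand reads to the original molecule's own 5' end.

#' Construct an aligned-read table
#'
#' The central container of the package: one row per mapped read, with the
#' fields needed for filtering, sexing and damage analysis. `ref_bases` holds
#' the reference bases under the aligned span (reference orientation); it may
#' be `NA` for reads whose alignment contains indels or clips, which are kept
#' for counting but excluded from damage analysis.
#'
#' @param read_id Character read identifiers.
#' @param chrom Chromosome names (normalised via [norm_chrom()]).
#' @param start 0-based leftmost reference coordinate.
#' @param length Aligned fragment length in bp.
#' @param strand `"+"` or `"-"`.
#' @param mapq Integer mapping quality (Phred scale, as produced upstream).
#' @param seq Read bases, reference orientation.
#' @param ref_bases Reference bases over the aligned span, or `NA`.
#' @return A `data.frame` of class `aligned_reads`.
#' @export
aligned_reads <- function(read_id = character(), chrom = character(),
                          start = integer(), length = integer(),
                          strand = character(), mapq = integer(),
                          seq = character(), ref_bases = NA_character_) {
  n <- length(read_id)
  x <- data.frame(
    read_id = as.character(read_id),
    chrom = norm_chrom(chrom),
    start = as.integer(start),
    length = as.integer(length),
    strand = as.character(strand),
    mapq = as.integer(mapq),
    seq = as.character(seq),
    ref_bases = rep_len(as.character(ref_bases), n),
    stringsAsFactors = FALSE
  )
  validate_aligned_reads(x)
  class(x) <- c("aligned_reads", "data.frame")
  x
}

validate_aligned_reads <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0L)) stop("negative alignment start coordinate")
  if (any(x$mapq < 0L)) stop("mapping quality must be >= 0")
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(nchar(x$seq) != x$length))
    stop("read length disagrees with number of bases in seq")
  hasref <- !is.na(x$ref_bases)
  if (any(nchar(x$ref_bases[hasref]) != x$length[hasref]))
    stop("ref_bases length disagrees with read length")
  invisible(x)
}

as_aligned_reads <- function(x) {
  stopifnot(is.data.frame(x))
  aligned_reads(x$read_id, x$chrom, x$start, x$length, x$strand, x$mapq,
                x$seq, x$ref_bases)
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("<aligned_reads> %d reads on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

tsv_columns <- c("read_id", "chrom", "start", "length", "strand", "mapq",
                 "seq", "ref_bases")

#' Load reference sequences from FASTA
#'
#' @param x Path to a FASTA file, a `DNAStringSet`, or a named character
#'   vector of sequences.
#' @return Named character vector of upper-case sequences with canonical
#'   chromosome names (first whitespace-separated token of each header).
#' @export
load_reference <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x)))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(x))
    x <- stats::setNames(as.character(x), nm)
  }
  if (!is.character(x) || is.null(names(x)))
    stop("reference must be a FASTA path, DNAStringSet or named character vector")
  names(x) <- norm_chrom(names(x))
  toupper(x)
}

cigar_ref_width <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  vapply(seq_along(cigar), function(i) {
    s <- regmatches(cigar[i], m[i])[[1]]
    op <- substring(s, nchar(s), nchar(s))
    len <- as.integer(substring(s, 1, nchar(s) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

cigar_is_simple <- function(cigar) grepl("^\\d+M$", cigar)

# extract reference bases under [start, start+len) for each read, wrapping
# around the origin of chromosomes listed in `circular`
extract_ref_bases <- function(ref, chrom, start, len, circular = "chrM") {
  missing <- setdiff(unique(chrom), names(ref))
  if (length(missing))
    stop("reference sequence not found for: ", paste(missing, collapse = ", "),
         " (known: ", paste(names(ref), collapse = ", "), ")")
  L <- unname(nchar(ref)[chrom])
  end <- start + len
  over <- end > L
  if (any(over & !(chrom %in% circular)))
    stop("read extends beyond the end of a linear reference: ",
         paste(utils::head(chrom[over & !(chrom %in% circular)]), collapse = ", "))
  out <- substring(ref[chrom], start + 1L, pmin(end, L))
  if (any(over)) {
    w <- which(over)
    out[w] <- paste0(out[w], substring(ref[chrom[w]], 1L, end[w] - L[w]))
  }
  unname(out)
}

#' Parse aligned reads from SAM/BAM or an alignment TSV
#'
#' Reads mapped records into an [aligned_reads()] table, converting SAM's
#' 1-based coordinates to the internal 0-based convention. Unmapped records
#' are skipped (their count is reported via `message()`). When a reference is
#' supplied, the reference bases under each alignment are attached; reads
#' whose CIGAR contains indels or clips get `NA` reference bases and are
#' thereby excluded from damage analysis while remaining countable.
#'
#' @param path Path to a `.sam`, `.bam` or `.tsv` file.
#' @param reference Optional FASTA path / `DNAStringSet` / named character
#'   vector used to attach `ref_bases` (required for damage analysis of
#'   SAM/BAM input; the TSV format carries its own `ref_bases` column).
#' @param format `"auto"` (by file extension), `"sam"`, `"bam"` or `"tsv"`.
#' @param circular Chromosome names treated as circular when extracting
#'   reference bases (alignments may run past the end and wrap).
#' @return An `aligned_reads` table.
#' @export
parse_alignments <- function(path, reference = NULL,
                             format = c("auto", "sam", "bam", "tsv"),
                             circular = "chrM") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", tsv = "tsv", txt = "tsv",
                     stop("cannot infer alignment format from extension '",
                          ext, "'; pass format="))
  }
  if (format == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    missing <- setdiff(tsv_columns[1:7], names(x))
    if (length(missing))
      stop("malformed alignment TSV ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
    if (is.null(x$ref_bases)) x$ref_bases <- NA_character_
    x$start <- as.integer(x$start)
    x$length <- as.integer(x$length)
    x$mapq <- as.integer(x$mapq)
    if (anyNA(x$start) || anyNA(x$length) || anyNA(x$mapq))
      stop("malformed alignment TSV ", path,
           ": non-numeric start/length/mapq field")
    x$ref_bases[x$ref_bases %in% c("", "NA", "*")] <- NA_character_
    return(as_aligned_reads(x))
  }
  bam <- path
  if (format == "sam")
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "mapq", "seq", "cigar"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(r$flag, 4L)
  n_skipped <- sum(!mapped)
  if (n_skipped)
    message(n_skipped, " unmapped record(s) skipped")
  chrom <- norm_chrom(as.character(r$rname[mapped]))
  cigar <- r$cigar[mapped]
  seq <- as.character(r$seq[mapped])
  width <- ifelse(cigar_is_simple(cigar), nchar(seq), cigar_ref_width(cigar))
  reads <- aligned_reads(
    read_id = r$qname[mapped], chrom = chrom,
    start = r$pos[mapped] - 1L, length = width,
    strand = as.character(r$strand[mapped]), mapq = r$mapq[mapped],
    seq = seq, ref_bases = NA_character_
  )
  if (!is.null(reference) && nrow(reads)) {
    ref <- load_reference(reference)
    simple <- cigar_is_simple(cigar)
    if (any(!simple))
      message(sum(!simple), " read(s) with indels/clips kept for counting ",
              "but excluded from damage analysis")
    reads$ref_bases[simple] <- extract_ref_bases(
      ref, reads$chrom[simple], reads$start[simple], reads$length[simple],
      circular = circular)
  }
  reads
}

#' Write aligned reads as SAM
#'
#' Emits a minimal single-end SAM file (`@HD`/`@SQ` header, flag 0/16,
#' `<len>M` CIGAR, no qualities) that round-trips through
#' [parse_alignments()]. Reads on circular chromosomes may overhang the
#' declared length; their POS stays within bounds.
#'
#' @param reads An `aligned_reads` table.
#' @param lengths Named vector of chromosome lengths for the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, lengths, path) {
  names(lengths) <- norm_chrom(names(lengths))
  missing <- setdiff(unique(reads$chrom), names(lengths))
  if (length(missing))
    stop("no header length for chromosome(s): ", paste(missing, collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), as.integer(lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
                  reads$chrom, reads$start + 1L, reads$mapq, reads$length,
                  reads$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write aligned reads as a plain alignment TSV
#'
#' @param reads An `aligned_reads` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(reads, path) {
  utils::write.table(as.data.frame(reads)[, tsv_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
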