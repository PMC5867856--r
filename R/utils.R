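# internal helpers shared across modules

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain `character` in and out (the package stores read bases as character
#' columns of a data frame).
#'
#' @param x Character vector of DNA sequences (IUPAC codes allowed).
#' @return Character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

# round half away from zero at `digits` decimals; base round() rounds half to
# even, which disagrees with how the reported tables round e.g. 0.08455
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalise chromosome names to the hg19 convention
#'
#' Maps `"1"`, `"chr1"`, `"X"`, `"MT"`, `"chrM"` etc. onto the canonical
#' `chr1..chr22, chrX, chrY, chrM` naming used throughout the package.
#' Unrecognised names are returned with a `chr` prefix so that non-human or
#' decoy contigs survive counting.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' norm_chrom(c("1", "chrX", "MT", "m"))
norm_chrom <- function(x) {
  x <- as.character(x)
  if (length(x) == 0L) return(character(0))
  stripped <- sub("^[Cc][Hh][Rr]", "", x)
  stripped <- toupper(stripped)
  stripped[stripped %in% c("M", "MT")] <- "M"
  paste0("chr", stripped)
}

is_autosome <- function(x) x %in% paste0("chr", 1:22)

#' hg19 chromosome lengths
#'
#' Lengths (bp) of the 22 autosomes, chrX and chrY of the GRCh37/hg19
#' assembly, plus the 16,569 bp circular mitochondrial reference (rCRS).
#' These are the default normalisation lengths for [compute_rx()] when
#' working with reads mapped to hg19; simulated miniature genomes carry
#' their own length table.
#'
#' @return Named numeric vector of 25 chromosome lengths.
#' @export
#' @examples
#' hg19_chrom_lengths()[c("chrX", "chrY")]
hg19_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566,
    chrM = 16569)
}
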