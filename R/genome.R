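#' Construct a genome layout
#'
#' A genome layout is the ordered list of chromosome names and lengths that
#' anchors every interval and track operation. It is represented as a
#' [GenomeInfoDb::Seqinfo] object.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp (> 0).
#' @return A [GenomeInfoDb::Seqinfo].
#' @examples
#' genome_layout(c("chrI", "chrII"), c(230218, 813184))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("`chroms` and `lengths` must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Read a genome layout from a tab-separated file
#'
#' Accepts the two-column `chrom<TAB>length` dialect as well as `samtools
#' faidx` `.fai` files (extra columns are ignored).
#'
#' @param path path to the TSV file.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
read_genome_layout <- function(path) {
  if (!file.exists(path)) stop("genome layout file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("genome layout needs at least 2 columns (chrom, length)")
  if (!is.numeric(tab[[2]])) stop("genome layout column 2 must be numeric lengths")
  genome_layout(tab[[1]], tab[[2]])
}

#' Write a genome layout as a two-column TSV
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(genome, path) {
  writeLines(paste(seqnames(genome), seqlengths(genome), sep = "\t"), path)
  invisible(path)
}

#' Chromosome layout approximating the S. cerevisiae nuclear genome
#'
#' Sixteen chromosomes with lengths close to the reference assembly
#' (~12.1 Mb total). Used as the default coordinate space of the
#' synthetic-data generator.
#'
#' @return A [GenomeInfoDb::Seqinfo] of 16 chromosomes.
#' @export
yeast_genome_layout <- function() {
  genome_layout(
    paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                    "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")),
    c(230218, 813184, 316620, 1531933, 576874, 270161, 1090940, 562643,
      439888, 745751, 666816, 1078177, 924431, 784333, 1091291, 948066))
}

# Validate that intervals fit inside a genome layout; used by readers and
# the shuffle machinery. Errors name the offending chromosome.
check_features_in_genome <- function(fs, genome) {
  if (is.null(genome)) return(invisible(fs))
  unknown <- setdiff(unique(as.character(seqnames(fs))), seqnames(genome))
  if (length(unknown))
    stop("interval on chromosome absent from genome layout: ",
         paste(unknown, collapse = ", "))
  lens <- seqlengths(genome)[as.character(seqnames(fs))]
  bad <- which(BiocGenerics::end(fs) > lens)
  if (length(bad))
    stop(sprintf("interval %d (%s:%d-%d) exceeds chromosome length %d",
                 bad[1], as.character(seqnames(fs))[bad[1]],
                 BiocGenerics::start(fs)[bad[1]] - 1L,
                 BiocGenerics::end(fs)[bad[1]], lens[bad[1]]))
  invisible(fs)
}

# Attach a Seqinfo to a GRanges (keeping only levels in use if the layout
# is absent).
apply_genome <- function(fs, genome) {
  if (is.null(genome)) return(fs)
  check_features_in_genome(fs, genome)
  GenomeInfoDb::seqlevels(fs) <- seqnames(genome)
  suppressWarnings(seqinfo(fs) <- genome)
  fs
}
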