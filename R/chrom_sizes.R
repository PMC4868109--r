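#' Chromosome sizes
#'
#' A `chrom_sizes` object is a named numeric vector of chromosome lengths in
#' bp. The order of the names is significant: it is the chromosome order used
#' for canonical ordering of PET anchors, so results are stable across naming
#' schemes (no lexicographic surprises with chr2 vs chr10).
#'
#' @param lengths named vector of chromosome lengths in bp (positive).
#' @return a `chrom_sizes` object.
#' @examples
#' chrom_sizes(c(chr1 = 2e6, chr2 = 2e6))
#' @export
chrom_sizes <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    petqc_stop("chromosome names must be present and unique",
               "petqc_argument_error")
  len <- as.numeric(lengths)
  if (any(!is.finite(len)) || any(len <= 0))
    petqc_stop("chromosome lengths must be positive", "petqc_argument_error")
  structure(stats::setNames(len, nm), class = "chrom_sizes")
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp. Order of
#' appearance defines the canonical chromosome order.
#'
#' @param path path to the chrom.sizes file.
#' @return a [chrom_sizes()] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path))
    petqc_stop(sprintf("chrom-sizes file not found: %s", path),
               "petqc_io_error")
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(tab$length, tab$chrom))
}

#' Write a chrom.sizes file
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat(sprintf("<chrom_sizes> %d chromosomes, %.3g bp total\n",
              length(x), sum(x)))
  invisible(x)
}

# index of each chromosome in canonical order; NA for unknown chromosomes
chrom_index <- function(chrom, sizes) match(chrom, names(sizes))
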