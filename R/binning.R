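#' Bin grid for contact-matrix construction
#'
#' Fixed-resolution genomic bins per chromosome: bin `k` covers
#' `[k*r, (k+1)*r)` (0-based, half-open); the last bin of each chromosome may
#' be truncated at the chromosome end. Default resolutions in the QC pipeline
#' are 5 kb and 25 kb, run independently over the same PET set.
#'
#' @param sizes a [chrom_sizes()] object.
#' @param resolution_bp bin width in bp (positive).
#' @return a `bin_grid` object.
#' @export
bin_grid <- function(sizes, resolution_bp) {
  if (length(resolution_bp) != 1 || !is.finite(resolution_bp) ||
      resolution_bp <= 0)
    petqc_stop("resolution_bp must be a single positive number",
               "petqc_argument_error")
  structure(list(
    resolution_bp = as.numeric(resolution_bp),
    sizes = sizes,
    n_bins = stats::setNames(as.integer(ceiling(unname(sizes) / resolution_bp)),
                             names(sizes))
  ), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %g bp resolution, %d chromosomes, %d bins total\n",
              x$resolution_bp, length(x$sizes), sum(x$n_bins)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(a$resolution_bp == b$resolution_bp) &&
    identical(names(a$sizes), names(b$sizes)) &&
    isTRUE(all(unname(a$sizes) == unname(b$sizes)))
}

#' Map a genomic position to its bin index
#'
#' @param pos 0-based position(s) in bp.
#' @param resolution_bp bin width in bp.
#' @return integer bin index (0-based): `floor(pos / resolution_bp)`.
#' @examples
#' pos_to_bin(4999, 5000) # 0
#' pos_to_bin(5000, 5000) # 1
#' @export
pos_to_bin <- function(pos, resolution_bp) {
  as.integer(pos %/% resolution_bp)
}

#' Bin intra-chromosomal PETs into a sparse contact matrix
#'
#' Each PET increments exactly one 2-D bin pair
#' `(pos_to_bin(pos1), pos_to_bin(pos2))` on its chromosome; counts are
#' stored sparsely, upper-triangular (`bin1 <= bin2`, guaranteed by anchor
#' canonicalization). The sum of all counts equals the number of PETs binned.
#'
#' @param pets a [pet_set()] containing only intra-chromosomal records
#'   (normally the output of [filter_long_range()]).
#' @param grid a [bin_grid()].
#' @return a `contact_matrix`: a data.table `chrom, bin1, bin2, count` with
#'   the grid and the binned PET total as attributes.
#' @export
bin_pets <- function(pets, grid) {
  dt <- as.data.table(pets)
  if (nrow(dt) && any(dt$chrom1 != dt$chrom2))
    petqc_stop("bin_pets requires intra-chromosomal PETs only; run filter_long_range() first",
               "petqc_contract_error")
  if (nrow(dt)) {
    cm <- dt[, .(chrom = chrom1,
                 bin1 = pos_to_bin(pos1, grid$resolution_bp),
                 bin2 = pos_to_bin(pos2, grid$resolution_bp))][
      , .(count = .N), by = .(chrom, bin1, bin2)]
    setorder(cm, chrom, bin1, bin2)
  } else {
    cm <- data.table(chrom = character(), bin1 = integer(),
                     bin2 = integer(), count = integer())
  }
  setattr(cm, "class", c("contact_matrix", class(data.table())))
  setattr(cm, "grid", grid)
  setattr(cm, "n_pets", nrow(dt))
  cm[]
}

#' @export
print.contact_matrix <- function(x, ...) {
  g <- attr(x, "grid", exact = TRUE)
  cat(sprintf("<contact_matrix> %g bp bins, %d non-empty bin pairs, %d PETs\n",
              g$resolution_bp, nrow(x), attr(x, "n_pets", exact = TRUE)))
  invisible(x)
}

#' Export a contact matrix as triplet text
#'
#' Tab-separated `chrom  bin_i  bin_j  count` with a one-line column header.
#'
#' @param cm a `contact_matrix` from [bin_pets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_contacts <- function(cm, path) {
  fwrite(as.data.table(cm), path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Export the bin table as BED
#'
#' One interval per bin: `chrom, k*r, min((k+1)*r, chrom_length)`.
#'
#' @param grid a [bin_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_bins_bed <- function(grid, path) {
  r <- grid$resolution_bp
  out <- rbindlist(lapply(names(grid$sizes), function(ch) {
    k <- seq_len(grid$n_bins[[ch]]) - 1L
    data.table(chrom = ch, start = as.integer(k * r),
               end = as.integer(pmin((k + 1) * r, grid$sizes[[ch]])))
  }))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
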