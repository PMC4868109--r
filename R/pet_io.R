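#' @title PET sets
#' @description
#' A `pet_set` holds mapped paired-end tags (PETs) as a `data.table` with
#' columns `chrom1, pos1, strand1, chrom2, pos2, strand2`. Positions are
#' 0-based anchor coordinates (the start of each mate's mapped interval).
#' Records are canonicalized so that anchor 1 is not after anchor 2 in
#' (chromosome-order, coordinate) order, with strands travelling with their
#' anchors. Attached attributes: the [chrom_sizes()] the set was read
#' against, a provenance label, and the number of records skipped at read
#' time (unknown chromosome or out-of-range position).
#'
#' @param records a data.frame with columns `chrom1, pos1, strand1, chrom2,
#'   pos2, strand2` (strands default to "+" when absent).
#' @param sizes a [chrom_sizes()] object.
#' @param provenance free-text label recorded on the object.
#' @return a `pet_set`.
#' @export
pet_set <- function(records, sizes, provenance = "constructed") {
  dt <- as.data.table(records)
  if (!"strand1" %in% names(dt)) dt[, strand1 := "+"]
  if (!"strand2" %in% names(dt)) dt[, strand2 := "+"]
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    petqc_stop(sprintf("missing PET columns: %s", paste(miss, collapse = ", ")),
               "petqc_argument_error")
  dt <- dt[, ..need]
  i1 <- chrom_index(dt$chrom1, sizes); i2 <- chrom_index(dt$chrom2, sizes)
  if (anyNA(i1) || anyNA(i2))
    petqc_stop("records reference chromosomes absent from chrom_sizes",
               "petqc_argument_error")
  bad <- dt$pos1 < 0 | dt$pos2 < 0 |
    dt$pos1 >= unname(sizes)[i1] | dt$pos2 >= unname(sizes)[i2]
  if (any(bad))
    petqc_stop("anchor positions must lie in [0, chromosome length)",
               "petqc_argument_error")
  new_pet_set(canonicalize_pets(dt, sizes), sizes, provenance, 0L)
}

# internal constructor; dt must already be canonical with the right columns
new_pet_set <- function(dt, sizes, provenance, n_skipped = 0L) {
  setDT(dt)
  setattr(dt, "class", c("pet_set", class(data.table())))
  setattr(dt, "chrom_sizes", sizes)
  setattr(dt, "provenance", provenance)
  setattr(dt, "n_skipped", as.integer(n_skipped))
  dt[]
}

# reorder anchors so (chrom-order, pos) of anchor 1 <= anchor 2
canonicalize_pets <- function(dt, sizes) {
  i1 <- chrom_index(dt$chrom1, sizes); i2 <- chrom_index(dt$chrom2, sizes)
  swap <- (i1 > i2) | (i1 == i2 & dt$pos1 > dt$pos2)
  if (any(swap)) {
    tmp <- dt[swap, .(chrom1, pos1, strand1)]
    dt[swap, `:=`(chrom1 = chrom2, pos1 = pos2, strand1 = strand2)]
    dt[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1, strand2 = tmp$strand1)]
  }
  dt
}

#' Accessors for pet_set metadata
#' @param pets a `pet_set`.
#' @return the associated [chrom_sizes()], provenance string, or skip count.
#' @export
pet_chrom_sizes <- function(pets) attr(pets, "chrom_sizes", exact = TRUE)

#' @rdname pet_chrom_sizes
#' @export
pet_provenance <- function(pets) attr(pets, "provenance", exact = TRUE)

#' @rdname pet_chrom_sizes
#' @export
pet_skipped <- function(pets) attr(pets, "n_skipped", exact = TRUE)

#' @export
print.pet_set <- function(x, ...) {
  cat(sprintf("<pet_set> %d PETs (%s), %d skipped at read\n",
              nrow(x), pet_provenance(x), pet_skipped(x)))
  if (nrow(x)) print(as.data.table(head(x, 5)))
  invisible(x)
}

# shared tail of the readers: drop unresolvable/out-of-range records with a
# tally, canonicalize, wrap
finish_read <- function(dt, sizes, provenance) {
  i1 <- chrom_index(dt$chrom1, sizes); i2 <- chrom_index(dt$chrom2, sizes)
  keep <- !is.na(i1) & !is.na(i2)
  keep[keep] <- dt$pos1[keep] >= 0 & dt$pos2[keep] >= 0 &
    dt$pos1[keep] < unname(sizes)[i1[keep]] &
    dt$pos2[keep] < unname(sizes)[i2[keep]]
  n_skip <- sum(!keep)
  dt <- dt[keep]
  new_pet_set(canonicalize_pets(dt, sizes), sizes, provenance, n_skip)
}

parse_int_col <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v))
  if (length(bad))
    petqc_stop(sprintf("%s: line %d has a non-numeric %s field",
                       path, bad[1], what), "petqc_parse_error")
  v
}

#' Read mapped PETs from a BEDPE file
#'
#' Tab-separated, at least 6 columns (`chrom1 start1 end1 chrom2 start2 end2`,
#' 0-based half-open intervals); columns 9-10 are the mate strands and default
#' to `+` when absent. The anchor coordinate of each mate is the interval
#' start. Records on chromosomes absent from `sizes` (scaffolds etc.) are
#' dropped and counted in the skip tally, not fatal.
#'
#' @param path path to the BEDPE file.
#' @param sizes a [chrom_sizes()] object.
#' @return a [pet_set()].
#' @export
read_bedpe <- function(path, sizes) {
  if (!file.exists(path))
    petqc_stop(sprintf("BEDPE file not found: %s", path), "petqc_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(new_pet_set(empty_pet_dt(), sizes, path, 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6))
    petqc_stop(sprintf("%s: line %d has %d fields, expected >= 6",
                       path, which(nf < 6)[1], nf[which(nf < 6)[1]]),
               "petqc_parse_error")
  col <- function(k, default = NULL) {
    vapply(f, function(x) if (length(x) >= k) x[[k]] else default,
           character(1))
  }
  has_strands <- all(nf >= 10)
  dt <- data.table(
    chrom1 = col(1),
    pos1 = parse_int_col(col(2), "start1", path),
    strand1 = if (has_strands) col(9) else "+",
    chrom2 = col(4),
    pos2 = parse_int_col(col(5), "start2", path),
    strand2 = if (has_strands) col(10) else "+"
  )
  finish_read(dt, sizes, path)
}

#' Read mapped PETs from a 4DN .pairs text file
#'
#' Header lines begin with `#`; data columns are
#' `readID chrom1 pos1 chrom2 pos2 strand1 strand2`. Positions are 1-based
#' per the .pairs standard and are converted to the internal 0-based
#' convention (`pos_internal = pos - 1`).
#'
#' @inheritParams read_bedpe
#' @return a [pet_set()].
#' @export
read_pairs <- function(path, sizes) {
  if (!file.exists(path))
    petqc_stop(sprintf(".pairs file not found: %s", path), "petqc_io_error")
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body_idx))
    return(new_pet_set(empty_pet_dt(), sizes, path, 0L))
  f <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 7))
    petqc_stop(sprintf("%s: line %d has %d columns, .pairs needs 7 (readID chrom1 pos1 chrom2 pos2 strand1 strand2)",
                       path, body_idx[which(nf < 7)[1]], nf[which(nf < 7)[1]]),
               "petqc_parse_error")
  col <- function(k) vapply(f, `[[`, character(1), k)
  dt <- data.table(
    chrom1 = col(2),
    pos1 = parse_int_col(col(3), "pos1", path) - 1,
    strand1 = col(6),
    chrom2 = col(4),
    pos2 = parse_int_col(col(5), "pos2", path) - 1,
    strand2 = col(7)
  )
  finish_read(dt, sizes, path)
}

empty_pet_dt <- function() {
  data.table(chrom1 = character(), pos1 = numeric(), strand1 = character(),
             chrom2 = character(), pos2 = numeric(), strand2 = character())
}

#' Write a pet_set as BEDPE
#'
#' Anchors are written as 1-bp intervals (`start = pos`, `end = pos + 1`) so
#' that re-reading the file reproduces the same anchor coordinates.
#'
#' @param pets a [pet_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pets, path) {
  out <- data.table(
    chrom1 = pets$chrom1, start1 = as.integer(pets$pos1),
    end1 = as.integer(pets$pos1) + 1L,
    chrom2 = pets$chrom2, start2 = as.integer(pets$pos2),
    end2 = as.integer(pets$pos2) + 1L,
    name = ".", score = ".",
    strand1 = pets$strand1, strand2 = pets$strand2
  )
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a pet_set in 4DN .pairs text format
#'
#' Emits the standard header and 1-based positions.
#'
#' @inheritParams write_bedpe
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pets, path) {
  sizes <- pet_chrom_sizes(pets)
  hdr <- c("## pairs format v1.0",
           sprintf("#chromsize: %s %d", names(sizes), as.integer(sizes)),
           "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  body <- sprintf("pet%d\t%s\t%d\t%s\t%d\t%s\t%s",
                  seq_len(nrow(pets)), pets$chrom1, as.integer(pets$pos1) + 1L,
                  pets$chrom2, as.integer(pets$pos2) + 1L,
                  pets$strand1, pets$strand2)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Remove clonal (PCR-duplicate) PETs
#'
#' Keeps the first occurrence of each distinct PET. By default the identity
#' key is the full coordinate-and-strand tuple
#' `(chrom1, pos1, strand1, chrom2, pos2, strand2)`: two PETs with identical
#' coordinates but different strand configuration are treated as distinct
#' ligation products. Set `use_strands = FALSE` to collapse on coordinates
#' only.
#'
#' @param pets a [pet_set()] (canonicalized, as produced by the readers).
#' @param use_strands include strands in the duplicate key (default TRUE).
#' @return a deduplicated [pet_set()]; its size is the library's unique-PET
#'   count.
#' @export
deduplicate <- function(pets, use_strands = TRUE) {
  key <- if (use_strands)
    c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  else c("chrom1", "pos1", "chrom2", "pos2")
  out <- unique(as.data.table(pets), by = key)
  new_pet_set(out, pet_chrom_sizes(pets), pet_provenance(pets),
              pet_skipped(pets))
}

#' Keep long-range intra-chromosomal PETs
#'
#' Retains records with both anchors on the same chromosome and an anchor
#' span strictly greater than `span_threshold_bp`. Short-range contacts
#' dominate interactomes (the matrix diagonal) and would bias the quality
#' assessment; inter-chromosomal PETs are excluded regardless of positions.
#' The result is the "filtered PETs" population on which all QC metrics are
#' computed.
#'
#' @param pets a deduplicated [pet_set()].
#' @param span_threshold_bp minimum genomic distance in bp, exclusive
#'   (default 10000).
#' @return the filtered [pet_set()].
#' @export
filter_long_range <- function(pets, span_threshold_bp = 10000) {
  if (length(span_threshold_bp) != 1 || !is.finite(span_threshold_bp) ||
      span_threshold_bp < 0)
    petqc_stop("span_threshold_bp must be a single non-negative number",
               "petqc_argument_error")
  out <- as.data.table(pets)[chrom1 == chrom2 &
                               (pos2 - pos1) > span_threshold_bp]
  new_pet_set(out, pet_chrom_sizes(pets), pet_provenance(pets),
              pet_skipped(pets))
}

#' Library summary statistics
#'
#' Counts reported for every scored library: total mapped PETs, unique PETs
#' after clonal-read removal, the intra/inter-chromosomal split of the unique
#' PETs, and the filtered PETs (intra-chromosomal contacts spanning more than
#' `span_threshold_bp`).
#'
#' @param pets_raw the as-read (pre-deduplication) [pet_set()].
#' @param span_threshold_bp span filter in bp (default 10000).
#' @param use_strands passed to [deduplicate()].
#' @return a `library_stats` list with fields `total_pets`, `unique_pets`,
#'   `intra_pets`, `inter_pets`, `filtered_pets`, `span_threshold_bp`.
#' @export
library_stats <- function(pets_raw, span_threshold_bp = 10000,
                          use_strands = TRUE) {
  uniq <- deduplicate(pets_raw, use_strands = use_strands)
  intra <- sum(uniq$chrom1 == uniq$chrom2)
  filt <- filter_long_range(uniq, span_threshold_bp)
  structure(list(
    total_pets = nrow(pets_raw),
    unique_pets = nrow(uniq),
    intra_pets = as.integer(intra),
    inter_pets = nrow(uniq) - as.integer(intra),
    filtered_pets = nrow(filt),
    span_threshold_bp = span_threshold_bp
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("<library_stats>\n")
  cat(sprintf("  total PETs:    %d\n", x$total_pets))
  cat(sprintf("  unique PETs:   %d (%.1f%%)\n", x$unique_pets,
              if (x$total_pets) 100 * x$unique_pets / x$total_pets else 0))
  cat(sprintf("  intra / inter: %d / %d\n", x$intra_pets, x$inter_pets))
  cat(sprintf("  filtered PETs: %d (span > %g bp)\n",
              x$filtered_pets, x$span_threshold_bp))
  invisible(x)
}
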