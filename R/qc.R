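#' QC configuration
#'
#' Parameters of the quality-assessment pipeline. Defaults follow the
#' standard protocol: 5 kb windows, 10 kb span filter, 10 percent dispersion
#' threshold.
#'
#' @param resolution_bp window (bin) size in bp; 5000 and 25000 are the two
#'   standard resolutions, run independently.
#' @param span_threshold_bp minimum intra-chromosomal span in bp for a PET to
#'   enter the filtered population (exclusive; default 10000).
#' @param dispersion_threshold_pct half-width of the dispersion acceptance
#'   band in percent (default 10): a window passes when
#'   `|dPETcounts| <= threshold`.
#' @param min_window_count minimum original count for a bin pair to enter the
#'   window universe (default 1; singleton windows quantize recovery to
#'   0/100, so raising this can be useful for very sparse libraries).
#' @param use_strands passed to [deduplicate()].
#' @return a `qc_config` object.
#' @export
qc_config <- function(resolution_bp = 5000, span_threshold_bp = 10000,
                      dispersion_threshold_pct = 10, min_window_count = 1L,
                      use_strands = TRUE) {
  if (dispersion_threshold_pct <= 0)
    petqc_stop("dispersion_threshold_pct must be positive",
               "petqc_argument_error")
  if (min_window_count < 1)
    petqc_stop("min_window_count must be >= 1", "petqc_argument_error")
  structure(list(resolution_bp = as.numeric(resolution_bp),
                 span_threshold_bp = as.numeric(span_threshold_bp),
                 dispersion_threshold_pct = as.numeric(dispersion_threshold_pct),
                 min_window_count = as.integer(min_window_count),
                 use_strands = isTRUE(use_strands)),
            class = "qc_config")
}

# comparisons at the band edge must not depend on floating-point rounding of
# 100*s/o, hence the epsilon
DISP_EPS <- 1e-9

#' Per-window recovered PET counts after sub-sampling
#'
#' For every window (2-D bin pair) of the original matrix with
#' `oPETcounts >= min_window_count`, the recovered percentage
#' `recPETcounts = 100 * samPETcounts / oPETcounts`. Windows absent from the
#' sub-sampled matrix recover 0; windows below `min_window_count` are
#' excluded from the universe (recovery undefined on an empty window).
#'
#' @param o the original `contact_matrix`.
#' @param s the `contact_matrix` of a sub-sample of the same PET set.
#' @param min_window_count window-universe floor (default 1).
#' @return a data.table `chrom, bin1, bin2, opet, sampet, recpet`.
#' @export
recovered_counts <- function(o, s, min_window_count = 1L) {
  go <- attr(o, "grid", exact = TRUE); gs <- attr(s, "grid", exact = TRUE)
  if (!same_grid(go, gs))
    petqc_stop("original and sub-sampled matrices use different bin grids",
               "petqc_contract_error")
  uni <- as.data.table(o)[count >= min_window_count]
  setnames(uni, "count", "opet")
  sd_ <- as.data.table(s)
  setnames(sd_, "count", "sampet")
  out <- sd_[uni, on = c("chrom", "bin1", "bin2")]
  out[is.na(sampet), sampet := 0L]
  out[, recpet := 100 * sampet / opet]
  setcolorder(out, c("chrom", "bin1", "bin2", "opet", "sampet", "recpet"))
  out[]
}

#' Dispersion of recovered counts from the proportional expectation
#'
#' Under proportional recovery a window keeps `samd` percent of its PETs, so
#' the dispersion `dPETcounts = samd - recPETcounts` is the local quality
#' indicator: 0 means the window behaved exactly proportionally, positive
#' values under-recovery, negative values over-recovery.
#'
#' @param recpet recovered percentage(s) from [recovered_counts()].
#' @param samd_pct sampling density in percent (90, 70, 50 by default).
#' @return dispersion value(s) in percent, in `[samd - 100, samd]`.
#' @export
dispersion <- function(recpet, samd_pct) samd_pct - recpet

#' Build the per-window dispersion map for one sub-sampling density
#'
#' @inheritParams recovered_counts
#' @param samd_pct sampling density in percent.
#' @param seed seed used for the draw (recorded for provenance).
#' @return a `dispersion_map`: data.table `chrom, bin1, bin2, opet, sampet,
#'   recpet, dpet` with density/resolution/seed attributes.
#' @export
dispersion_map <- function(o, s, samd_pct, min_window_count = 1L,
                           seed = NA_integer_) {
  dm <- recovered_counts(o, s, min_window_count)
  dm[, dpet := dispersion(recpet, samd_pct)]
  setattr(dm, "class", c("dispersion_map", class(data.table())))
  setattr(dm, "density_pct", samd_pct)
  setattr(dm, "grid", attr(o, "grid", exact = TRUE))
  setattr(dm, "seed", seed)
  dm[]
}

#' @export
print.dispersion_map <- function(x, ...) {
  cat(sprintf("<dispersion_map> s%g, %d windows, mean |dPET| = %.2f%%\n",
              attr(x, "density_pct", exact = TRUE), nrow(x),
              mean(abs(x$dpet))))
  invisible(x)
}

#' Density quality indicator (denQC)
#'
#' Fraction of assessable windows whose dispersion lies within the
#' acceptance band: `|dPETcounts| <= threshold` (absolute value, non-strict).
#' Over-recovery is a deviation from proportionality too, so the band is
#' symmetric around zero.
#'
#' @param dmap a [dispersion_map()].
#' @param threshold_pct band half-width in percent (default 10).
#' @return fraction in [0, 1].
#' @export
denqc <- function(dmap, threshold_pct = 10) {
  if (nrow(dmap) == 0)
    petqc_stop("no assessable windows: the window universe is empty",
               "petqc_empty_universe")
  mean(abs(dmap$dpet) <= threshold_pct + DISP_EPS)
}

#' Similarity quality indicator (simQC)
#'
#' Ratio of a higher-density denQC to the reference (lowest-density) denQC.
#' At interactome saturation the fraction of windows affected by sub-sampling
#' is the same at every density, so simQC equals 1; the closer to 1, the
#' higher the dataset quality.
#'
#' @param denqc_hi denQC at the higher density.
#' @param denqc_ref denQC at the reference density (s50 by default); must be
#'   positive.
#' @return `denqc_hi / denqc_ref`.
#' @export
simqc <- function(denqc_hi, denqc_ref) {
  if (denqc_ref <= 0)
    petqc_stop("simQC undefined: reference denQC is zero",
               "petqc_undefined_score")
  denqc_hi / denqc_ref
}

#' Global QCscore
#'
#' Combines the reference denQC and the similarity indicators into one
#' quality readout: `raw = prod(denqc_ref / simqc)` over the higher
#' densities, which with the standard densities is
#' `(denQC.50 / simQC.90/50) * (denQC.50 / simQC.70/50)`. The reported score
#' is the decibel-style transform `10 * log10(raw)` (0 at saturation,
#' increasingly negative for lower quality); the raw value is returned
#' alongside.
#'
#' @param denqc_ref reference denQC (s50), positive.
#' @param simqcs numeric vector of similarity indicators (one per higher
#'   density), positive.
#' @return list with elements `raw` and `score`.
#' @export
qcscore <- function(denqc_ref, simqcs) {
  if (denqc_ref <= 0 || any(simqcs <= 0))
    petqc_stop("QCscore undefined: inputs must be positive",
               "petqc_undefined_score")
  raw <- prod(denqc_ref / simqcs)
  list(raw = raw, score = 10 * log10(raw))
}

# score an already filtered PET population (internal core shared by run_qc
# and depth_ladder)
score_filtered <- function(filtered, config, plan, stats = NULL,
                           keep_maps = TRUE) {
  if (nrow(filtered) == 0)
    petqc_stop("nothing to score: zero filtered PETs", "petqc_no_data",
               data = stats)
  grid <- bin_grid(pet_chrom_sizes(filtered), config$resolution_bp)
  o <- bin_pets(filtered, grid)
  n_windows <- sum(o$count >= config$min_window_count)
  dens <- sort(plan$densities, decreasing = TRUE)
  ref <- min(dens)
  lab <- function(d) as.character(round(100 * d))

  summaries <- vector("list", plan$replicates)
  maps1 <- NULL
  for (r in seq_len(plan$replicates)) {
    dq <- numeric(length(dens)); names(dq) <- lab(dens)
    seeds <- integer(length(dens)); names(seeds) <- lab(dens)
    maps <- list()
    for (i in seq_along(dens)) {
      d <- dens[i]
      seeds[i] <- derive_seed(plan$master_seed, d, r)
      s <- bin_pets(subsample_pets(filtered, d, seeds[i]), grid)
      dm <- dispersion_map(o, s, 100 * d, config$min_window_count, seeds[i])
      dq[i] <- denqc(dm, config$dispersion_threshold_pct)
      if (keep_maps && r == 1L) maps[[lab(d)]] <- dm
    }
    if (dq[[lab(ref)]] <= 0)
      petqc_stop(
        sprintf("QCscore undefined: denQC.%s is zero (pathologically sparse input)",
                lab(ref)),
        "petqc_undefined_score",
        data = list(denqc = dq, library_stats = stats))
    hi <- dens[dens > ref]
    sq <- vapply(hi, function(d) simqc(dq[[lab(d)]], dq[[lab(ref)]]),
                 numeric(1))
    names(sq) <- vapply(hi, lab, character(1))
    qs <- qcscore(dq[[lab(ref)]], sq)
    summ <- c(
      stats::setNames(as.list(dq), paste0("denqc_", names(dq))),
      stats::setNames(as.list(sq), sprintf("simqc_%s_%s", names(sq), lab(ref))),
      list(qcscore_raw = qs$raw, qcscore = qs$score,
           n_windows = n_windows, replicate = r,
           seeds = as.list(seeds))
    )
    summaries[[r]] <- structure(summ, class = "qc_summary")
    if (r == 1L) maps1 <- maps
  }

  scores <- vapply(summaries, function(s) s$qcscore, numeric(1))
  res <- structure(list(
    summaries = summaries,
    summary = summaries[[1]],
    maps = maps1,
    library_stats = stats,
    config = config,
    plan = plan,
    n_filtered = nrow(filtered),
    qcscore_mean = mean(scores),
    qcscore_cv_pct = if (plan$replicates > 1)
      100 * stats::sd(scores) / abs(mean(scores)) else NA_real_
  ), class = "qc_result")
  res
}

#' Run the full quality-assessment pipeline
#'
#' Pipeline: clonal-read removal, long-range span filter, binning of the
#' original filtered PETs, then for each sampling density (and replicate) a
#' seeded sub-sampling draw, re-binning, per-window recovery and dispersion,
#' and denQC; finally the simQC ratios and the global QCscore. With
#' `replicates > 1` each replicate gets independent draws and the
#' coefficient of variation of the score is reported.
#'
#' @param pets_raw the as-read (pre-deduplication) [pet_set()].
#' @param config a [qc_config()].
#' @param plan a [sampling_plan()].
#' @param keep_maps retain the dispersion maps of replicate 1 (default TRUE).
#' @return a `qc_result`: per-replicate `qc_summary` objects, dispersion
#'   maps, library statistics, and (for replicated runs) the score CV.
#' @export
run_qc <- function(pets_raw, config = qc_config(), plan = sampling_plan(),
                   keep_maps = TRUE) {
  if (nrow(pets_raw) == 0)
    petqc_stop("empty PET set", "petqc_no_data")
  stats <- library_stats(pets_raw, config$span_threshold_bp,
                         config$use_strands)
  filtered <- filter_long_range(
    deduplicate(pets_raw, config$use_strands), config$span_threshold_bp)
  score_filtered(filtered, config, plan, stats, keep_maps)
}

#' @export
print.qc_summary <- function(x, ...) {
  dq <- x[startsWith(names(x), "denqc_")]
  sq <- x[startsWith(names(x), "simqc_")]
  cat("<qc_summary>\n")
  for (nm in names(dq)) cat(sprintf("  %s = %.4f\n", nm, dq[[nm]]))
  for (nm in names(sq)) cat(sprintf("  %s = %.4f\n", nm, sq[[nm]]))
  cat(sprintf("  QCscore = %.2f (raw %.4g), %d windows\n",
              x$qcscore, x$qcscore_raw, x$n_windows))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d replicate(s), %d filtered PETs, %g bp windows\n",
              x$plan$replicates, x$n_filtered, x$config$resolution_bp))
  print(x$summary)
  if (!is.na(x$qcscore_cv_pct))
    cat(sprintf("  mean QCscore = %.2f, CV = %.2f%%\n",
                x$qcscore_mean, x$qcscore_cv_pct))
  invisible(x)
}

parse_region <- function(region, sizes) {
  m <- regmatches(region,
                  regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m))
    petqc_stop(sprintf("cannot parse region '%s' (expect chrom or chrom:start-end)",
                       region), "petqc_argument_error")
  chrom <- m[2]
  if (!chrom %in% names(sizes))
    petqc_stop(sprintf("unknown chromosome '%s' in region", chrom),
               "petqc_argument_error")
  if (nzchar(m[3])) {
    start <- as.numeric(m[4]); end <- as.numeric(m[5])
    if (end <= start || end > sizes[[chrom]])
      petqc_stop(sprintf("region '%s' outside chromosome bounds", region),
                 "petqc_argument_error")
  } else {
    start <- 0; end <- sizes[[chrom]]
  }
  list(chrom = chrom, start = start, end = end)
}

#' Export a dispersion map
#'
#' Writes per-window dispersions (percent) for a region, either as sparse
#' triplet text (`chrom  bin_i  bin_j  dpet`; windows outside the universe
#' are simply absent) or as a dense matrix with `NA` for non-assessable
#' windows. `#`-prefixed header lines record density, resolution, threshold
#' and seed. Regions are `chrom` or `chrom:start-end` with 0-based half-open
#' bp coordinates; a window is kept when both of its anchor bins overlap the
#' region.
#'
#' @param dmap a [dispersion_map()].
#' @param path output path.
#' @param region region string, or NULL for the whole genome.
#' @param fmt `"triplet"` (default) or `"dense"`.
#' @param value column to export: `"dpet"` (dispersion, default), `"recpet"`
#'   or `"opet"` (counts).
#' @param threshold_pct threshold recorded in the header (provenance only).
#' @return `path`, invisibly.
#' @export
export_dispersion_map <- function(dmap, path, region = NULL,
                                  fmt = c("triplet", "dense"),
                                  value = c("dpet", "recpet", "opet"),
                                  threshold_pct = 10) {
  fmt <- match.arg(fmt); value <- match.arg(value)
  grid <- attr(dmap, "grid", exact = TRUE)
  dt <- as.data.table(dmap)
  if (!is.null(region)) {
    reg <- parse_region(region, grid$sizes)
    b0 <- pos_to_bin(reg$start, grid$resolution_bp)
    b1 <- pos_to_bin(reg$end - 1, grid$resolution_bp)
    dt <- dt[chrom == reg$chrom & bin1 >= b0 & bin1 <= b1 &
               bin2 >= b0 & bin2 <= b1]
  }
  hdr <- c("# petqc dispersion map",
           sprintf("# value=%s", value),
           sprintf("# density_pct=%g", attr(dmap, "density_pct", exact = TRUE)),
           sprintf("# resolution_bp=%g", grid$resolution_bp),
           sprintf("# threshold_pct=%g", threshold_pct),
           sprintf("# seed=%s", attr(dmap, "seed", exact = TRUE)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  if (fmt == "triplet") {
    writeLines(sprintf("chrom\tbin_i\tbin_j\t%s", value), con)
    if (nrow(dt))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", dt$chrom, dt$bin1, dt$bin2,
                         dt[[value]]), con)
  } else {
    if (is.null(region))
      petqc_stop("dense export requires a region", "petqc_argument_error")
    bins <- b0:b1
    m <- matrix(NA_real_, length(bins), length(bins),
                dimnames = list(bins, bins))
    if (nrow(dt)) {
      m[cbind(match(dt$bin1, bins), match(dt$bin2, bins))] <- dt[[value]]
      m[cbind(match(dt$bin2, bins), match(dt$bin1, bins))] <- dt[[value]]
    }
    writeLines(paste(c("bin", colnames(m)), collapse = "\t"), con)
    for (i in seq_along(bins))
      writeLines(paste(c(bins[i], formatC(m[i, ], format = "g", digits = 10)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Re-import a triplet dispersion-map export
#'
#' @param path a file written by [export_dispersion_map()] (triplet format).
#' @return a data.table `chrom, bin1, bin2, value` with the header fields as
#'   attributes.
#' @export
read_dispersion_map <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- regmatches(hdr, regexec("^# ([a-z_]+)=(.*)$", hdr))
  kv <- kv[lengths(kv) == 3]
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(body[1], "\t")[[1]]
  dt <- if (length(body) > 1) {
    fread(text = body[-1], sep = "\t", header = FALSE, col.names = cols)
  } else {
    data.table(chrom = character(), bin_i = integer(), bin_j = integer(),
               value = numeric())
  }
  setnames(dt, cols[1:3], c("chrom", "bin1", "bin2"))
  for (p in kv) setattr(dt, p[2], p[3])
  dt[]
}

#' Serialize a QC result
#'
#' `write_qc_json()` writes the full result (per-replicate indicators,
#' library statistics, configuration, seeds) as JSON; `write_qc_tsv()`
#' writes one flat row per replicate.
#'
#' @param result a `qc_result` from [run_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(result, path) {
  strip <- function(s) {
    s <- unclass(s); s
  }
  payload <- list(
    summaries = lapply(result$summaries, strip),
    library_stats = if (!is.null(result$library_stats))
      unclass(result$library_stats),
    n_filtered = result$n_filtered,
    qcscore_mean = result$qcscore_mean,
    qcscore_cv_pct = result$qcscore_cv_pct,
    config = unclass(result$config),
    plan = unclass(result$plan)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_qc_json
#' @export
write_qc_tsv <- function(result, path) {
  rows <- rbindlist(lapply(result$summaries, function(s) {
    flat <- s[!vapply(s, is.list, logical(1))]
    as.data.table(flat)
  }))
  fwrite(rows, path, sep = "\t")
  invisible(path)
}
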