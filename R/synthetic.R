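#' Synthetic PET generator configuration
#'
#' Parameters of the TAD-block contact model used to generate synthetic PET
#' libraries. Intra-chromosomal bin pairs `(i, j)`, `j > i`, receive
#' probability `p(i,j)` proportional to `((j - i) * r)^(-alpha)`, multiplied
#' by the enrichment `tau` when both bins fall inside the same TAD interval;
#' a fraction of PETs become uniform inter-chromosomal pairs and a fraction
#' of records is emitted twice to emulate PCR clones. Short-range mass is
#' deliberately included (no span floor at generation) so the long-range
#' filter is genuinely exercised.
#'
#' @param sizes a [chrom_sizes()] object (default: two 2 Mb chromosomes).
#' @param resolution_bp bin size of the generating model in bp (default 5000).
#' @param tads named list (one element per chromosome) of two-column
#'   start/end matrices in bp, non-overlapping, within bounds; `NULL` gives
#'   a default tiling of 300-600 kb domains.
#' @param tau within-TAD contact enrichment, >= 1 (default 5).
#' @param alpha power-law distance-decay exponent (default 1).
#' @param inter_fraction fraction of PETs that are inter-chromosomal noise
#'   (default 0.1).
#' @param dup_rate clonal duplication rate: each record is emitted twice
#'   with this probability (default 0.05).
#' @param n_pets number of base PETs to generate (pre-duplication).
#' @param seed integer generator seed.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(sizes = chrom_sizes(c(chrS1 = 2e6, chrS2 = 2e6)),
                             resolution_bp = 5000, tads = NULL, tau = 5,
                             alpha = 1, inter_fraction = 0.1,
                             dup_rate = 0.05, n_pets = 1e5, seed = 1L) {
  if (is.null(tads)) tads <- default_tads(sizes)
  if (!all(names(tads) %in% names(sizes)))
    petqc_stop("TAD list names must be chromosomes in sizes",
               "petqc_argument_error")
  for (ch in names(tads)) {
    tb <- tads[[ch]]
    if (ncol(tb) != 2 || any(tb[, 1] >= tb[, 2]) || any(tb[, 1] < 0) ||
        any(tb[, 2] > sizes[[ch]]))
      petqc_stop(sprintf("invalid TAD intervals on %s", ch),
                 "petqc_argument_error")
    o <- order(tb[, 1])
    if (nrow(tb) > 1 && any(tb[o, 1][-1] < tb[o, 2][-nrow(tb)]))
      petqc_stop(sprintf("overlapping TADs on %s", ch),
                 "petqc_argument_error")
  }
  if (tau < 1) petqc_stop("tau must be >= 1", "petqc_argument_error")
  if (inter_fraction < 0 || inter_fraction > 1 || dup_rate < 0 || dup_rate > 1)
    petqc_stop("fractions must lie in [0, 1]", "petqc_argument_error")
  if (inter_fraction > 0 && length(sizes) < 2)
    petqc_stop("inter_fraction > 0 needs at least two chromosomes",
               "petqc_argument_error")
  if (n_pets < 1) petqc_stop("n_pets must be >= 1", "petqc_argument_error")
  structure(list(sizes = sizes, resolution_bp = as.numeric(resolution_bp),
                 tads = tads, tau = as.numeric(tau), alpha = as.numeric(alpha),
                 inter_fraction = as.numeric(inter_fraction),
                 dup_rate = as.numeric(dup_rate),
                 n_pets = as.integer(n_pets), seed = as.integer(seed)),
            class = "synthetic_config")
}

# default domain tiling: alternating 300-600 kb blocks covering most of each
# chromosome, realistic for mammalian TAD sizes
default_tads <- function(sizes) {
  widths <- c(4e5, 3e5, 6e5, 4e5, 3e5)
  out <- lapply(unname(sizes), function(len) {
    starts <- cumsum(c(0, widths))
    tb <- cbind(head(starts, -1), cumsum(widths))
    tb <- tb[tb[, 1] < len, , drop = FALSE]
    tb[, 2] <- pmin(tb[, 2], len)
    tb
  })
  stats::setNames(out, names(sizes))
}

# TAD id of each bin (by bin midpoint); NA when outside every domain
bin_tad_ids <- function(n_bins, resolution_bp, tads_chrom) {
  mid <- (seq_len(n_bins) - 0.5) * resolution_bp
  id <- rep(NA_integer_, n_bins)
  if (!is.null(tads_chrom)) {
    for (t in seq_len(nrow(tads_chrom)))
      id[mid >= tads_chrom[t, 1] & mid < tads_chrom[t, 2]] <- t
  }
  id
}

# true intra-chromosomal bin-pair sampling weights of the model
intra_weights <- function(config) {
  r <- config$resolution_bp
  rbindlist(lapply(names(config$sizes), function(ch) {
    nb <- as.integer(ceiling(config$sizes[[ch]] / r))
    if (nb < 2) return(NULL)
    i <- rep(0:(nb - 2), (nb - 1):1)
    j <- sequence((nb - 1):1, from = 2:nb) - 1L
    w <- if (config$alpha == 0) rep(1, length(i))
         else ((j - i) * r)^(-config$alpha)
    tid <- bin_tad_ids(nb, r, config$tads[[ch]])
    same <- !is.na(tid[i + 1L]) & !is.na(tid[j + 1L]) &
      tid[i + 1L] == tid[j + 1L]
    w[same] <- w[same] * config$tau
    data.table(chrom = ch, bin1 = i, bin2 = j, w = w)
  }))
}

#' Generate a synthetic raw PET library
#'
#' Samples bin pairs from the TAD-block model of [synthetic_config()], then
#' places anchors uniformly within the chosen bins (so the binned matrix of
#' the generated data is exactly a multinomial draw from the model weights),
#' adds uniform inter-chromosomal pairs and clonal duplicates, and returns
#' the raw, pre-deduplication [pet_set()]. Fully deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a raw [pet_set()]; the model's true bin-pair probabilities are
#'   attached as attribute `"truth"` for oracle tests.
#' @export
generate_pets <- function(config) {
  W <- intra_weights(config)
  if (is.null(W) || nrow(W) == 0)
    petqc_stop("infeasible synthetic config: no valid intra-chromosomal bin pair",
               "petqc_argument_error")
  r <- config$resolution_bp
  sizes <- config$sizes
  dt <- withr::with_seed(config$seed, {
    n <- config$n_pets
    n_inter <- if (config$inter_fraction > 0) rbinom(1, n, config$inter_fraction) else 0L
    n_intra <- n - n_inter
    # intra: multinomial over bin pairs, uniform offsets inside each bin
    idx <- sample.int(nrow(W), n_intra, replace = TRUE, prob = W$w)
    ch <- W$chrom[idx]
    len <- unname(sizes)[chrom_index(ch, sizes)]
    w1 <- pmin(r, len - W$bin1[idx] * r)
    w2 <- pmin(r, len - W$bin2[idx] * r)
    intra <- data.table(
      chrom1 = ch, pos1 = W$bin1[idx] * r + floor(runif(n_intra) * w1),
      strand1 = sample(c("+", "-"), n_intra, replace = TRUE),
      chrom2 = ch, pos2 = W$bin2[idx] * r + floor(runif(n_intra) * w2),
      strand2 = sample(c("+", "-"), n_intra, replace = TRUE)
    )
    parts <- list(intra)
    if (n_inter > 0) {
      p_chr <- unname(sizes) / sum(sizes)
      c1 <- sample(names(sizes), n_inter, replace = TRUE, prob = p_chr)
      c2 <- sample(names(sizes), n_inter, replace = TRUE, prob = p_chr)
      while (any(same <- c1 == c2))
        c2[same] <- sample(names(sizes), sum(same), replace = TRUE,
                           prob = p_chr)
      parts$inter <- data.table(
        chrom1 = c1,
        pos1 = floor(runif(n_inter) * unname(sizes)[chrom_index(c1, sizes)]),
        strand1 = sample(c("+", "-"), n_inter, replace = TRUE),
        chrom2 = c2,
        pos2 = floor(runif(n_inter) * unname(sizes)[chrom_index(c2, sizes)]),
        strand2 = sample(c("+", "-"), n_inter, replace = TRUE)
      )
    }
    out <- rbindlist(parts)
    if (config$dup_rate > 0) {
      dup <- runif(nrow(out)) < config$dup_rate
      out <- rbind(out, out[dup])
    }
    out
  })
  pets <- new_pet_set(canonicalize_pets(dt, sizes), sizes, "synthetic", 0L)
  truth <- copy(W)[, p := w / sum(w)]
  setattr(pets, "truth", list(config = config, bin_pair_probs = truth[]))
  pets
}

#' Synthetic saturated PET library
#'
#' Deterministically constructs a library in which every non-empty window
#' holds exactly `count_per_window` distinct long-range PETs — a synthetic
#' stand-in for a sequencing-saturated interactome. Anchor offsets enumerate
#' distinct (pos1, pos2) combinations so deduplication removes nothing, and
#' window spans always exceed 10 kb at the default geometry.
#'
#' @param n_windows number of occupied bin pairs (default 20).
#' @param count_per_window PETs per window (default 10000; must not exceed
#'   `resolution_bp^2`).
#' @param resolution_bp bin size in bp (default 5000).
#' @param gap_bins bin distance between the two anchors of each window
#'   (default 4, i.e. spans > 15 kb at 5 kb bins).
#' @return a raw [pet_set()] on one synthetic chromosome.
#' @export
generate_saturated_pets <- function(n_windows = 20, count_per_window = 10000,
                                    resolution_bp = 5000, gap_bins = 4L) {
  if (count_per_window > resolution_bp^2)
    petqc_stop("count_per_window exceeds the number of distinct anchor pairs per window",
               "petqc_argument_error")
  stride <- gap_bins + 2L
  r <- resolution_bp
  len <- (n_windows * stride + gap_bins + 1) * r
  sizes <- chrom_sizes(c(chrSat = len))
  k <- 0:(count_per_window - 1)
  dt <- rbindlist(lapply(seq_len(n_windows) - 1L, function(w) {
    i <- w * stride
    data.table(chrom1 = "chrSat", pos1 = i * r + (k %% r), strand1 = "+",
               chrom2 = "chrSat", pos2 = (i + gap_bins) * r + (k %/% r),
               strand2 = "+")
  }))
  new_pet_set(dt, sizes, "synthetic-saturated", 0L)
}

#' Depth-calibration ladder
#'
#' Emulates the metafile calibration protocol: generate one large synthetic
#' library, reduce it to the filtered PET population, derive smaller datasets
#' of the requested filtered-PET depths by seeded random sub-sampling of that
#' metafile, and score each with the full QC pipeline. The global QCscore is
#' expected to increase with depth.
#'
#' @param config a [synthetic_config()] whose `n_pets` is large enough that
#'   the filtered population covers `max(depths)`.
#' @param depths increasing vector of filtered-PET depths to score.
#' @param qc a [qc_config()].
#' @param plan a [sampling_plan()]; with `replicates > 1` a per-depth CV of
#'   the QCscore is included.
#' @return a data.table with one row per depth: depth, number of assessable
#'   windows, denQC/simQC indicators, raw and log-scaled QCscore, and
#'   (if replicated) the score CV in percent.
#' @export
depth_ladder <- function(config, depths, qc = qc_config(),
                         plan = sampling_plan()) {
  if (is.unsorted(depths, strictly = TRUE))
    petqc_stop("depths must be strictly increasing", "petqc_argument_error")
  meta <- filter_long_range(
    deduplicate(generate_pets(config), qc$use_strands), qc$span_threshold_bp)
  n_meta <- nrow(meta)
  if (n_meta < max(depths))
    petqc_stop(sprintf("metafile has %d filtered PETs < max depth %d; raise config$n_pets",
                       n_meta, max(depths)), "petqc_argument_error")
  rows <- lapply(seq_along(depths), function(k) {
    d <- depths[k]
    sub <- if (d == n_meta) meta else
      take_exact(meta, d, derive_seed(config$seed, d / (n_meta + 1), k))
    res <- score_filtered(sub, qc, plan, stats = NULL, keep_maps = FALSE)
    flat <- res$summary[!vapply(res$summary, is.list, logical(1))]
    flat$replicate <- NULL
    cbind(data.table(depth = d),
          as.data.table(flat),
          data.table(qcscore_mean = res$qcscore_mean,
                     qcscore_cv_pct = res$qcscore_cv_pct))
  })
  out <- rbindlist(rows)
  setattr(out, "metafile_filtered_pets", n_meta)
  out[]
}

# draw exactly k records without replacement (shared by subsample_pets)
take_exact <- function(pets, k, seed) {
  n <- nrow(pets)
  idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, k)))
  new_pet_set(as.data.table(pets)[idx], pet_chrom_sizes(pets),
              pet_provenance(pets), pet_skipped(pets))
}
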