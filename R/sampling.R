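#' Sub-sampling plan
#'
#' Densities and seeding for the random sub-sampling step. The default
#' densities are 90, 70 and 50 percent of the filtered PETs (s90/s70/s50).
#' A single draw per density is used for scoring; replicates serve only to
#' estimate score reproducibility (coefficient of variation).
#'
#' @param densities fractions in (0,1), unique (default `c(0.9, 0.7, 0.5)`).
#' @param replicates number of independent scoring replicates (default 1).
#' @param master_seed integer master seed; per-draw seeds are derived with
#'   [derive_seed()].
#' @return a `sampling_plan` object.
#' @export
sampling_plan <- function(densities = c(0.9, 0.7, 0.5), replicates = 1L,
                          master_seed = 1L) {
  if (any(densities <= 0) || any(densities >= 1) || anyDuplicated(densities))
    petqc_stop("densities must be unique fractions strictly between 0 and 1",
               "petqc_argument_error")
  if (length(replicates) != 1 || replicates < 1)
    petqc_stop("replicates must be >= 1", "petqc_argument_error")
  structure(list(densities = as.numeric(densities),
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed)),
            class = "sampling_plan")
}

#' Derive a child seed for one sub-sampling draw
#'
#' Deterministic mixing of `(master_seed, density, replicate)` into a
#' 31-bit seed, so that every (density, replicate) pair gets its own
#' independent random stream and adding a replicate never changes earlier
#' draws. Uses iterated Lehmer steps modulo the Mersenne prime 2^31 - 1
#' (exact in double precision).
#'
#' @param master_seed integer master seed.
#' @param density sampling density in (0,1).
#' @param replicate replicate index (1-based).
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, density, replicate = 1L) {
  m <- 2147483647  # 2^31 - 1
  a <- 48271
  s <- (abs(as.numeric(master_seed)) %% (m - 1))
  for (k in c(round(density * 1e6), as.numeric(replicate), 977)) {
    s <- (a * ((s + k + 1) %% m)) %% m
    s <- (a * (s + 1)) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

#' Draw a random subset of PETs at a fixed density
#'
#' Samples exactly `floor(density * N)` records uniformly without
#' replacement. Identical `(pets, density, seed)` always return the identical
#' subset; the caller's RNG state is left untouched.
#'
#' @param pets a [pet_set()] with at least one record.
#' @param density fraction in (0,1).
#' @param seed integer seed for this draw.
#' @return a [pet_set()] of `floor(density * nrow(pets))` records, in
#'   original order.
#' @export
subsample_pets <- function(pets, density, seed) {
  if (length(density) != 1 || !is.finite(density) ||
      density <= 0 || density >= 1)
    petqc_stop("density must lie strictly between 0 and 1",
               "petqc_argument_error")
  n <- nrow(pets)
  if (n < 1)
    petqc_stop("cannot subsample an empty pet_set", "petqc_argument_error")
  k <- as.integer(floor(density * n))
  idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, k)))
  new_pet_set(as.data.table(pets)[idx], pet_chrom_sizes(pets),
              paste0(pet_provenance(pets), sprintf(";s%g", density * 100)),
              pet_skipped(pets))
}
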