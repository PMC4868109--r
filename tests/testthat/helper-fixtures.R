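# fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdir()

tiny_sizes <- function() chrom_sizes(c(chrA = 1e6, chrB = 5e5))

# record content only, metadata attributes (provenance etc.) dropped
strip_pets <- function(x) {
  df <- as.data.frame(x)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  rownames(df) <- NULL
  df
}

# a hand-built canonical PET table (intra + inter mix)
toy_records <- function() {
  data.frame(
    chrom1 = c("chrA", "chrA", "chrA", "chrB", "chrA"),
    pos1 = c(100, 2000, 50000, 1000, 700),
    strand1 = c("+", "-", "+", "+", "-"),
    chrom2 = c("chrA", "chrA", "chrA", "chrB", "chrB"),
    pos2 = c(50000, 7000, 80000, 40000, 900),
    strand2 = c("-", "+", "+", "-", "+")
  )
}

# random raw pet_set for property tests: mixed intra/inter with duplicates
rand_pets <- function(n, sizes = tiny_sizes(), seed = 1) {
  withr::with_seed(seed, {
    nm <- names(sizes)
    c1 <- sample(nm, n, replace = TRUE)
    c2 <- sample(nm, n, replace = TRUE)
    df <- data.frame(
      chrom1 = c1, pos1 = floor(runif(n) * unname(sizes)[match(c1, nm)]),
      strand1 = sample(c("+", "-"), n, TRUE),
      chrom2 = c2, pos2 = floor(runif(n) * unname(sizes)[match(c2, nm)]),
      strand2 = sample(c("+", "-"), n, TRUE)
    )
    dup <- sample(n, ceiling(n / 10), replace = TRUE)
    df <- rbind(df, df[dup, ])
  })
  pet_set(df, sizes, "random-fixture")
}

write_bedpe_lines <- function(lines, path = tempfile(fileext = ".bedpe")) {
  writeLines(lines, path)
  path
}

# a pet_set with prescribed per-window counts: window w sits at bin pair
# (w*stride, w*stride + gap) on one chromosome; spans always > 10 kb
window_pets <- function(counts, resolution_bp = 5000, gap = 4L, stride = 6L) {
  r <- resolution_bp
  len <- (length(counts) * stride + gap + 1) * r
  sizes <- chrom_sizes(c(chrW = len))
  dt <- do.call(rbind, lapply(seq_along(counts), function(w) {
    i <- (w - 1L) * stride
    k <- seq_len(counts[w]) - 1L
    data.frame(chrom1 = "chrW", pos1 = i * r + (k %% r), strand1 = "+",
               chrom2 = "chrW", pos2 = (i + gap) * r + (k %/% r),
               strand2 = "+")
  }))
  pet_set(dt, sizes, "window-fixture")
}
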