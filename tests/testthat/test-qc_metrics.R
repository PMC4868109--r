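make_matrices <- function(counts, density, seed) {
  pets <- window_pets(counts)
  grid <- bin_grid(pet_chrom_sizes(pets), 5000)
  o <- bin_pets(pets, grid)
  s <- bin_pets(subsample_pets(pets, density, seed), grid)
  list(pets = pets, grid = grid, o = o, s = s)
}

test_that("recovery is samPET/oPET in percent over the window universe", {
  m <- make_matrices(c(10, 4), 0.5, 1)
  # exact fractions via hand-built matrices instead of a random draw
  o <- m$o
  s <- data.table::copy(m$o)
  s$count <- c(5L, 4L)
  data.table::setattr(s, "grid", attr(m$o, "grid"))
  rc <- recovered_counts(o, s)
  expect_equal(rc$recpet, c(50, 100))
  # windows absent from the subsample recover 0; empty windows never enter
  s2 <- s[1]
  data.table::setattr(s2, "grid", attr(m$o, "grid"))
  rc2 <- recovered_counts(o, s2)
  expect_equal(rc2$sampet, c(5L, 0L))
  expect_true(all(rc2$opet >= 1))
  # min_window_count trims the universe
  expect_equal(nrow(recovered_counts(o, s, min_window_count = 5)), 1L)
  # mismatched grids are a contract error
  pets2 <- window_pets(c(10, 4), resolution_bp = 25000)
  o25 <- bin_pets(pets2, bin_grid(pet_chrom_sizes(pets2), 25000))
  expect_error(recovered_counts(o, o25), class = "petqc_contract_error")
})

test_that("dispersion is density minus recovery", {
  expect_equal(dispersion(50, 50), 0)
  expect_equal(dispersion(100, 90), -10)
  expect_equal(dispersion(40, 70), 30)
})

test_that("denQC counts windows inside the symmetric band, boundary inclusive", {
  dm <- data.table::data.table(dpet = c(0, 5, 15, 20))
  class(dm) <- c("dispersion_map", class(dm))
  expect_equal(denqc(dm, 10), 0.5)
  dm2 <- data.table::data.table(dpet = c(-10, 10))
  class(dm2) <- c("dispersion_map", class(dm2))
  expect_equal(denqc(dm2, 10), 1)
  dm0 <- dm[0]
  expect_error(denqc(dm0, 10), class = "petqc_empty_universe")
})

test_that("simQC and QCscore follow their defining ratios", {
  expect_equal(simqc(0.4, 0.4), 1)
  expect_equal(simqc(0.8, 0.4), 2)
  expect_error(simqc(0.5, 0), class = "petqc_undefined_score")
  qs <- qcscore(1, c(1, 1))
  expect_equal(qs$raw, 1)
  expect_equal(qs$score, 0)
  # hand-verified: (0.01/2)*(0.01/1.5) = 1/30000
  qs2 <- qcscore(0.01, c(2, 1.5))
  expect_equal(qs2$raw, 1 / 30000, tolerance = 1e-12)
  expect_equal(qs2$score, -44.7712, tolerance = 1e-4)
  expect_error(qcscore(0, c(1, 1)), class = "petqc_undefined_score")
  # strictly increasing in the reference denQC at fixed simQCs
  scores <- vapply(c(0.1, 0.3, 0.6, 0.9),
                   function(d) qcscore(d, c(1.4, 1.2))$score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("two same-window PETs at 50 % density always give denQC.50 = 1", {
  # every size-1 subset of 2 same-window PETs leaves count 1: rec = 50, d = 0
  pets <- window_pets(2)
  for (seed in 1:10) {
    res <- run_qc(pets, qc_config(), sampling_plan(0.5, master_seed = seed))
    expect_equal(res$summary$denqc_50, 1)
  }
})

test_that("recovery and dispersion respect their bounds on random fixtures", {
  for (seed in 1:3) {
    filt <- filter_long_range(deduplicate(rand_pets(800, seed = seed)), 10000)
    grid <- bin_grid(tiny_sizes(), 5000)
    o <- bin_pets(filt, grid)
    for (d in c(0.9, 0.5)) {
      s <- bin_pets(subsample_pets(filt, d, derive_seed(seed, d, 1)), grid)
      dm <- dispersion_map(o, s, 100 * d)
      expect_true(all(dm$recpet >= 0 & dm$recpet <= 100))
      expect_true(all(dm$dpet >= 100 * d - 100 & dm$dpet <= 100 * d))
    }
  }
})

test_that("exhaustive subset enumeration matches the Monte-Carlo denQC", {
  # 12 PETs in 3 windows (6/4/2); all C(12,6) = 924 half-density subsets
  counts <- c(6, 4, 2)
  pets <- window_pets(counts)
  labels <- pets$pos1 %/% 30000 + 1  # stride 6 bins * 5 kb
  expect_equal(tabulate(labels, 3), counts)
  subs <- combn(12, 6)
  exact <- mean(apply(subs, 2, function(ix) {
    s <- tabulate(labels[ix], 3)
    mean(abs(50 - 100 * s / counts) <= 10 + 1e-9)
  }))
  grid <- bin_grid(pet_chrom_sizes(pets), 5000)
  o <- bin_pets(pets, grid)
  mc <- vapply(1:2000, function(seed) {
    s <- bin_pets(subsample_pets(pets, 0.5, seed), grid)
    denqc(dispersion_map(o, s, 50), 10)
  }, numeric(1))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - exact), 3 * se)
})

test_that("single-window pass rates match the hypergeometric law", {
  # window holds 20 of 100 PETs; at d = 0.5 the window passes the 10 % band
  # iff its drawn count lies in 8..12
  pets <- window_pets(c(20, 80))
  grid <- bin_grid(pet_chrom_sizes(pets), 5000)
  o <- bin_pets(pets, grid)
  p_exact <- sum(dhyper(8:12, 20, 80, 50))
  pass <- vapply(1:1200, function(seed) {
    s <- bin_pets(subsample_pets(pets, 0.5, seed), grid)
    dm <- dispersion_map(o, s, 50)
    abs(dm$dpet[1]) <= 10 + 1e-9
  }, logical(1))
  expect_lt(abs(mean(pass) - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / length(pass)))
})

test_that("denQC ordering across densities holds at moderate counts", {
  pets <- window_pets(rep(c(20, 30, 40, 50, 60), 6))
  ord_90_70 <- ord_70_50 <- logical(20)
  for (s in 1:20) {
    res <- run_qc(pets, qc_config(), sampling_plan(master_seed = s),
                  keep_maps = FALSE)
    ord_90_70[s] <- res$summary$denqc_90 >= res$summary$denqc_70
    ord_70_50[s] <- res$summary$denqc_70 >= res$summary$denqc_50
  }
  expect_gt(mean(ord_90_70), 0.5)
  expect_gt(mean(ord_70_50), 0.5)
})

test_that("identical master seeds reproduce the summary bit for bit", {
  pets <- window_pets(rep(c(5, 10, 20), 15))
  a <- run_qc(pets, qc_config(), sampling_plan(master_seed = 77))
  b <- run_qc(pets, qc_config(), sampling_plan(master_seed = 77))
  expect_identical(a$summary, b$summary)
})

test_that("degenerate inputs fail with informative conditions", {
  # all-singleton windows: rec quantized to 0/100, denQC.50 = 0
  sparse <- window_pets(rep(1, 8))
  err <- tryCatch(run_qc(sparse, qc_config(), sampling_plan()),
                  petqc_undefined_score = identity)
  expect_s3_class(err, "petqc_undefined_score")
  expect_equal(unname(err$data$denqc["50"]), 0)
  # nothing to score: inter-chromosomal only input
  inter <- pet_set(data.frame(chrom1 = "chrA", pos1 = 1,
                              chrom2 = "chrB", pos2 = 1), tiny_sizes())
  err2 <- tryCatch(run_qc(inter, qc_config(), sampling_plan()),
                   petqc_no_data = identity)
  expect_s3_class(err2, "petqc_no_data")
  expect_equal(err2$data$unique_pets, 1L)
})

test_that("dispersion maps export and re-import losslessly", {
  m <- make_matrices(c(15, 25, 35), 0.7, 5)
  dm <- dispersion_map(m$o, m$s, 70, seed = 5)
  path <- tempfile(fileext = ".tsv")
  export_dispersion_map(dm, path)
  back <- read_dispersion_map(path)
  expect_equal(back$dpet, dm$dpet, tolerance = 1e-9)
  expect_equal(attr(back, "density_pct"), "70")
  # restricting to a sub-bin region: dense export is a single-cell matrix
  dense <- tempfile(fileext = ".tsv")
  export_dispersion_map(dm, dense, region = "chrW:100-200", fmt = "dense")
  lines <- readLines(dense)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2L)  # header row + one bin row
  # empty universe in region -> header-only triplet
  empty <- tempfile(fileext = ".tsv")
  export_dispersion_map(dm, empty, region = "chrW:100-200")
  elines <- readLines(empty)
  expect_equal(sum(!startsWith(elines, "#")), 1L)  # column header only
  expect_error(export_dispersion_map(dm, tempfile(), region = "chrZ:1-2"),
               class = "petqc_argument_error")
})

test_that("replicated runs report the score CV and per-replicate summaries", {
  pets <- window_pets(rep(c(10, 20, 30), 10))
  res <- run_qc(pets, qc_config(), sampling_plan(replicates = 4,
                                                 master_seed = 2))
  expect_length(res$summaries, 4)
  scores <- vapply(res$summaries, function(s) s$qcscore, numeric(1))
  expect_equal(res$qcscore_cv_pct, 100 * sd(scores) / abs(mean(scores)))
  # serialization round trip carries all replicates
  js <- tempfile(fileext = ".json"); tsv <- tempfile(fileext = ".tsv")
  write_qc_json(res, js); write_qc_tsv(res, tsv)
  parsed <- jsonlite::read_json(js)
  expect_length(parsed$summaries, 4)
  expect_equal(parsed$summaries[[1]]$qcscore, scores[1])
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$qcscore, scores)
})
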