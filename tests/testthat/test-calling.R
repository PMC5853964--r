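test_that("minimal qualifying low run is called with bin-boundary coordinates", {
  nc <- nc_from_values(c(1, 1, 0.05, 0.05, 0.05, 0.05, 1, 1, 1, 1))
  calls <- call_deletions(nc)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 2e6)
  expect_equal(calls$end, 6e6)
  expect_equal(calls$n_low_bins, 4L)
  expect_equal(calls$method, "bin")
})

test_that("runs below min_low_run are never called", {
  nc <- nc_from_values(c(1, 0.05, 0.05, 0.05, 1, 1, 1, 1, 1))
  expect_equal(nrow(call_deletions(nc)), 0L)
})

test_that("short interior high runs are absorbed; long ones terminate", {
  v <- c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1)
  calls <- call_deletions(nc_from_values(v))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 11e6)
  # matches the independent segment-splitting oracle
  o <- oracle_calls(v <= 0.1)
  expect_equal(c(calls$start / 1e6 + 1, calls$end / 1e6), c(o[1, 1], o[1, 2]))
})

test_that("masked bins are neutral and reported inside calls", {
  v <- c(1, 1, 0.05, 0.05, NA, 0.05, 0.05, 1, 1, 1, 1)
  calls <- call_deletions(nc_from_values(v))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 2e6)
  expect_equal(calls$end, 7e6)    # masked bin spanned
  expect_equal(calls$n_low_bins, 4L)

  # a masked run does not terminate a deletion
  v2 <- c(0.05, 0.05, NA, NA, NA, NA, NA, 0.05, 0.05, 1, 1, 1, 1)
  calls2 <- call_deletions(nc_from_values(v2))
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$start, 0)
  expect_equal(calls2$end, 9e6)
})

test_that("empty and degenerate profiles give empty call sets", {
  nc <- nc_from_values(numeric(0))
  expect_equal(nrow(call_deletions(nc)), 0L)
  nc_all_masked <- nc_from_values(rep(NA_real_, 8))
  expect_equal(nrow(call_deletions(nc_all_masked)), 0L)
  expect_error(caller_params(low_fraction = 1.2), "low_fraction")
  expect_error(caller_params(min_low_run = 0), "min_low_run")
})

test_that("scanner agrees with the oracle on random profiles", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    v <- ifelse(runif(n) < 0.3, 0.02, 1)
    a <- delscan:::scan_low_runs(v <= 0.1, 4L, 4L)
    b <- oracle_calls(v <= 0.1, 4L, 4L)
    expect_equal(dim(a), dim(b))
    if (nrow(a)) expect_true(all(a == b))
  }
})

test_that("raising the low threshold only grows calls", {
  set.seed(7)
  for (i in 1:50) {
    v <- runif(40, 0, 0.5)
    c1 <- call_deletions(nc_from_values(v), caller_params(low_fraction = 0.1))
    c2 <- call_deletions(nc_from_values(v), caller_params(low_fraction = 0.3))
    expect_gte(sum(v <= 0.3), sum(v <= 0.1))
    if (nrow(c1)) {
      contained <- vapply(seq_len(nrow(c1)), function(k) {
        any(c2$start <= c1$start[k] & c2$end >= c1$end[k])
      }, logical(1))
      expect_true(all(contained))
    }
  }
})

test_that("noise-free profiles from the published A1/D4 intervals are recovered exactly", {
  spec <- paragon_layout()
  params <- coverage_sim_params(capture_efficiency_sd = 0,
                                residual_in_deletion = 0, poisson = FALSE)
  truth <- paragon_deletions("bin")
  for (ln in c("A1", "D4")) {
    sim <- simulate_coverage_pair(spec, params, line = ln)
    nc <- lift_parts_to_full(normalize_coverage(sim$mutant, sim$wildtype),
                             sim$parts)
    calls <- call_deletions(nc)
    want <- truth[truth$line_id == ln, ]
    expect_equal(nrow(calls), nrow(want))
    calls <- calls[order(calls$chrom), ]
    want <- want[order(want$chrom), ]
    expect_equal(calls$chrom, want$chrom)
    expect_equal(calls$start, want$start)
    expect_equal(calls$end, want$end)
  }
})

test_that("deletions shorter than min_low_run bins stay uncalled in noise-free data", {
  spec <- genome_spec(
    data.frame(chrom = "chr1", length = 5e7, part1_length = NA),
    data.frame(line_id = "m", chrom = "chr1", start = 1e7, end = 1.3e7))
  sim <- simulate_coverage_pair(
    spec, coverage_sim_params(capture_efficiency_sd = 0,
                              residual_in_deletion = 0, poisson = FALSE))
  nc <- normalize_coverage(sim$mutant, sim$wildtype)
  expect_equal(nrow(call_deletions(nc)), 0L)
})

test_that("calls shared between lines are flagged, not removed", {
  a <- call_deletions(nc_from_values(c(1, 0.05, 0.05, 0.05, 0.05, 1, 1, 1, 1),
                                     chrom = "chr6B", line = "A1"))
  b <- call_deletions(nc_from_values(c(1, 0.05, 0.05, 0.05, 0.05, 1, 1, 1, 1),
                                     chrom = "chr6B", line = "D4"))
  flagged <- flag_shared_calls(rbind(a, b))
  expect_equal(nrow(flagged), 2L)
  expect_true(all(grepl("background_polymorphism_suspect", flagged$flags)))

  # non-overlapping calls on the same chromosome stay unflagged
  c1 <- call_deletions(nc_from_values(c(0.05, 0.05, 0.05, 0.05, 1, 1, 1, 1, 1, 1),
                                      chrom = "chr2", line = "L1"))
  c2 <- call_deletions(nc_from_values(c(1, 1, 1, 1, 1, 1, 0.05, 0.05, 0.05, 0.05),
                                      chrom = "chr2", line = "L2"))
  expect_true(all(flag_shared_calls(rbind(c1, c2))$flags == ""))

  # a call present in one of three lines is unflagged
  three <- rbind(a, c1, c2)
  three$line_id <- c("L1", "L2", "L3")
  expect_true(all(flag_shared_calls(three)$flags == ""))

  expect_message(flag_shared_calls(a), "fewer than two lines")
})

test_that("the shared 6B artifact is called in both lines and flagged", {
  spec <- paragon_layout(artifact_6b = TRUE)
  params <- coverage_sim_params(capture_efficiency_sd = 0,
                                residual_in_deletion = 0.02, poisson = FALSE)
  calls <- list()
  for (ln in c("A1", "D4")) {
    sim <- simulate_coverage_pair(spec, params, line = ln)
    nc <- lift_parts_to_full(normalize_coverage(sim$mutant, sim$wildtype),
                             sim$parts)
    calls[[ln]] <- call_deletions(nc)
  }
  expect_equal(nrow(calls$A1), 5L)
  expect_equal(nrow(calls$D4), 7L)
  flagged <- flag_shared_calls(calls)
  on6b <- flagged$chrom == "chr6B"
  expect_true(all(grepl("background_polymorphism_suspect", flagged$flags[on6b])))
  expect_true(all(flagged$flags[!on6b] == ""))
})

test_that("deletion_size equals end minus start, including published rows", {
  expect_equal(deletion_size(list(start = 576555092, end = 600555092)), 24000000)
  expect_equal(deletion_size(list(start = 562939364, end = 673617499)), 110678135)
  expect_equal(deletion_size(list(start = 0, end = 21516171)), 21516171)
  for (m in c("bin", "refined")) {
    tab <- paragon_deletions(m)
    expect_equal(deletion_size(tab), tab$size_bp)
  }
})
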