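# shuffles, z-score, p-value, convergence, per-window metric assembly

test_that("z-score arithmetic is exact", {
  expect_equal(z_score(-30, c(-20, -22, -18)), -5)
  expect_equal(z_score(-20, c(-22, -18)), 0)
  expect_true(is.na(z_score(-20, c(-20, -20, -20))))
  expect_error(z_score(-20, -21), "at least 2")
})

test_that("empirical p-value counts strictly more stable randoms", {
  expect_equal(empirical_p_value(-30, c(-35, -20, -10)), 1 / 3)
  expect_equal(empirical_p_value(-40, c(-35, -20, -10)), 0)
  expect_equal(empirical_p_value(-20, c(-20, -20)), 0)  # ties excluded
  expect_error(empirical_p_value(-20, numeric(0)), "at least 1")
})

test_that("mononucleotide shuffles conserve composition deterministically", {
  sh <- shuffle_sequence("ACGU", 20, seed = 5)
  expect_true(all(vapply(sh, function(x) {
    identical(sort(strsplit(x, "")[[1]]), c("A", "C", "G", "U"))
  }, logical(1))))
  expect_identical(sh, shuffle_sequence("ACGU", 20, seed = 5))
  expect_false(identical(sh, shuffle_sequence("ACGU", 20, seed = 6)))
  expect_true(all(shuffle_sequence("AAAA", 5, seed = 1) == "AAAA"))
  # N is permuted like any other letter
  sh <- shuffle_sequence("ACGN", 10, seed = 2)
  expect_true(all(grepl("N", sh)))
})

test_that("dinucleotide shuffles conserve dinucleotide counts", {
  dinucs <- function(x) sort(substring(x, 1:(nchar(x) - 1), 2:nchar(x)))
  s <- "ACGUACGGUUACGAACCGUAGC"
  sh <- shuffle_sequence(s, 10, seed = 8, method = "dinucleotide")
  expect_true(all(vapply(sh, function(x) identical(dinucs(x), dinucs(s)),
                         logical(1))))
  expect_identical(sh, shuffle_sequence(s, 10, seed = 8,
                                        method = "dinucleotide"))
})

test_that("per-window seeds are reproducible, distinct, and 32-bit safe", {
  s1 <- derive_seed(1, "chr1", 4001, "+")
  expect_identical(s1, derive_seed(1, "chr1", 4001, "+"))
  expect_false(s1 == derive_seed(1, "chr1", 4001, "-"))
  expect_false(s1 == derive_seed(1, "chr1", 4041, "+"))
  expect_false(s1 == derive_seed(2, "chr1", 4001, "+"))
  seeds <- vapply(seq(1, 2e6, by = 4e4), derive_seed, integer(1),
                  seed = 1, chrom = "chr1", strand = "+")
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("randomization-count convergence behaves at the extremes", {
  eng <- fold_engine("builtin:bp_min")
  # homopolymer: degenerate at the starting count
  expect_equal(converge_randomizations(strrep("A", 60), eng, seed = 3), 10)
  expect_error(converge_randomizations("GAAAC", eng, start_n = 5), "at least 10")
  set.seed(91)
  s <- hairpin_window_seq(stem = 20, loop = 6, width = 80)
  n1 <- converge_randomizations(s, eng, seed = 7)
  expect_identical(n1, converge_randomizations(s, eng, seed = 7))
  expect_gte(n1, 20)
  # the accepted count marks a genuine plateau: an independent estimate at
  # 4x the accepted count stays within the z estimator's sampling noise
  # (which exceeds the doubling tolerance for independent redraws)
  native <- engine_fold(eng, s, ensemble = FALSE)$mfe
  z_at <- function(n, seed) z_score(native, engine_mfe_batch(
    eng, shuffle_sequence(s, n, seed = seed)))
  expect_lt(abs(z_at(n1, 1001) - z_at(4 * n1, 1002)), 1)
})

test_that("window metrics: degenerate, skipped, and structured cases", {
  cfg <- scan_config(window = 120, step = 40, seed = 42)
  eng <- fold_engine("builtin:bp_min")
  # all-A window: nothing can pair
  m <- compute_window_metrics(window_row(strrep("A", 120)), cfg, eng)
  expect_equal(m$mfe, 0)
  expect_equal(m$ed, 0)
  expect_equal(m$fmfe, 1)
  expect_true(is.na(m$zscore))
  expect_true(m$degenerate)
  expect_false(m$skipped)
  # mostly-N window is skipped with null metrics
  m <- compute_window_metrics(
    window_row(paste0(strrep("N", 80), strrep("A", 40))), cfg, eng)
  expect_true(m$skipped)
  expect_true(is.na(m$mfe) && is.na(m$zscore) && is.na(m$ed))
  # a perfect hairpin dominating the window stands far out of its null
  set.seed(7)
  m <- compute_window_metrics(window_row(hairpin_window_seq(stem = 40)),
                              cfg, eng)
  expect_lt(m$zscore, -2)
  expect_equal(m$pvalue, 0)
  expect_false(m$degenerate)
})

test_that("window metrics are bit-reproducible", {
  cfg <- scan_config(window = 120, step = 40, seed = 9)
  eng <- fold_engine("builtin:bp_min")
  set.seed(12)
  w <- window_row(random_rna(120), chrom = "chr9", start = 4001)
  expect_identical(compute_window_metrics(w, cfg, eng),
                   compute_window_metrics(w, cfg, eng))
})

test_that("p-value and z-score cohere on a synthetic corpus", {
  cfg <- scan_config(window = 120, step = 40, seed = 20)
  eng <- fold_engine("builtin:bp_min")
  set.seed(20)
  rows <- lapply(1:40, function(i) {
    s <- if (i %% 4 == 0) hairpin_window_seq() else random_rna(120)
    compute_window_metrics(window_row(s, start = 1 + (i - 1) * 40), cfg, eng)
  })
  mets <- dplyr::bind_rows(rows)
  strong <- !is.na(mets$zscore) & mets$zscore < -3
  expect_true(all(mets$pvalue[strong] == 0))
})

test_that("the shuffle null is calibrated on uniform random windows", {
  cfg <- scan_config(window = 120, step = 40, seed = 33)
  eng <- fold_engine("builtin:bp_min")
  set.seed(33)
  zs <- vapply(1:500, function(i) {
    s <- random_rna(120)
    native <- engine_mfe_batch(eng, list(s))
    sh <- shuffle_sequence(s, 30, seed = derive_seed(33, "cal", i, "+"))
    z_score(native, engine_mfe_batch(eng, sh))
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.15)
})

test_that("scan_sequences returns one tidy row per window with provenance", {
  set.seed(50)
  fa <- tibble::tibble(name = "r", sequence = random_rna(280))
  cfg <- scan_config(window = 120, step = 40, seed = 4)
  m <- scan_sequences(fa, cfg)
  expect_equal(nrow(m), 2 * 5)  # both strands
  expect_true(all(c("mfe", "structure", "zscore", "pvalue", "ed", "fmfe",
                    "n_randomizations", "seed", "degenerate", "skipped")
                  %in% names(m)))
  expect_true(all(m$n_randomizations == 30))
  info <- attr(m, "scan_info")
  expect_equal(info$window, 120)
  expect_equal(info$seed, 4)
  # strand subsetting
  mf <- scan_sequences(fa, scan_config(window = 120, step = 40,
                                       strands = "forward", seed = 4))
  expect_equal(nrow(mf), 5)
  expect_true(all(mf$strand == "+"))
  # rescanning reproduces every field
  expect_identical(as.data.frame(m),
                   as.data.frame(scan_sequences(fa, cfg)))
})
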