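# synthetic fixtures and the command-line pipeline

test_that("fixture specs validate bounds, overlap and GC", {
  expect_error(fixture_spec(length = 100, gc = 0))
  expect_error(fixture_spec(length = 1000, hairpins = tibble::tibble(
    pos = 990, stem = 10, loop = 5)), "out of bounds")
  expect_error(fixture_spec(length = 1000, hairpins = tibble::tibble(
    pos = c(100, 120), stem = c(20, 20), loop = c(5, 5))), "overlap")
})

test_that("simulated chromosomes embed what the truth table says", {
  spec <- fixture_spec("chrF", 10000, gc = 0.5,
                       hairpins = tibble::tibble(pos = 5000, stem = 25,
                                                 loop = 8),
                       n_runs = tibble::tibble(pos = 100, len = 50),
                       seed = 7)
  sim <- simulate_chromosome(spec)
  expect_equal(nchar(sim$sequence), 10000)
  hp <- sim$truth[sim$truth$type == "hairpin", ]
  expect_equal(c(hp$start, hp$end), c(5000, 5000 + 2 * 25 + 8 - 1))
  # the embedded span is an exact inverted repeat (DNA alphabet)
  stem5 <- substr(sim$sequence, hp$start, hp$start + 24)
  stem3 <- substr(sim$sequence, hp$end - 24, hp$end)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", stem5), "")[[1]]),
              collapse = "")
  expect_equal(stem3, rc)
  nr <- sim$truth[sim$truth$type == "n_run", ]
  expect_equal(substr(sim$sequence, nr$start, nr$end), strrep("N", 50))
  # byte-identical under the same seed
  expect_identical(sim$sequence, simulate_chromosome(spec)$sequence)
  expect_false(identical(
    sim$sequence,
    simulate_chromosome(fixture_spec("chrF", 10000, gc = 0.5,
      hairpins = tibble::tibble(pos = 5000, stem = 25, loop = 8),
      n_runs = tibble::tibble(pos = 100, len = 50), seed = 8))$sequence))
})

test_that("generate_fixture writes FASTA plus a truth GFF3", {
  td <- withr::local_tempdir()
  spec <- fixture_spec("chrF", 2000, hairpins = tibble::tibble(
    pos = 1000, stem = 20, loop = 6), seed = 3)
  fa_path <- file.path(td, "fix.fa")
  truth_path <- file.path(td, "truth.gff3")
  generate_fixture(spec, fa_path, truth_path)
  fa <- read_fasta(fa_path)
  expect_equal(fa$name, "chrF")
  expect_equal(fa$length, 2000)
  expect_equal(readLines(truth_path)[1], "##gff-version 3")
  expect_true(any(grepl("inverted_repeat", readLines(truth_path))))
})

test_that("the scan CLI runs end to end and is byte-reproducible", {
  td <- withr::local_tempdir()
  fa_path <- file.path(td, "fix.fa")
  generate_fixture(fixture_spec("chrF", 1200, hairpins = tibble::tibble(
    pos = 600, stem = 25, loop = 8), seed = 5),
    fa_path, file.path(td, "truth.gff3"))
  suppressMessages(
    cli_scan(c("--fasta", fa_path, "--out-prefix", file.path(td, "runA"),
               "--seed", "2")))
  expect_true(file.exists(file.path(td, "runA.gff3")))
  expect_true(file.exists(file.path(td, "runA.csv")))
  expect_length(list.files(td, pattern = "runA_.*\\.bedGraph"), 10)
  suppressMessages(
    cli_scan(c("--fasta", fa_path, "--out-prefix", file.path(td, "runB"),
               "--seed", "2")))
  expect_identical(readLines(file.path(td, "runA.csv")),
                   readLines(file.path(td, "runB.csv")))
  # forward-only emits 5 tracks
  suppressMessages(
    cli_scan(c("--fasta", fa_path, "--out-prefix", file.path(td, "fwd"),
               "--strands", "forward", "--seed", "2")))
  expect_length(list.files(td, pattern = "fwd_.*\\.bedGraph"), 5)
})

test_that("the domains CLI recovers embedded hairpins from a scan CSV", {
  td <- withr::local_tempdir()
  fa_path <- file.path(td, "fix.fa")
  hp <- tibble::tibble(pos = seq(1500, 8500, by = 1000), stem = 25, loop = 8)
  gen <- generate_fixture(fixture_spec("chrF", 10000, hairpins = hp,
                                       seed = 11),
                          fa_path, file.path(td, "truth.gff3"))
  suppressMessages(
    cli_scan(c("--fasta", fa_path, "--out-prefix", file.path(td, "scan"),
               "--strands", "forward", "--seed", "6")))
  suppressMessages(
    rep <- cli_domains(c("--metrics-csv", file.path(td, "scan.csv"),
                         "--out-prefix", file.path(td, "dom"))))
  expect_true(file.exists(file.path(td, "dom_domains.csv")))
  expect_true(file.exists(file.path(td, "dom_domains.bed")))
  truth <- gen$truth
  covered <- vapply(seq_len(nrow(truth)), function(i)
    any(rep$domains$start <= truth$end[i] &
        rep$domains$end >= truth$start[i]), logical(1))
  expect_gte(mean(covered), 0.8)
  # sigma 0 puts the threshold at the regional mean
  suppressMessages(
    rep0 <- cli_domains(c("--metrics-csv", file.path(td, "scan.csv"),
                          "--out-prefix", file.path(td, "dom0"),
                          "--sigma", "0")))
  expect_equal(rep0$threshold, rep0$mean_z)
  # min-windows 1 promotes singletons
  suppressMessages(
    rep1 <- cli_domains(c("--metrics-csv", file.path(td, "scan.csv"),
                          "--out-prefix", file.path(td, "dom1"),
                          "--min-windows", "1")))
  expect_equal(nrow(rep1$singletons), 0)
  expect_gte(nrow(rep1$domains), nrow(rep$domains))
})

test_that("CLI usage errors are explicit", {
  expect_error(cli_main(character(0)), "usage")
  expect_error(cli_main("frobnicate"), "unknown subcommand")
  expect_error(cli_scan(c("--fasta", "x.fa")), "required")
  expect_error(cli_domains(c("--out-prefix", "p")), "required")
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.csv"); writeLines("x", f1)
  expect_error(cli_domains(c("--metrics-csv", f1, "--gff3", f1,
                             "--out-prefix", "p")), "mutually exclusive")
})

test_that("plot builders return ggplot objects", {
  set.seed(9)
  fa <- tibble::tibble(name = "t", sequence = random_rna(280))
  m <- scan_sequences(fa, scan_config(window = 120, step = 40, seed = 2))
  expect_s3_class(plot_metric_profile(m, "zscore"), "ggplot")
  rep <- merge_domains(m, cutoff = 0)
  expect_s3_class(autoplot(rep), "ggplot")
})
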