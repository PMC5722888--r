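# shared fixtures: models, random sequences, synthetic hairpin windows

bp_min <- energy_model("bp_min")
nn_lite <- energy_model("nn_lite")

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a window holding a perfect inverted-repeat hairpin padded with random
# background to `width` nt
hairpin_window_seq <- function(stem = 25, loop = 8, width = 120) {
  s <- sample(c("A", "C", "G", "U"), stem, replace = TRUE)
  l <- sample(c("A", "C", "G", "U"), loop, replace = TRUE)
  hp <- c(s, l, rev(chartr("ACGU", "UGCA", s)))
  pad <- width - length(hp)
  left <- pad %/% 2
  paste(c(sample(c("A", "C", "G", "U"), left, replace = TRUE), hp,
          sample(c("A", "C", "G", "U"), pad - left, replace = TRUE)),
        collapse = "")
}

window_row <- function(sequence, chrom = "w", start = 1, strand = "+") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + nchar(sequence) - 1L), strand = strand,
    sequence = sequence,
    n_count = nchar(sequence) - nchar(gsub("N", "", sequence, fixed = TRUE)))
}

# validity of a dot-bracket structure for a sequence under a model
expect_valid_structure <- function(sequence, structure, model) {
  expect_equal(nchar(structure), nchar(sequence))
  pairs <- parse_dotbracket(structure)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (nrow(pairs) > 0) {
    expect_true(all(pairs[, 2] - pairs[, 1] - 1 >= model$min_hairpin))
    expect_false(any(is.na(
      model$pair_energy[cbind(chars[pairs[, 1]], chars[pairs[, 2]])])))
    expect_false(any(chars[c(pairs)] == "N"))
  }
  invisible(pairs)
}
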