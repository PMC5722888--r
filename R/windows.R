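#' Scan configuration
#'
#' Collects the parameters of a sliding-window scan.  Defaults follow the
#' genome-database design this package implements: 120-nt windows advanced
#' by 40 nt, both strands, 30 composition-preserving randomizations per
#' window, folding at 37 C.
#'
#' @param window window size in nt (default 120).
#' @param step step between window starts in nt (default 40; must satisfy
#'   `1 <= step <= window`).
#' @param strands `"both"`, `"forward"` or `"reverse"`.
#' @param max_n_fraction windows whose fraction of N placeholders exceeds
#'   this are skipped (metrics emitted as NA with a `skipped` flag);
#'   default 0.5.
#' @param temperature folding temperature in kelvin (default 310.15).
#' @param randomizations number of shuffled sequences per window
#'   (default 30; at least 2).
#' @param seed global integer seed; per-window seeds are derived from it
#'   with [derive_seed()].
#' @param end_anchored also emit a final end-anchored window `[L-window+1, L]`
#'   when the record length minus the window size is not a multiple of the
#'   step (default FALSE: trailing remainder nucleotides are not emitted as
#'   a partial window, keeping all windows equal length).
#' @param shuffle `"mononucleotide"` (default; preserves nucleotide
#'   composition exactly) or `"dinucleotide"` (also preserves dinucleotide
#'   counts).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(window = 120, step = 40,
                        strands = c("both", "forward", "reverse"),
                        max_n_fraction = 0.5,
                        temperature = 310.15,
                        randomizations = 30,
                        seed = 1,
                        end_anchored = FALSE,
                        shuffle = c("mononucleotide", "dinucleotide")) {
  strands <- match.arg(strands)
  shuffle <- match.arg(shuffle)
  stopifnot(window >= 1, step >= 1, step <= window,
            max_n_fraction >= 0, max_n_fraction <= 1,
            randomizations >= 2, temperature > 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 strands = strands, max_n_fraction = max_n_fraction,
                 temperature = temperature,
                 randomizations = as.integer(randomizations),
                 seed = as.integer(seed), end_anchored = end_anchored,
                 shuffle = shuffle),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan config> window ", x$window, " nt, step ", x$step,
      " nt, strands ", x$strands, ", ", x$randomizations,
      " randomizations, T = ", x$temperature, " K, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Read (and normalize) a FASTA file
#'
#' Reads single- or multi-record FASTA, uppercases, converts T to U, and
#' maps IUPAC ambiguity codes other than A/C/G/T/U to N, so every sequence
#' is over the scanning alphabet A/C/G/U/N.
#'
#' @param path FASTA file path.
#' @return tibble with columns `name`, `length`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*", "", names(set))
  seqs <- as.character(set)
  empty <- nchar(seqs) == 0
  if (any(empty))
    stop("record with empty sequence: ", nm[which(empty)[1]], call. = FALSE)
  seqs <- normalize_sequence(unname(seqs))
  tibble::tibble(name = nm, length = nchar(seqs), sequence = seqs)
}

#' Write sequences to FASTA
#'
#' @param x tibble with columns `name` and `sequence`, or a named character
#'   vector.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x)) x <- tibble::tibble(name = names(x), sequence = x)
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

window_starts <- function(L, window, step, end_anchored = FALSE) {
  if (L < window) return(1L)
  starts <- seq.int(1L, L - window + 1L, by = step)
  if (end_anchored && (L - window) %% step != 0)
    starts <- c(starts, L - window + 1L)
  starts
}

#' Fragment records into overlapping forward-strand windows
#'
#' Windows start at 1, 1+step, 1+2*step, ... while they fit entirely inside
#' the record; a record shorter than the window yields a single window
#' covering the whole record.  N placeholders are kept in the window
#' sequence and counted in `n_count`.  Coordinates are 1-based inclusive.
#'
#' @param x tibble with columns `name` and `sequence` (as from
#'   [read_fasta()]).
#' @param config a [scan_config()]; `window`, `step` and `end_anchored`
#'   are used here.
#' @return tibble of window records: `chrom`, `start`, `end`, `strand`
#'   (`"+"`), `sequence` (A/C/G/U/N), `n_count`.
#' @export
#' @examples
#' fragment_windows(tibble::tibble(name = "x", sequence = strrep("ACGU", 50)),
#'                  scan_config(window = 120, step = 40))
fragment_windows <- function(x, config = scan_config()) {
  stopifnot(all(c("name", "sequence") %in% names(x)))
  purrr::pmap_dfr(list(x$name, normalize_sequence(x$sequence)),
                  function(nm, seq) {
    L <- nchar(seq)
    starts <- window_starts(L, config$window, config$step,
                            config$end_anchored)
    ends <- pmin(starts + config$window - 1L, L)
    wseq <- substring(seq, starts, ends)
    tibble::tibble(
      chrom = nm, start = as.integer(starts), end = as.integer(ends),
      strand = "+", sequence = wseq,
      n_count = nchar(wseq) - nchar(gsub("N", "", wseq, fixed = TRUE)))
  })
}

#' Reverse-complement windows onto the minus strand
#'
#' Keeps the genomic coordinates of each forward window and replaces the
#' sequence by its reverse complement (A<->U, G<->C, N<->N), i.e. the RNA
#' that would be transcribed from the opposite strand.
#'
#' @param forward_windows tibble from [fragment_windows()].
#' @return tibble of the same shape with `strand = "-"`.
#' @export
reverse_windows <- function(forward_windows) {
  dplyr::mutate(forward_windows,
                strand = "-",
                sequence = revcomp_rna(.data$sequence))
}

# forward and/or reverse windows per the config, in scan order
make_windows <- function(fasta_tbl, config) {
  fwd <- fragment_windows(fasta_tbl, config)
  out <- switch(config$strands,
    forward = fwd,
    reverse = reverse_windows(fwd),
    both = dplyr::bind_rows(fwd, reverse_windows(fwd)))
  sort_windows(out)
}
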