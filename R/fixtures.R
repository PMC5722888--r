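# Synthetic chromosome-like fixtures: i.i.d. background with controlled GC
# content, embedded inverted-repeat hairpins at known coordinates, and runs
# of N placeholders.  Makes every pipeline stage testable without any
# genome download, with a truth file for parameter-recovery checks.

#' Specify a synthetic chromosome
#'
#' @param name record name.
#' @param length chromosome length in nt.
#' @param gc background GC content, strictly between 0 and 1 (default 0.5).
#' @param hairpins tibble/data.frame with columns `pos`, `stem`, `loop`:
#'   at `pos` the fixture embeds `stem` random nt, a `loop`-nt spacer, and
#'   the reverse complement of the stem, i.e. a perfect inverted repeat
#'   spanning `2*stem + loop` nt.
#' @param n_runs tibble with columns `pos`, `len`: runs of N placeholders.
#' @param seed integer seed; the fixture is byte-reproducible.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(name = "chrS", length, gc = 0.5,
                         hairpins = NULL, n_runs = NULL, seed = 1) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  spans <- list()
  if (!is.null(hairpins) && nrow(hairpins) > 0) {
    hairpins <- tibble::as_tibble(hairpins)
    stopifnot(all(c("pos", "stem", "loop") %in% names(hairpins)))
    spans <- c(spans, lapply(seq_len(nrow(hairpins)), function(i)
      c(hairpins$pos[i],
        hairpins$pos[i] + 2 * hairpins$stem[i] + hairpins$loop[i] - 1)))
  } else hairpins <- tibble::tibble(pos = integer(), stem = integer(),
                                    loop = integer())
  if (!is.null(n_runs) && nrow(n_runs) > 0) {
    n_runs <- tibble::as_tibble(n_runs)
    stopifnot(all(c("pos", "len") %in% names(n_runs)))
    spans <- c(spans, lapply(seq_len(nrow(n_runs)), function(i)
      c(n_runs$pos[i], n_runs$pos[i] + n_runs$len[i] - 1)))
  } else n_runs <- tibble::tibble(pos = integer(), len = integer())
  if (length(spans) > 0) {
    m <- do.call(rbind, spans)
    if (any(m[, 1] < 1) || any(m[, 2] > length))
      stop("embedded element out of bounds", call. = FALSE)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("embedded elements overlap", call. = FALSE)
  }
  structure(list(name = name, length = as.integer(length), gc = gc,
                 hairpins = hairpins, n_runs = n_runs,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Simulate a chromosome from a fixture spec
#'
#' Background bases are drawn i.i.d. with the requested GC content (DNA
#' alphabet, as in a genome FASTA); each hairpin spec overwrites its span
#' with stem + loop + reverse-complemented stem; each N run overwrites its
#' span with N.  Deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `name`, `sequence` (DNA string) and `truth`, a tibble
#'   of embedded elements (`type`, `start`, `end`, `stem`, `loop`).
#' @export
simulate_chromosome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  hp <- spec$hairpins
  nr <- spec$n_runs
  seq <- with_local_seed(spec$seed, {
    chars <- sample(names(p), spec$length, replace = TRUE, prob = p)
    for (i in seq_len(nrow(hp))) {
      stem <- sample(names(p), hp$stem[i], replace = TRUE, prob = p)
      loop <- sample(names(p), hp$loop[i], replace = TRUE, prob = p)
      rc <- rev(chartr("ACGT", "TGCA", stem))
      ins <- c(stem, loop, rc)
      chars[hp$pos[i]:(hp$pos[i] + length(ins) - 1)] <- ins
    }
    for (i in seq_len(nrow(nr)))
      chars[nr$pos[i]:(nr$pos[i] + nr$len[i] - 1)] <- "N"
    paste(chars, collapse = "")
  })
  truth <- dplyr::bind_rows(
    tibble::tibble(type = "hairpin", start = as.integer(hp$pos),
                   end = as.integer(hp$pos + 2 * hp$stem + hp$loop - 1),
                   stem = as.integer(hp$stem), loop = as.integer(hp$loop)),
    tibble::tibble(type = "n_run", start = as.integer(nr$pos),
                   end = as.integer(nr$pos + nr$len - 1),
                   stem = NA_integer_, loop = NA_integer_))
  truth <- dplyr::arrange(truth, .data$start)
  list(name = spec$name, sequence = seq, truth = truth)
}

#' Generate a FASTA fixture plus truth GFF3
#'
#' Writes the simulated chromosome(s) as FASTA and the embedded-element
#' coordinates as a truth GFF3 (`inverted_repeat` / `gap` features).
#'
#' @param specs a [fixture_spec()] or list of them (one record each).
#' @param fasta_path output FASTA path.
#' @param truth_path output GFF3 path.
#' @return invisibly, list with the simulated records and the combined
#'   truth tibble (with a `chrom` column).
#' @export
generate_fixture <- function(specs, fasta_path, truth_path) {
  if (inherits(specs, "fixture_spec")) specs <- list(specs)
  sims <- lapply(specs, simulate_chromosome)
  fa <- tibble::tibble(
    name = vapply(sims, `[[`, character(1), "name"),
    sequence = vapply(sims, `[[`, character(1), "sequence"))
  write_fasta(fa, fasta_path)
  truth <- dplyr::bind_rows(lapply(sims, function(s)
    dplyr::mutate(s$truth, chrom = s$name, .before = 1)))
  lines <- if (nrow(truth)) {
    type <- ifelse(truth$type == "hairpin", "inverted_repeat", "gap")
    attrs <- paste0("ID=", truth$type, "_", truth$chrom, "_", truth$start,
                    ifelse(truth$type == "hairpin",
                           paste0(";Stem=", truth$stem, ";Loop=",
                                  truth$loop), ""))
    paste(truth$chrom, "foldscan_fixture", type, truth$start, truth$end,
          ".", "+", ".", attrs, sep = "\t")
  } else character(0)
  writeLines(c("##gff-version 3", lines), truth_path)
  invisible(list(records = sims, truth = truth))
}
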