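#' Composition-preserving sequence shuffles
#'
#' Generates randomized versions of a sequence for the thermodynamic null.
#' The default mononucleotide shuffle draws uniform random permutations of
#' the letters, so the nucleotide multiset (N placeholders included) is
#' conserved exactly.  The stricter dinucleotide shuffle also conserves all
#' dinucleotide counts, via a random Eulerian trail on the dinucleotide
#' transition graph (Altschul-Erickson construction).
#'
#' @param sequence A/C/G/U/N string.
#' @param count number of shuffles (>= 1).
#' @param seed integer seed; the output is deterministic given
#'   (sequence, count, seed).
#' @param method `"mononucleotide"` or `"dinucleotide"`.
#' @return character vector of `count` shuffled sequences.
#' @export
shuffle_sequence <- function(sequence, count, seed,
                             method = c("mononucleotide", "dinucleotide")) {
  method <- match.arg(method)
  stopifnot(count >= 1)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  with_local_seed(seed, {
    if (method == "mononucleotide") {
      vapply(seq_len(count),
             function(i) paste(sample(chars), collapse = ""),
             character(1))
    } else {
      vapply(seq_len(count),
             function(i) dinucleotide_shuffle_once(chars),
             character(1))
    }
  })
}

# one dinucleotide-preserving shuffle: randomize the multiset of outgoing
# edges per symbol, keeping for each non-terminal symbol one edge that leads
# toward the terminal symbol as its last exit (random-spanning-arborescence
# form of the Altschul-Erickson algorithm), then walk the trail
dinucleotide_shuffle_once <- function(chars) {
  n <- length(chars)
  if (n < 3) return(paste(chars, collapse = ""))
  syms <- unique(chars)
  edges <- lapply(syms, function(s) chars[which(chars[-n] == s) + 1])
  names(edges) <- syms
  last <- chars[n]
  repeat {
    shuffled <- lapply(edges, function(e) if (length(e)) sample(e) else e)
    # walk
    out <- character(n)
    out[1] <- chars[1]
    pos <- stats::setNames(rep(1L, length(syms)), syms)
    ok <- TRUE
    for (i in 2:n) {
      cur <- out[i - 1]
      k <- pos[[cur]]
      if (k > length(shuffled[[cur]])) { ok <- FALSE; break }
      out[i] <- shuffled[[cur]][k]
      pos[[cur]] <- k + 1L
    }
    if (ok && all(vapply(syms, function(s)
      pos[[s]] == length(shuffled[[s]]) + 1L, logical(1))))
      return(paste(out, collapse = ""))
    # a walk that strands edges is rejected and redrawn; termination is
    # guaranteed because a valid Eulerian ordering has positive probability
  }
}

#' Thermodynamic z-score
#'
#' `z = (dG_native - mean(dG_random)) / sd(dG_random)` with the sample
#' (n-1) standard deviation.  Negative values mean the native nucleotide
#' order folds more stably than composition-matched random sequences.
#' Returns `NA` (the degenerate case) when the random energies have zero
#' spread, e.g. for homopolymer windows.
#'
#' @param dg_native native MFE in kcal/mol.
#' @param dg_randoms numeric vector of shuffled-sequence MFEs (>= 2 values).
#' @return dimensionless z-score, or `NA_real_` when degenerate.
#' @export
#' @examples
#' z_score(-30, c(-20, -22, -18))  # -5
z_score <- function(dg_native, dg_randoms) {
  if (length(dg_randoms) < 2)
    stop("z-score needs at least 2 random energies", call. = FALSE)
  s <- stats::sd(dg_randoms)
  if (s == 0) return(NA_real_)
  (dg_native - mean(dg_randoms)) / s
}

#' Empirical p-value of the native fold
#'
#' The fraction of shuffled sequences whose MFE is strictly lower (more
#' stable) than the native MFE; ties do not count.  Values close to zero
#' mean few or no randomized sequences beat the native sequence.
#'
#' @inheritParams z_score
#' @return fraction in \[0, 1\], always a multiple of
#'   `1/length(dg_randoms)`.
#' @export
#' @examples
#' empirical_p_value(-30, c(-35, -20, -10))  # 1/3
empirical_p_value <- function(dg_native, dg_randoms) {
  if (length(dg_randoms) < 1)
    stop("p-value needs at least 1 random energy", call. = FALSE)
  sum(dg_randoms < dg_native) / length(dg_randoms)
}

#' Find a converged randomization count
#'
#' Doubles the number of shuffles until the z-score estimate moves by less
#' than `tolerance` between consecutive counts, mirroring how the
#' randomization number of a scan is calibrated.  The shuffle set grows
#' cumulatively (each doubling extends the previous set), so successive
#' estimates share their folds and the stopping rule tracks the estimate's
#' stabilization rather than independent resampling noise.  Returns the
#' first count at which the estimate has stabilized (the doubled count),
#' `start_n` immediately when the window is degenerate, or `max_n` with a
#' warning if the estimate never settles.
#'
#' @param sequence window sequence.
#' @param engine a [fold_engine()].
#' @param start_n initial count (>= 10).
#' @param max_n largest count to try.
#' @param tolerance absolute z change regarded as converged (default 0.1).
#' @param seed integer seed.
#' @return accepted randomization count (integer).
#' @export
converge_randomizations <- function(sequence, engine = fold_engine(),
                                    start_n = 10, max_n = 320,
                                    tolerance = 0.1, seed = 1) {
  if (start_n < 10) stop("start_n must be at least 10", call. = FALSE)
  engine <- fold_engine(engine)
  native <- engine_fold(engine, sequence, ensemble = FALSE)$mfe
  draw <- function(n, level) engine_mfe_batch(engine, shuffle_sequence(
    sequence, n, seed = derive_seed(seed, "conv", level, "+")))
  n <- as.integer(start_n)
  dgs <- draw(n, 0L)
  z_prev <- z_score(native, dgs)
  if (is.na(z_prev)) return(n)
  level <- 1L
  while (length(dgs) * 2L <= max_n) {
    dgs <- c(dgs, draw(length(dgs), level))
    z_new <- z_score(native, dgs)
    if (is.na(z_new) || abs(z_new - z_prev) < tolerance)
      return(length(dgs))
    z_prev <- z_new
    level <- level + 1L
  }
  warning("z-score did not converge by max_n = ", max_n)
  as.integer(max_n)
}

#' Compute the five folding metrics for one window
#'
#' Orchestrates the per-window work: fold the native sequence (MFE
#' structure plus ensemble diversity and MFE frequency), generate
#' composition-preserving shuffles from a seed derived from the window's
#' coordinates, fold the shuffles for their MFEs, and form the z-score and
#' empirical p-value.  Windows whose N fraction exceeds
#' `config$max_n_fraction` are skipped: metrics come back `NA` with
#' `skipped = TRUE`.
#'
#' @param window one-row tibble (or list) with `chrom`, `start`, `end`,
#'   `strand`, `sequence`, `n_count`.
#' @param config a [scan_config()].
#' @param engine a [fold_engine()].
#' @return one-row tibble of window metrics (see [scan_sequences()] for the
#'   columns).
#' @export
compute_window_metrics <- function(window, config = scan_config(),
                                   engine = fold_engine()) {
  engine <- fold_engine(engine)
  w <- as.list(window)
  seed_w <- derive_seed(config$seed, w$chrom, w$start, w$strand)
  width <- nchar(w$sequence)
  base <- tibble::tibble(
    chrom = w$chrom, start = as.integer(w$start), end = as.integer(w$end),
    strand = w$strand, sequence = w$sequence,
    n_count = as.integer(w$n_count),
    mfe = NA_real_, structure = NA_character_,
    zscore = NA_real_, pvalue = NA_real_,
    ed = NA_real_, fmfe = NA_real_,
    n_randomizations = config$randomizations,
    seed = as.integer(seed_w),
    degenerate = TRUE, skipped = FALSE)

  if (w$n_count / width > config$max_n_fraction) {
    base$skipped <- TRUE
    return(base)
  }
  native <- tryCatch(
    engine_fold(engine, w$sequence, ensemble = TRUE),
    error = function(e) stop("engine failure at ", w$chrom, ":", w$start,
                             "-", w$end, "(", w$strand, "): ",
                             conditionMessage(e), call. = FALSE))
  shuffles <- shuffle_sequence(w$sequence, config$randomizations,
                               seed = seed_w, method = config$shuffle)
  dg_rand <- engine_mfe_batch(engine, shuffles)
  z <- z_score(native$mfe, dg_rand)
  base$mfe <- native$mfe
  base$structure <- native$structure
  base$zscore <- z
  base$pvalue <- empirical_p_value(native$mfe, dg_rand)
  base$ed <- native$ed
  base$fmfe <- native$fmfe
  base$degenerate <- is.na(z)
  base
}

#' Scan sequences: windows in, five folding metrics out
#'
#' The main pipeline entry point.  Fragments every record into overlapping
#' windows on the requested strands, computes the five archived metrics for
#' each window (MFE and its dot-bracket structure, shuffle-null z-score,
#' empirical p-value, ensemble diversity, MFE frequency), and returns one
#' tidy row per window.  Fully deterministic for a given config seed;
#' windows are independent work units whose seeds derive from their
#' coordinates, so partial or parallel runs agree with a serial run.
#'
#' @param x FASTA tibble from [read_fasta()] (columns `name`, `sequence`),
#'   or a pre-fragmented window tibble from [fragment_windows()] /
#'   [reverse_windows()].
#' @param config a [scan_config()].
#' @param engine a [fold_engine()] or engine specification.
#' @param progress emit a message per record scanned?
#' @return tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `sequence`, `n_count`, `mfe`, `structure`, `zscore`, `pvalue`, `ed`,
#'   `fmfe`, `n_randomizations`, `seed`, `degenerate`, `skipped`, carrying
#'   the scan settings in `attr(, "scan_info")`.
#' @export
#' @examples
#' fa <- tibble::tibble(name = "toy", sequence = strrep("GGGAAACCCAU", 20))
#' m <- scan_sequences(fa, scan_config(window = 60, step = 20, seed = 7,
#'                                     strands = "forward"))
#' dplyr::select(m, start, mfe, zscore, pvalue)
scan_sequences <- function(x, config = scan_config(),
                           engine = fold_engine("builtin:bp_min"),
                           progress = FALSE) {
  engine <- fold_engine(engine)
  windows <- if (all(c("strand", "start", "sequence") %in% names(x))) {
    sort_windows(x)
  } else {
    make_windows(x, config)
  }
  res <- vector("list", nrow(windows))
  last_chrom <- ""
  for (i in seq_len(nrow(windows))) {
    if (progress && windows$chrom[i] != last_chrom) {
      last_chrom <- windows$chrom[i]
      message("scanning ", last_chrom)
    }
    res[[i]] <- compute_window_metrics(windows[i, ], config, engine)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "scan_info") <- list(
    tool = "foldscan", version = scan_tool_version(),
    engine = engine$name, window = config$window, step = config$step,
    strands = config$strands, randomizations = config$randomizations,
    temperature = config$temperature, seed = config$seed,
    shuffle = config$shuffle)
  out
}
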