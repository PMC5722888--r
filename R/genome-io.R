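# Readers/writers for the scan's data products: per-window GFF3, the
# consolidated CSV, per-metric strand-split bedGraph tracks, and joins
# against gene annotations.
#
# Numeric precision in files: energies and ED to 2 decimals, z to 2,
# p to 3, fMFE to 4; full precision is kept in memory only.

io_header <- function(metrics, comment = "#") {
  info <- attr(metrics, "scan_info")
  if (is.null(info)) return(character(0))
  paste0(comment, "! ", c(
    paste0("tool=", info$tool, " version=", info$version),
    paste0("engine=", info$engine),
    paste0("window=", info$window, " step=", info$step,
           " strands=", info$strands),
    paste0("randomizations=", info$randomizations,
           " shuffle=", info$shuffle,
           " temperature=", info$temperature,
           " seed=", info$seed)))
}

strand_tag <- function(strand) ifelse(strand == "+", "fwd", "rev")

#' Write window metrics as GFF3
#'
#' One `sequence_feature` per window: 1-based coordinates, the z-score in
#' the score column (`.` for degenerate windows), and attributes `ID`,
#' `Sequence`, `MFE`, `Zscore`, `Pvalue`, `ED`, `fMFE`, `Structure`.
#' Degenerate windows omit the `Zscore`/`Pvalue` attributes; skipped
#' windows carry only `ID` and `Sequence`.  A config-echo comment header
#' records the engine and scan settings.
#'
#' @param metrics metrics tibble from [scan_sequences()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(metrics, path) {
  attr_or <- function(name, value, keep) ifelse(keep, paste0(name, "=", value), NA)
  ids <- paste0(metrics$chrom, "_", metrics$start, "_",
                strand_tag(metrics$strand))
  folded <- !metrics$skipped
  scored <- folded & !metrics$degenerate
  attrs <- cbind(
    paste0("ID=", ids),
    paste0("Sequence=", metrics$sequence),
    attr_or("MFE", fmt_mfe(metrics$mfe), folded),
    attr_or("Zscore", fmt_z(metrics$zscore), scored),
    attr_or("Pvalue", fmt_p(metrics$pvalue), scored),
    attr_or("ED", fmt_ed(metrics$ed), folded),
    attr_or("fMFE", fmt_fmfe(metrics$fmfe), folded),
    attr_or("Structure", metrics$structure, folded))
  attr_col <- apply(attrs, 1, function(r) paste(r[!is.na(r)], collapse = ";"))
  lines <- paste(metrics$chrom, "foldscan", "sequence_feature",
                 metrics$start, metrics$end,
                 ifelse(scored, fmt_z(metrics$zscore), "."),
                 metrics$strand, ".", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", io_header(metrics, "#"), lines), path)
  invisible(path)
}

parse_gff3_attrs <- function(attr_col) {
  lapply(strsplit(attr_col, ";", fixed = TRUE), function(kv) {
    kv <- kv[nzchar(kv)]
    parts <- regmatches(kv, regexpr("=", kv), invert = TRUE)
    stats::setNames(vapply(parts, function(p) trimws(p[2]), character(1)),
                    vapply(parts, function(p) trimws(p[1]), character(1)))
  })
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read GFF3: scan output or gene annotations
#'
#' Requires the `##gff-version 3` header.  Lines whose attributes carry the
#' scanner's `Structure`/`MFE` keys are returned as a metrics tibble
#' (degenerate windows get `NA` z/p); Gencode-style lines with
#' `gene_id`/`gene_name` come back as a gene-feature tibble with columns
#' `id`, `symbol`, `type`, `chrom`, `start`, `end`, `strand`.  Malformed
#' lines raise an error naming the line number.
#'
#' @param path GFF3 path.
#' @param what `"auto"` (default), `"metrics"`, or `"genes"`.
#' @return a tibble (see above).
#' @export
read_gff3 <- function(path, what = c("auto", "metrics", "genes")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^##gff-version 3", lines[1]))
    stop("not a GFF3 file (missing '##gff-version 3' header): ", path,
         call. = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 9)
  if (length(bad) > 0)
    stop("malformed GFF3 line ", lineno[bad[1]], " in ", path,
         call. = FALSE)
  m <- do.call(rbind, rows)
  attrs <- parse_gff3_attrs(m[, 9])
  has_metrics <- vapply(attrs, function(a) "Sequence" %in% names(a),
                        logical(1))
  if (what == "auto") what <- if (all(has_metrics)) "metrics" else "genes"
  if (what == "metrics") {
    get <- function(key) vapply(attrs, function(a)
      if (key %in% names(a)) a[[key]] else NA_character_, character(1))
    z <- num_or_na(get("Zscore"))
    tibble::tibble(
      chrom = m[, 1], start = as.integer(m[, 4]), end = as.integer(m[, 5]),
      strand = m[, 7], sequence = get("Sequence"),
      n_count = nchar(get("Sequence")) -
        nchar(gsub("N", "", get("Sequence"), fixed = TRUE)),
      mfe = num_or_na(get("MFE")), structure = get("Structure"),
      zscore = z, pvalue = num_or_na(get("Pvalue")),
      ed = num_or_na(get("ED")), fmfe = num_or_na(get("fMFE")),
      degenerate = is.na(z), skipped = is.na(get("MFE")))
  } else {
    get <- function(key) vapply(attrs, function(a)
      if (key %in% names(a)) a[[key]] else NA_character_, character(1))
    tibble::tibble(
      id = get("gene_id"), symbol = get("gene_name"), type = m[, 3],
      chrom = m[, 1], start = as.integer(m[, 4]), end = as.integer(m[, 5]),
      strand = m[, 7])
  }
}

#' Write the consolidated metrics CSV
#'
#' Columns `chrom,start,end,strand,sequence,mfe,zscore,pvalue,ed,fmfe,`
#' `structure` in that order; degenerate/skipped fields are empty cells.
#' Values contain no commas, so no quoting is needed.  A `#` comment header
#' echoes the scan settings.
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- tibble::tibble(
    chrom = metrics$chrom, start = metrics$start, end = metrics$end,
    strand = metrics$strand, sequence = metrics$sequence,
    mfe = fmt_mfe(metrics$mfe), zscore = fmt_z(metrics$zscore),
    pvalue = fmt_p(metrics$pvalue), ed = fmt_ed(metrics$ed),
    fmfe = fmt_fmfe(metrics$fmfe),
    structure = ifelse(is.na(metrics$structure), "", metrics$structure))
  stopifnot(!any(grepl(",", unlist(df))))
  body <- readr::format_csv(df)
  readr::write_lines(c(io_header(metrics), sub("\n$", "", body)), path)
  invisible(path)
}

#' Read a consolidated metrics CSV
#'
#' @param path CSV written by [write_metrics_csv()].
#' @return metrics tibble (degenerate flags reconstructed from empty
#'   z cells).
#' @export
read_metrics_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    chrom = "c", start = "i", end = "i", strand = "c", sequence = "c",
    mfe = "d", zscore = "d", pvalue = "d", ed = "d", fmfe = "d",
    structure = "c"))
  dplyr::mutate(df,
    n_count = nchar(.data$sequence) -
      nchar(gsub("N", "", .data$sequence, fixed = TRUE)),
    degenerate = is.na(.data$zscore), skipped = is.na(.data$mfe),
    .after = "sequence")
}

#' Write per-metric strand-split bedGraph tracks
#'
#' One text bedGraph per metric (mfe, zscore, pvalue, ed, fmfe) and strand
#' present in the data.  Each window contributes one interval covering only
#' its initial `step` nucleotides (genomic `[start-1, start-1+step)`,
#' 0-based half-open), so on the step grid the intervals tile the scanned
#' region without overlap; windows lacking the metric (degenerate or
#' skipped) are omitted.
#'
#' @param metrics metrics tibble, sorted by coordinate.
#' @param out_prefix path prefix; files are named
#'   `<prefix>_<metric>_<fwd|rev>.bedGraph`.
#' @param step trimmed interval length; defaults to the scan step recorded
#'   in the metrics.
#' @return character vector of files written (5 per strand present).
#' @export
write_metric_tracks <- function(metrics, out_prefix, step = NULL) {
  info <- attr(metrics, "scan_info")
  if (is.null(step)) step <- info$step
  if (is.null(step)) stop("supply `step` (not recorded in metrics)",
                          call. = FALSE)
  fmts <- list(mfe = fmt_mfe, zscore = fmt_z, pvalue = fmt_p,
               ed = fmt_ed, fmfe = fmt_fmfe)
  files <- character(0)
  for (metric in names(fmts)) {
    for (str in sort(unique(metrics$strand))) {
      rows <- metrics[metrics$strand == str & !is.na(metrics[[metric]]), ]
      rows <- rows[order(rows$chrom, rows$start), ]
      from <- rows$start - 1L
      to <- pmin(from + step, rows$end)
      # the step grid guarantees non-overlap within a record
      by_chrom <- split(seq_len(nrow(rows)), rows$chrom)
      for (idx in by_chrom)
        stopifnot(all(from[idx][-1] >= to[idx][-length(idx)]))
      f <- paste0(out_prefix, "_", metric, "_", strand_tag(str),
                  ".bedGraph")
      lines <- paste(rows$chrom, from, to, fmts[[metric]](rows[[metric]]),
                     sep = "\t")
      writeLines(c(io_header(metrics), lines), f)
      files <- c(files, f)
    }
  }
  files
}

parse_region <- function(region) {
  if (is.list(region)) return(region)
  m <- regmatches(region,
                  regexec("^(.+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4) stop("cannot parse region: ", region, call. = FALSE)
  list(chrom = m[2], start = as.integer(gsub(",", "", m[3])),
       end = as.integer(gsub(",", "", m[4])))
}

#' Select windows by annotation, coordinates and metric filters
#'
#' Returns the windows overlapping (by at least 1 nt) the selected gene or
#' region; coordinate, gene-id and symbol filters compose as an
#' intersection, and additional metric filters can be given as
#' `dplyr::filter()` expressions in `...` (e.g. `zscore < -2`).  An unknown
#' gene id or symbol yields an empty result with a warning.
#'
#' @param metrics metrics tibble.
#' @param features gene-feature tibble from
#'   `read_gff3(..., what = "genes")`; needed for id/symbol filters.
#' @param ... metric filter expressions.
#' @param region `"chrom:start-end"` string or `list(chrom, start, end)`.
#' @param gene_id Ensembl-style gene id.
#' @param gene_symbol gene symbol.
#' @return filtered metrics tibble.
#' @export
annotate_windows <- function(metrics, features = NULL, ..., region = NULL,
                             gene_id = NULL, gene_symbol = NULL) {
  out <- metrics
  lookup <- function(col, value) {
    hit <- features[!is.na(features[[col]]) & features[[col]] == value, ]
    if (nrow(hit) == 0) {
      warning("no feature with ", col, " = ", value)
      return(NULL)
    }
    list(chrom = hit$chrom[1], start = min(hit$start), end = max(hit$end))
  }
  regions <- list()
  if (!is.null(region)) regions <- c(regions, list(parse_region(region)))
  if (!is.null(gene_id)) {
    if (is.null(features)) stop("gene filters need `features`", call. = FALSE)
    r <- lookup("id", gene_id)
    if (is.null(r)) return(out[0, ])
    regions <- c(regions, list(r))
  }
  if (!is.null(gene_symbol)) {
    if (is.null(features)) stop("gene filters need `features`", call. = FALSE)
    r <- lookup("symbol", gene_symbol)
    if (is.null(r)) return(out[0, ])
    regions <- c(regions, list(r))
  }
  for (r in regions)
    out <- out[out$chrom == r$chrom & out$start <= r$end &
               out$end >= r$start, ]
  dots <- rlang::enquos(...)
  if (length(dots) > 0) out <- dplyr::filter(out, !!!dots)
  out
}
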