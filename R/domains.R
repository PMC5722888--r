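# Structured-domain discovery: concatenate runs of consecutive low-z
# windows into candidate domains and summarize them.

#' Regional z-score cutoff
#'
#' `cutoff = mean(z) - sigma_multiplier * sd(z)` over the non-degenerate
#' windows of the scanned region (sample sd, n-1).  With the default
#' multiplier of 1 this selects windows at least one standard deviation
#' more negative than the regional average.
#'
#' @param metrics metrics tibble from [scan_sequences()].
#' @param sigma_multiplier how many regional standard deviations below the
#'   mean (default 1).
#' @return the z cutoff.
#' @export
domain_threshold <- function(metrics, sigma_multiplier = 1) {
  z <- metrics$zscore[!is.na(metrics$zscore)]
  if (length(z) < 2)
    stop("need at least 2 non-degenerate windows to set a threshold",
         call. = FALSE)
  mean(z) - sigma_multiplier * stats::sd(z)
}

#' Summarize a set of member windows
#'
#' Arithmetic mean and minimum of the z-score, native MFE and ensemble
#' diversity over the windows of a domain; invariant under window order.
#'
#' @param metrics tibble of member windows.
#' @return one-row tibble with `z_avg`, `z_min`, `dg_avg`, `dg_min`,
#'   `ed_avg`, `ed_min`.
#' @export
region_summary <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  tibble::tibble(
    z_avg = mean(metrics$zscore), z_min = min(metrics$zscore),
    dg_avg = mean(metrics$mfe), dg_min = min(metrics$mfe),
    ed_avg = mean(metrics$ed), ed_min = min(metrics$ed))
}

#' Concatenate low-z windows into structured domains
#'
#' Maximal runs of at least `min_windows` consecutive windows (adjacent on
#' the step grid: start difference exactly `step`, same record and strand)
#' with `zscore < cutoff` become domains spanning from the first member's
#' start to the last member's end.  Shorter runs are reported as singleton
#' low-z windows.  Windows separated by a skipped or degenerate window do
#' not merge.  Strands are processed independently.
#'
#' @param metrics metrics tibble sorted by (chrom, strand, start); unsorted
#'   input is an error.
#' @param cutoff z cutoff; computed via [domain_threshold()] when `NULL`.
#' @param sigma_multiplier forwarded to [domain_threshold()] when `cutoff`
#'   is `NULL`.
#' @param min_windows minimum run length for a domain (default 2).
#' @param step the scan step in nt; taken from `attr(metrics, "scan_info")`
#'   when available.
#' @return an object of class `domain_report`: a list with `threshold`,
#'   `sigma_multiplier`, `mean_z`, `sd_z`, `step`, `min_windows`, a
#'   `domains` tibble (`label`, coordinates, `window_count`, `z_avg`,
#'   `z_min`, `dg_avg`, `dg_min`, `ed_avg`, `ed_min`) labelled with roman
#'   numerals in genomic order, a `singletons` tibble of low-z windows not
#'   in any domain, and the scanned `windows`.
#' @export
merge_domains <- function(metrics, cutoff = NULL, sigma_multiplier = 1,
                          min_windows = 2, step = NULL) {
  if (!identical(window_order(metrics), seq_len(nrow(metrics))))
    stop("metrics must be sorted by (chrom, strand, start)", call. = FALSE)
  info <- attr(metrics, "scan_info")
  if (is.null(step)) {
    step <- info$step
    if (is.null(step)) {
      d <- diff(metrics$start)
      d <- d[d > 0]
      if (length(d) == 0)
        stop("cannot infer the scan step; supply `step`", call. = FALSE)
      step <- min(d)
    }
  }
  z_all <- metrics$zscore[!is.na(metrics$zscore)]
  mean_z <- mean(z_all); sd_z <- stats::sd(z_all)
  if (is.null(cutoff))
    cutoff <- domain_threshold(metrics, sigma_multiplier)

  low <- metrics[!is.na(metrics$zscore) & metrics$zscore < cutoff, ]
  domains <- tibble::tibble()
  singles <- tibble::tibble()
  if (nrow(low) > 0) {
    new_run <- c(TRUE, !(low$chrom[-1] == low$chrom[-nrow(low)] &
                         low$strand[-1] == low$strand[-nrow(low)] &
                         diff(low$start) == step))
    run_id <- cumsum(new_run)
    pieces <- split(low, run_id)
    is_domain <- vapply(pieces, nrow, integer(1)) >= min_windows
    if (any(is_domain)) {
      domains <- purrr::map_dfr(pieces[is_domain], function(p) {
        dplyr::bind_cols(
          tibble::tibble(chrom = p$chrom[1], start = min(p$start),
                         end = max(p$end), strand = p$strand[1],
                         window_count = nrow(p)),
          region_summary(p))
      })
      domains <- dplyr::arrange(domains, .data$chrom, .data$strand,
                                .data$start)
      domains <- dplyr::mutate(domains,
        label = as.character(utils::as.roman(dplyr::row_number())),
        .before = 1)
    }
    if (any(!is_domain))
      singles <- dplyr::bind_rows(pieces[!is_domain])
  }
  structure(list(
    threshold = cutoff, sigma_multiplier = sigma_multiplier,
    mean_z = mean_z, sd_z = sd_z, step = step, min_windows = min_windows,
    domains = domains, singletons = singles, windows = metrics),
    class = "domain_report")
}

#' @export
print.domain_report <- function(x, ...) {
  cat("<domain report>\n")
  cat("  z threshold ", formatC(x$threshold, format = "f", digits = 2),
      " (mean ", formatC(x$mean_z, format = "f", digits = 2), " - ",
      x$sigma_multiplier, " sd ", formatC(x$sd_z, format = "f", digits = 2),
      ")\n", sep = "")
  cat("  ", nrow(x$domains), " domains, ", nrow(x$singletons),
      " singleton low-z windows\n", sep = "")
  if (nrow(x$domains) > 0) print(x$domains, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a domain report into its domain table
#' @param x a `domain_report`.
#' @param ... unused.
#' @return the `domains` tibble.
#' @export
tidy.domain_report <- function(x, ...) x$domains

#' One-row summary of a domain report
#' @param x a `domain_report`.
#' @param ... unused.
#' @return one-row tibble: threshold, regional mean/sd z, domain and
#'   singleton counts, total nucleotides covered by domains.
#' @export
glance.domain_report <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, mean_z = x$mean_z, sd_z = x$sd_z,
    n_domains = nrow(x$domains), n_singletons = nrow(x$singletons),
    domain_nt = if (nrow(x$domains)) sum(x$domains$end - x$domains$start + 1)
                else 0L)
}
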