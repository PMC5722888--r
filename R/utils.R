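# shared helpers: alphabet handling, seeds, number formatting

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U, and maps any IUPAC ambiguity code other than
#' A/C/G/T/U to N.
#'
#' @param x character vector of sequences.
#' @return character vector over A, C, G, U, N.
#' @keywords internal
normalize_sequence <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  # anything outside ACGUN becomes N
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[!chars %in% RNA_ALPHABET] <- "N"
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# integer encoding used by the compiled core (A=0 C=1 G=2 U=3 N=4)
encode_sequence <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  code <- match(chars, RNA_ALPHABET) - 1L
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("invalid characters in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  code
}

# accept lowercase and DNA input in folding entry points, reject the rest
check_fold_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence))
    stop("sequence must be a single character string", call. = FALSE)
  if (nchar(sequence) < 1) stop("empty sequence", call. = FALSE)
  s <- chartr("Tt", "Uu", toupper(sequence))
  s <- toupper(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(chars %in% RNA_ALPHABET))
    stop("invalid characters in sequence: ",
         paste(unique(chars[!chars %in% RNA_ALPHABET]), collapse = ", "),
         call. = FALSE)
  s
}

#' Reverse complement in RNA space
#'
#' A<->U, G<->C, N<->N, reading the string backwards.
#'
#' @param x character vector of A/C/G/U/N sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_rna("GGAU")
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Derive a reproducible per-window seed
#'
#' Hashes the global seed with the window's chromosome, start and strand so
#' that any window's metrics can be recomputed in isolation and parallel or
#' partial runs agree with a full serial run.  Result is in `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param chrom chromosome / record identifier.
#' @param start 1-based window start.
#' @param strand "+" or "-".
#' @return integer seed.
#' @export
derive_seed <- function(seed, chrom, start, strand) {
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(as.character(chrom))) h <- (h * 131 + k) %% m
  h <- (h * 131 + as.numeric(start)) %% m
  h <- (h * 131 + if (identical(strand, "-")) 2 else 1) %% m
  as.integer(h)
}

# run code under a temporary RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fixed-precision formatting used in all output files
fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}
fmt_mfe  <- function(x) fmt_num(x, 2)
fmt_z    <- function(x) fmt_num(x, 2)
fmt_p    <- function(x) fmt_num(x, 3)
fmt_ed   <- function(x) fmt_num(x, 2)
fmt_fmfe <- function(x) fmt_num(x, 4)

# canonical window ordering: record, then strand (+ before -), then start;
# locale-independent
window_order <- function(df) {
  order(df$chrom, match(df$strand, c("+", "-")), df$start, method = "radix")
}
sort_windows <- function(df) df[window_order(df), ]

scan_tool_version <- function() {
  as.character(utils::packageVersion("foldscan"))
}
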