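#' Nearest-neighbor energy models
#'
#' An energy model bundles the pairing rules and thermodynamic parameters the
#' folding engine uses: the set of allowed base pairs (the six canonical
#' pairs AU, UA, GC, CG, GU, UG; N never pairs), the minimum hairpin loop
#' size, the temperature, and per-model energy tables.
#'
#' Two models ship with the package:
#'
#' * `"bp_min"` - every allowed pair contributes -1.0 kcal/mol and all loop
#'   terms are zero, so the minimum free energy is minus the maximum number
#'   of admissible pairs.  Fast, fully transparent, and the model all
#'   enumeration oracles and worked examples use.
#' * `"nn_lite"` - a lightweight nearest-neighbor model: a 6x6
#'   Watson-Crick/GU stacking table plus size-dependent hairpin, bulge and
#'   internal loop penalties and an affine multiloop term
#'   `a + b * branches + c * unpaired` (defaults 3.4, 0.4, 0.0 kcal/mol),
#'   loaded from a plain-text parameter file shipped in
#'   `system.file("extdata", "nn_lite.par", package = "foldscan")`.
#'
#' Neither built-in model reproduces full Turner-parameter engines such as
#' RNAfold; use [rnafold_engine()] to delegate to one.
#'
#' @param name `"bp_min"` or `"nn_lite"`.
#' @param temperature folding temperature in kelvin (default 310.15, 37 C).
#' @param params optional path to a parameter file (see
#'   [read_energy_params()]); defaults to the shipped `nn_lite.par` when
#'   `name = "nn_lite"`.
#' @param min_hairpin minimum number of unpaired nucleotides in a hairpin
#'   loop (default 3).
#' @param max_internal cap on the total number of unpaired nucleotides in a
#'   bulge or internal loop considered by the dynamic programs (default 30,
#'   the conventional cap).
#' @return an object of class `foldscan_model`.
#' @export
#' @examples
#' m <- energy_model("bp_min")
#' fold_mfe("GGGAAACCC", m)
energy_model <- function(name = c("bp_min", "nn_lite"),
                         temperature = 310.15,
                         params = NULL,
                         min_hairpin = 3,
                         max_internal = 30) {
  name <- match.arg(name)
  gas_constant <- 0.0019872
  stopifnot(temperature > 0, min_hairpin >= 0, max_internal >= 0)

  pair_energy <- matrix(NA_real_, 5, 5,
                        dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  canonical <- rbind(c("A", "U"), c("U", "A"), c("G", "C"),
                     c("C", "G"), c("G", "U"), c("U", "G"))

  if (name == "bp_min") {
    pair_energy[canonical] <- -1.0
    pair_codes <- c("AU", "UA", "GC", "CG", "GU", "UG")
    tabs <- list(
      stack = matrix(0, 6, 6, dimnames = list(pair_codes, pair_codes)),
      lxc = 0,
      hairpin = rep(0, 30), bulge = rep(0, 30), internal = rep(0, 30),
      multiloop = c(0, 0, 0))
  } else {
    pair_energy[canonical] <- 0.0
    if (is.null(params))
      params <- system.file("extdata", "nn_lite.par", package = "foldscan")
    tabs <- read_energy_params(params)
  }

  model <- structure(list(
    name = name,
    pair_energy = pair_energy,
    stack = tabs$stack,
    hairpin = tabs$hairpin,
    bulge = tabs$bulge,
    internal = tabs$internal,
    lxc = tabs$lxc,
    multiloop = tabs$multiloop,
    min_hairpin = as.integer(min_hairpin),
    max_internal = as.integer(max_internal),
    temperature = temperature,
    gas_constant = gas_constant,
    RT = gas_constant * temperature
  ), class = "foldscan_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  stopifnot(model$temperature > 0, model$gas_constant > 0,
            model$min_hairpin >= 0)
  pe <- model$pair_energy
  # allowed pairs must be symmetric under reversal
  if (!identical(is.na(pe), is.na(t(pe))))
    stop("allowed_pairs is not symmetric under reversal", call. = FALSE)
  if (any(!is.na(pe["N", ])) || any(!is.na(pe[, "N"])))
    stop("N must never pair", call. = FALSE)
  invisible(model)
}

#' Read an energy parameter file
#'
#' Plain-text key/value schema, one record per line, `#` comments:
#' `multiloop a b c`, `lxc x`, `stack <outer-pair> <inner-pair> <kcal/mol>`,
#' and `hairpin|bulge|internal <size> <kcal/mol>`.  Loop tables must cover
#' sizes up to 30; larger loops are extrapolated logarithmically with
#' coefficient `lxc`.
#'
#' @param path file path.
#' @return list with elements `stack` (6x6 matrix indexed AU, UA, GC, CG,
#'   GU, UG), `hairpin`, `bulge`, `internal` (length-30 numeric vectors
#'   indexed by loop size), `lxc`, and `multiloop` (length-3 numeric).
#' @export
read_energy_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pair_codes <- c("AU", "UA", "GC", "CG", "GU", "UG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pair_codes, pair_codes))
  hairpin <- rep(NA_real_, 30); bulge <- rep(NA_real_, 30)
  internal <- rep(NA_real_, 30)
  lxc <- 0; multiloop <- c(0, 0, 0)
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- f[1]
    if (key == "multiloop") {
      multiloop <- as.numeric(f[2:4])
    } else if (key == "lxc") {
      lxc <- as.numeric(f[2])
    } else if (key == "stack") {
      if (!f[2] %in% pair_codes || !f[3] %in% pair_codes)
        stop("unknown pair code in: ", ln, call. = FALSE)
      stack[f[2], f[3]] <- as.numeric(f[4])
    } else if (key %in% c("hairpin", "bulge", "internal")) {
      size <- as.integer(f[2])
      if (is.na(size) || size < 1 || size > 30)
        stop("loop size out of range in: ", ln, call. = FALSE)
      val <- as.numeric(f[3])
      if (key == "hairpin") hairpin[size] <- val
      else if (key == "bulge") bulge[size] <- val
      else internal[size] <- val
    } else stop("unknown key in parameter file: ", key, call. = FALSE)
  }
  # unreachable loop sizes (hairpins below the minimum loop, internal loops
  # below 2 nt) default to a prohibitive energy
  hairpin[is.na(hairpin)] <- 99
  bulge[is.na(bulge)] <- 99
  internal[is.na(internal)] <- 99
  if (any(is.na(stack))) stop("incomplete stack table", call. = FALSE)
  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       lxc = lxc, multiloop = multiloop)
}

#' @export
print.foldscan_model <- function(x, ...) {
  cat("<foldscan energy model '", x$name, "'>\n", sep = "")
  cat("  temperature: ", x$temperature, " K (RT = ",
      formatC(x$RT, format = "f", digits = 5), " kcal/mol)\n", sep = "")
  cat("  min hairpin loop: ", x$min_hairpin,
      " nt; internal loop cap: ", x$max_internal, " nt\n", sep = "")
  cat("  multiloop (a, b, c): ",
      paste(x$multiloop, collapse = ", "), " kcal/mol\n", sep = "")
  invisible(x)
}

# TRUE when the model is equivalent to maximum pairing (uniform per-pair
# energy, all loop terms zero), enabling the O(n^3/6) fast path
model_is_uniform <- function(model) {
  pe <- model$pair_energy[!is.na(model$pair_energy)]
  length(unique(pe)) == 1 &&
    all(model$stack == 0) && all(model$hairpin == 0) &&
    all(model$bulge == 0) && all(model$internal == 0) &&
    all(model$multiloop == 0)
}

# list handed to the C++ core
model_for_cpp <- function(model) {
  list(pair_energy = model$pair_energy,
       stack = model$stack,
       hairpin = model$hairpin,
       bulge = model$bulge,
       internal = model$internal,
       lxc = model$lxc,
       multiloop = model$multiloop,
       min_hairpin = model$min_hairpin,
       max_internal = model$max_internal,
       RT = model$RT)
}
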