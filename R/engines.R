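# Folding engines.  The scanning pipeline is engine-agnostic: an engine is a
# list with a name plus three callables, and everything downstream only ever
# calls engine_fold() / engine_mfe_batch().

#' Construct a folding engine
#'
#' An engine wraps a folding backend behind a uniform contract so the
#' scanning pipeline never needs to know how windows are folded.  Accepted
#' specifications:
#'
#' * `"builtin:bp_min"` / `"builtin:nn_lite"` - the compiled built-in
#'   engine under the named [energy_model()];
#' * a `foldscan_model` object - the built-in engine under that model;
#' * `"rnafold"` - delegate to an external RNAfold executable
#'   (see [rnafold_engine()]);
#' * a function - a custom adapter, see [engine_adapter()].
#'
#' @param spec engine specification (see above).
#' @param temperature folding temperature in kelvin; forwarded to the model
#'   or external engine.
#' @return an object of class `fold_engine`.
#' @export
#' @examples
#' eng <- fold_engine("builtin:bp_min")
#' engine_fold(eng, "GGGAAACCC")$mfe
fold_engine <- function(spec = "builtin:bp_min", temperature = 310.15) {
  if (inherits(spec, "fold_engine")) return(spec)
  if (inherits(spec, "foldscan_model")) return(builtin_engine(spec))
  if (is.function(spec)) return(engine_adapter(spec, temperature = temperature))
  if (!is.character(spec) || length(spec) != 1)
    stop("cannot interpret engine specification", call. = FALSE)
  if (spec %in% c("builtin:bp_min", "builtin:nn_lite")) {
    name <- sub("^builtin:", "", spec)
    return(builtin_engine(energy_model(name, temperature = temperature)))
  }
  if (spec %in% c("rnafold", "adapter:rnafold"))
    return(rnafold_engine(temperature = temperature))
  stop("engine not found: ", spec, call. = FALSE)
}

builtin_engine <- function(model) {
  structure(list(
    name = paste0("builtin:", model$name),
    model = model,
    fold = function(sequence, ensemble = TRUE) {
      mfe <- fold_mfe(sequence, model)
      out <- list(mfe = mfe$energy, structure = mfe$structure,
                  ensemble_free_energy = NA_real_, ed = NA_real_,
                  fmfe = NA_real_)
      if (ensemble) {
        ens <- fold_ensemble(sequence, model, mfe = mfe)
        out$ensemble_free_energy <- ens$ensemble_free_energy
        out$ed <- ens$ensemble_diversity
        out$fmfe <- ens$mfe_frequency
      }
      out
    },
    mfe_batch = function(sequences) fold_energies(sequences, model)
  ), class = "fold_engine")
}

#' Wrap an external folding callable as an engine
#'
#' The adapter contract: `fun(sequence, temperature)` must return a list
#' with elements `mfe` (kcal/mol) and `structure` (dot-bracket), and for
#' ensemble calls either `ed` and `fmfe` directly or an
#' `ensemble_free_energy` from which they can be derived.  The pipeline
#' treats adapter engines exactly like the built-in ones.
#'
#' @param fun the callable.
#' @param name engine name used in logs and file headers.
#' @param temperature kelvin, passed through to `fun`.
#' @return a `fold_engine`.
#' @export
engine_adapter <- function(fun, name = "adapter", temperature = 310.15) {
  stopifnot(is.function(fun))
  structure(list(
    name = name,
    model = NULL,
    fold = function(sequence, ensemble = TRUE) {
      res <- fun(sequence, temperature)
      if (!all(c("mfe", "structure") %in% names(res)))
        stop("adapter must return 'mfe' and 'structure'", call. = FALSE)
      list(mfe = res$mfe, structure = res$structure,
           ensemble_free_energy = res$ensemble_free_energy %||% NA_real_,
           ed = res$ed %||% NA_real_, fmfe = res$fmfe %||% NA_real_)
    },
    mfe_batch = function(sequences)
      vapply(sequences, function(s) fun(s, temperature)$mfe, numeric(1))
  ), class = "fold_engine")
}

#' RNAfold adapter engine
#'
#' Delegates folding to an RNAfold executable (ViennaRNA) found on the
#' search path: full Turner-parameter MFE, ensemble free energy, ensemble
#' diversity and MFE frequency.  Batch MFE calls stream all sequences
#' through a single process.  Errors immediately if the executable is not
#' available - there is no silent fallback to the built-in engine.
#'
#' @param temperature kelvin (converted to RNAfold's Celsius flag).
#' @param exe executable name or path (default `"RNAfold"`).
#' @return a `fold_engine`.
#' @export
rnafold_engine <- function(temperature = 310.15, exe = "RNAfold") {
  path <- Sys.which(exe)
  if (!nzchar(path))
    stop("engine not found: RNAfold executable '", exe,
         "' is not on the PATH", call. = FALSE)
  celsius <- temperature - 273.15

  run <- function(seqs, partition) {
    args <- c("--noPS", "-T", format(celsius))
    if (partition) args <- c(args, "-p")
    dir <- tempfile("rnafold")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    owd <- setwd(dir); on.exit(setwd(owd), add = TRUE, after = FALSE)
    out <- system2(path, args, input = seqs, stdout = TRUE, stderr = FALSE)
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop("RNAfold exited with status ", status, call. = FALSE)
    out
  }
  parse_energy <- function(line) {
    as.numeric(sub(".*[\\(\\[\\{]\\s*(-?[0-9.]+).*", "\\1", line))
  }

  structure(list(
    name = "rnafold",
    model = NULL,
    fold = function(sequence, ensemble = TRUE) {
      sequence <- check_fold_sequence(sequence)
      out <- run(sequence, partition = ensemble)
      mfe_line <- out[2]
      db <- sub("\\s.*", "", mfe_line)
      res <- list(mfe = parse_energy(mfe_line), structure = db,
                  ensemble_free_energy = NA_real_,
                  ed = NA_real_, fmfe = NA_real_)
      if (ensemble) {
        res$ensemble_free_energy <- parse_energy(out[3])
        freq_line <- out[grepl("frequency of mfe structure", out)][1]
        res$fmfe <- as.numeric(sub(".*ensemble\\s+([0-9.eE+-]+);.*", "\\1",
                                   freq_line))
        res$ed <- as.numeric(sub(".*ensemble diversity\\s+([0-9.eE+-]+).*",
                                 "\\1", freq_line))
      }
      res
    },
    mfe_batch = function(sequences) {
      sequences <- vapply(sequences, check_fold_sequence, character(1),
                          USE.NAMES = FALSE)
      out <- run(sequences, partition = FALSE)
      vapply(out[seq(2, length(out), by = 2)], parse_energy, numeric(1),
             USE.NAMES = FALSE)
    }
  ), class = "fold_engine")
}

#' Fold one sequence through an engine
#'
#' @param engine a [fold_engine()].
#' @param sequence RNA string.
#' @param ensemble also compute ensemble quantities (ED, fMFE)?
#' @return list with `mfe`, `structure`, `ensemble_free_energy`, `ed`,
#'   `fmfe`.
#' @export
engine_fold <- function(engine, sequence, ensemble = TRUE) {
  engine <- fold_engine(engine)
  engine$fold(sequence, ensemble = ensemble)
}

#' MFE energies for many sequences (used for the shuffled nulls)
#' @param engine a [fold_engine()].
#' @param sequences list or character vector of RNA strings.
#' @return numeric vector of MFE energies (kcal/mol).
#' @export
engine_mfe_batch <- function(engine, sequences) {
  engine <- fold_engine(engine)
  engine$mfe_batch(sequences)
}

#' @export
print.fold_engine <- function(x, ...) {
  cat("<fold engine '", x$name, "'>\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
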