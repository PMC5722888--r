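#' Minimum free energy structure of an RNA sequence
#'
#' Predicts the pseudoknot-free minimum free energy (MFE) secondary
#' structure under a nearest-neighbor model by dynamic programming over the
#' usual loop decomposition (hairpin, stacked pair, bulge/internal loop,
#' multiloop with an affine penalty).  Ties are broken deterministically:
#' the external trace prefers leaving the 3'-most base unpaired, then the
#' smallest 5' partner for a closing pair, so repeated calls give
#' byte-identical dot-bracket strings.
#'
#' N is accepted as a placeholder: it never pairs and contributes no energy.
#' The empty structure is always admissible, so the reported energy is
#' never positive.
#'
#' @param sequence RNA string over A/C/G/U/N (T and lowercase are accepted
#'   and normalized).
#' @param model an [energy_model()].
#' @return list of class `fold_result` with elements `energy` (kcal/mol)
#'   and `structure` (dot-bracket string of the same length).
#' @export
#' @examples
#' fold_mfe("GGGAAACCC", energy_model("bp_min"))
fold_mfe <- function(sequence, model = energy_model("bp_min")) {
  sequence <- check_fold_sequence(sequence)
  res <- cpp_mfe(encode_sequence(sequence), model_for_cpp(model),
                 fast_path = model_is_uniform(model), want_structure = TRUE)
  structure(list(energy = res$energy, structure = res$structure,
                 sequence = sequence),
            class = "fold_result")
}

# energy-only batch fold (no traceback); used for shuffled nulls
fold_energies <- function(sequences, model) {
  seqs <- lapply(sequences, encode_sequence)
  cpp_mfe_batch(seqs, model_for_cpp(model),
                fast_path = model_is_uniform(model))
}

#' Boltzmann ensemble of an RNA sequence
#'
#' Computes the partition function `Z = sum over structures S of
#' exp(-E(S)/RT)` (the empty structure contributes 1) with a
#' McCaskill-style inside recursion over the same unambiguous grammar the
#' MFE dynamic program uses, base-pair probabilities by the matching
#' outside recursion, the ensemble free energy `G = -RT log Z`, the
#' ensemble diversity, and the Boltzmann frequency of the MFE structure.
#'
#' @inheritParams fold_mfe
#' @param mfe optionally, a precomputed [fold_mfe()] result for the same
#'   sequence and model (saves recomputing it for `mfe_frequency`).
#' @return list of class `ensemble_result` with elements
#'   `partition_function`, `ensemble_free_energy` (kcal/mol),
#'   `pair_probabilities` (upper-triangular matrix), `ensemble_diversity`
#'   (expected base-pair distance, in pairs), and `mfe_frequency`.
#' @export
#' @examples
#' fold_ensemble("GAAAC", energy_model("bp_min"))
fold_ensemble <- function(sequence, model = energy_model("bp_min"),
                          mfe = NULL) {
  sequence <- check_fold_sequence(sequence)
  pf <- cpp_partition(encode_sequence(sequence), model_for_cpp(model),
                      fast_path = model_is_uniform(model))
  if (is.null(mfe)) mfe <- fold_mfe(sequence, model)
  res <- structure(list(
    partition_function = pf$Z,
    ensemble_free_energy = pf$G,
    pair_probabilities = pf$pair_prob,
    ensemble_diversity = NA_real_,
    mfe_frequency = NA_real_,
    sequence = sequence
  ), class = "ensemble_result")
  res$ensemble_diversity <- ensemble_diversity(res)
  res$mfe_frequency <- mfe_frequency(mfe, res, model)
  res
}

#' Ensemble diversity
#'
#' The Boltzmann-expected base-pair distance between two independent draws
#' from the equilibrium ensemble, where the distance between two structures
#' is the number of base pairs by which they differ (symmetric difference).
#' From the pair probabilities this is `ED = sum over i<j of
#' 2 p_ij (1 - p_ij)`.
#'
#' @param ensemble an `ensemble_result`, or a pair-probability matrix.
#' @return expected base-pair distance (non-negative, in pairs).
#' @export
ensemble_diversity <- function(ensemble) {
  p <- if (is.matrix(ensemble)) ensemble else ensemble$pair_probabilities
  if (is.null(p)) stop("no pair-probability matrix available", call. = FALSE)
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("malformed pair-probability matrix",
                                          call. = FALSE)
  sum(2 * p * (1 - p))
}

#' Boltzmann frequency of the MFE structure
#'
#' `fMFE = exp(-E_MFE / RT) / Z = exp((G - E_MFE) / RT)`, the equilibrium
#' probability of the single reported MFE structure.  When several
#' structures tie at the minimum energy this is still the probability of
#' one of them, so `fMFE = 1` exactly when the ensemble contains only the
#' MFE structure.
#'
#' @param mfe a [fold_mfe()] result.
#' @param ensemble a [fold_ensemble()] result for the same sequence/model.
#' @param model the [energy_model()] both were computed under.
#' @return probability in (0, 1].
#' @export
mfe_frequency <- function(mfe, ensemble, model) {
  n_mfe <- nchar(mfe$structure)
  n_ens <- nrow(ensemble$pair_probabilities)
  if (!is.null(n_ens) && n_mfe != n_ens)
    stop("MFE and ensemble results are for different sequence lengths",
         call. = FALSE)
  f <- exp((ensemble$ensemble_free_energy - mfe$energy) / model$RT)
  min(f, 1)  # guards rounding at the 1e-16 level for single-structure ensembles
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (",
      formatC(x$energy, format = "f", digits = 2), " kcal/mol)\n", sep = "")
  invisible(x)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble of ", nchar(x$sequence), " nt>\n",
      "  Z = ", format(x$partition_function), ", G = ",
      formatC(x$ensemble_free_energy, format = "f", digits = 2),
      " kcal/mol\n",
      "  ED = ", formatC(x$ensemble_diversity, format = "f", digits = 2),
      " pairs, fMFE = ",
      formatC(x$mfe_frequency, format = "f", digits = 4), "\n", sep = "")
  invisible(x)
}
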