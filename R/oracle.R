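# Exhaustive enumeration oracle and the reference structure scorer.  Both
# are written independently of the compiled dynamic programs (plain R over
# the loop decomposition) so the two routes check each other in the tests.

#' Parse a dot-bracket string
#'
#' @param structure dot-bracket string over `.`, `(`, `)`.
#' @return two-column integer matrix of (i, j) pairs, 1-based, i < j.
#' @export
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(".", "(", ")")))
    stop("invalid dot-bracket characters", call. = FALSE)
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  out <- vector("list", length(chars))
  np <- 0
  for (k in seq_along(chars)) {
    if (chars[k] == "(") open <- c(open, k)
    else if (chars[k] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket", call. = FALSE)
      np <- np + 1
      out[[np]] <- c(open[length(open)], k)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0) stop("unbalanced dot-bracket", call. = FALSE)
  if (np == 0) return(matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, out[seq_len(np)])
  colnames(m) <- c("i", "j")
  m[order(m[, 1]), , drop = FALSE]
}

#' Score a secondary structure under an energy model
#'
#' Reference implementation of the energy function: decomposes the
#' structure into its loops and sums per-pair energies, hairpin / bulge /
#' internal penalties, stacking energies, and the affine multiloop term.
#' The external loop is free.  Used to score enumerated structures; the
#' compiled MFE and partition-function recursions must agree with it.
#'
#' @inheritParams fold_mfe
#' @param structure dot-bracket string, same length as `sequence`.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure,
                             model = energy_model("bp_min")) {
  sequence <- check_fold_sequence(sequence)
  n <- nchar(sequence)
  if (nchar(structure) != n)
    stop("structure and sequence lengths differ", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pairs <- parse_dotbracket(structure)
  if (nrow(pairs) == 0) return(0)

  pe <- model$pair_energy
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (j - i - 1 < model$min_hairpin)
      stop("hairpin loop below minimum size at pair (", i, ",", j, ")",
           call. = FALSE)
    if (is.na(pe[chars[i], chars[j]]))
      stop("disallowed pair ", chars[i], "-", chars[j], " at (", i, ",", j,
           ")", call. = FALSE)
  }

  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]

  loop_pen <- function(tab, size) {
    if (size <= length(tab)) tab[size]
    else tab[length(tab)] + model$lxc * log(size / length(tab))
  }
  pair_code <- function(i, j) paste0(chars[i], chars[j])

  total <- sum(pe[cbind(chars[pairs[, 1]], chars[pairs[, 2]])])
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # walk the loop closed by (i, j): collect direct children and unpaired nt
    children <- matrix(integer(0), ncol = 2)
    unpaired <- 0
    k <- i + 1
    while (k < j) {
      if (partner[k] > k) {
        children <- rbind(children, c(k, partner[k]))
        k <- partner[k] + 1
      } else {
        unpaired <- unpaired + 1
        k <- k + 1
      }
    }
    nb <- nrow(children)
    if (nb == 0) {
      total <- total + loop_pen(model$hairpin, j - i - 1)
    } else if (nb == 1) {
      k <- children[1, 1]; l <- children[1, 2]
      n1 <- k - i - 1; n2 <- j - l - 1
      if (n1 == 0 && n2 == 0)
        total <- total + model$stack[pair_code(i, j), pair_code(k, l)]
      else if (n1 == 0 || n2 == 0)
        total <- total + loop_pen(model$bulge, n1 + n2)
      else
        total <- total + loop_pen(model$internal, n1 + n2)
    } else {
      ml <- model$multiloop
      total <- total + ml[1] + ml[2] * (nb + 1) + ml[3] * unpaired
    }
  }
  total
}

#' Enumerate every admissible secondary structure of a short sequence
#'
#' Brute-force oracle: generates all pseudoknot-free structures respecting
#' the model's pairing rules and minimum hairpin loop, scores each with
#' [structure_energy()], and returns them as a tibble.  The empty structure
#' (energy 0) is always included.  Guarded by a length cap because the
#' structure count grows exponentially.
#'
#' @inheritParams fold_mfe
#' @param max_length refuse sequences longer than this (default 25).
#' @return tibble with columns `structure` and `energy`, one row per
#'   admissible structure, no duplicates.
#' @export
#' @examples
#' enumerate_structures("GGAAACC", energy_model("bp_min"))
enumerate_structures <- function(sequence, model = energy_model("bp_min"),
                                 max_length = 25) {
  sequence <- check_fold_sequence(sequence)
  n <- nchar(sequence)
  if (n > max_length)
    stop("sequence length ", n, " exceeds enumeration cap ", max_length,
         call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pe <- model$pair_energy
  minh <- model$min_hairpin
  can <- function(a, b) !is.na(pe[chars[a], chars[b]])

  # all structures of region i..j as lists of pair matrices; condition on
  # whether j is unpaired or paired with some k, so each structure appears
  # exactly once
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i < minh + 1) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- gen(i, j - 1)                      # j unpaired
    for (k in i:(j - minh - 1)) {
      if (!can(k, j)) next
      left <- if (k > i) gen(i, k - 1) else
        list(matrix(integer(0), ncol = 2))
      inner <- gen(k + 1, j - 1)
      for (L in left) for (Im in inner)
        out <- c(out, list(rbind(L, Im, c(k, j))))
    }
    memo[[key]] <- out
    out
  }
  structs <- gen(1, n)
  db <- vapply(structs, function(p) {
    s <- rep(".", n)
    if (nrow(p) > 0) { s[p[, 1]] <- "("; s[p[, 2]] <- ")" }
    paste(s, collapse = "")
  }, character(1))
  stopifnot(!anyDuplicated(db))
  tibble::tibble(
    structure = db,
    energy = vapply(db, structure_energy, numeric(1),
                    sequence = sequence, model = model, USE.NAMES = FALSE))
}

# partition function, ensemble diversity and fMFE straight from an
# enumeration; the independent cross-check for the compiled McCaskill pass
ensemble_from_enumeration <- function(sequence, model,
                                      max_length = 25) {
  ss <- enumerate_structures(sequence, model, max_length)
  w <- exp(-ss$energy / model$RT)
  Z <- sum(w)
  prob <- w / Z
  n <- nchar(sequence)
  p <- matrix(0, n, n)
  for (r in seq_len(nrow(ss))) {
    prs <- parse_dotbracket(ss$structure[r])
    if (nrow(prs) > 0) p[prs] <- p[prs] + prob[r]
  }
  e_min <- min(ss$energy)
  list(Z = Z, G = -model$RT * log(Z), pair_prob = p,
       ed = sum(2 * p * (1 - p)),
       fmfe = exp(-e_min / model$RT) / Z,
       mfe_energy = e_min)
}
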