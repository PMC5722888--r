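# folding engine: MFE dynamic program, partition function, ensemble
# metrics, enumeration oracle

test_that("MFE folding handles the canonical small cases", {
  r <- fold_mfe("AAAAA", bp_min)
  expect_equal(r$energy, 0)
  expect_equal(r$structure, ".....")

  r <- fold_mfe("GAAAC", bp_min)
  expect_equal(r$energy, -1)
  expect_equal(r$structure, "(...)")

  r <- fold_mfe("GGGAAACCC", bp_min)
  # exhaustive enumeration confirms -3 is the admissible minimum
  ss <- enumerate_structures("GGGAAACCC", bp_min)
  expect_equal(r$energy, min(ss$energy))
  expect_equal(r$energy, -3)
  expect_equal(r$structure, "(((...)))")
})

test_that("invalid folding input is rejected", {
  expect_error(fold_mfe("", bp_min), "empty")
  expect_error(fold_mfe("ACGX", bp_min), "invalid characters")
  expect_error(fold_mfe(c("AC", "GU"), bp_min), "single")
})

test_that("enumeration oracle produces the expected structure sets", {
  expect_equal(nrow(enumerate_structures("AAAA", bp_min)), 1)
  expect_equal(nrow(enumerate_structures("GAAAC", bp_min)), 2)
  # empty, 4 single pairs with loop >= 3, 1 nested two-pair
  ss <- enumerate_structures("GGAAACC", bp_min)
  expect_equal(nrow(ss), 6)
  expect_true("......." %in% ss$structure)
  expect_equal(ss$energy[ss$structure == "......."], 0)
  expect_equal(min(ss$energy), -2)
  expect_error(enumerate_structures(strrep("A", 30), bp_min), "cap")
})

test_that("partition function matches closed forms", {
  e <- fold_ensemble("AAAA", bp_min)
  expect_equal(e$partition_function, 1)
  expect_equal(e$ensemble_free_energy, 0)
  expect_equal(e$mfe_frequency, 1)
  expect_equal(e$ensemble_diversity, 0)

  # two-state system: empty structure and the single pair
  RT <- bp_min$RT
  e <- fold_ensemble("GAAAC", bp_min)
  expect_equal(e$partition_function, 1 + exp(1 / RT), tolerance = 1e-12)
  q <- exp(1 / RT) / (1 + exp(1 / RT))
  expect_equal(e$mfe_frequency, q, tolerance = 1e-12)
  expect_equal(e$ensemble_diversity, 2 * q * (1 - q), tolerance = 1e-12)
})

test_that("ensemble diversity follows its closed forms", {
  expect_equal(ensemble_diversity(matrix(0, 4, 4)), 0)
  # two structures differing by d pairs with probabilities q, 1-q
  d <- 5; q <- 0.3
  p <- matrix(0, 12, 12)
  p[cbind(1:d, 8:12)] <- q
  expect_equal(ensemble_diversity(p), 2 * q * (1 - q) * d)
  expect_error(ensemble_diversity(matrix(2, 2, 2)), "malformed")
})

test_that("mfe_frequency rejects mismatched inputs", {
  m <- fold_mfe("GAAAC", bp_min)
  e <- fold_ensemble("GGGAAACCC", bp_min)
  expect_error(mfe_frequency(m, e, bp_min), "different sequence lengths")
})

test_that("DP agrees with enumeration for both models on random sequences", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(8:16, 1)
    s <- random_rna(n, alphabet = c("A", "C", "G", "U", "N"))
    for (model in list(bp_min, nn_lite)) {
      en <- foldscan:::ensemble_from_enumeration(s, model)
      f <- fold_mfe(s, model)
      e <- fold_ensemble(s, model, mfe = f)
      expect_equal(f$energy, en$mfe_energy, tolerance = 1e-9)
      expect_equal(e$partition_function, en$Z, tolerance = 1e-9)
      expect_equal(e$ensemble_diversity, en$ed, tolerance = 1e-6)
      expect_equal(e$mfe_frequency, en$fmfe, tolerance = 1e-6)
    }
  }
})

test_that("ensemble invariants hold on random sequences", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(8:40, 1)
    s <- random_rna(n)
    for (model in list(bp_min, nn_lite)) {
      f <- fold_mfe(s, model)
      e <- fold_ensemble(s, model, mfe = f)
      expect_true(e$partition_function >= 1)
      expect_lte(e$ensemble_free_energy, 0)
      expect_lte(e$ensemble_free_energy, f$energy + 1e-9)
      expect_gt(e$mfe_frequency, 0)
      expect_lte(e$mfe_frequency, 1)
      expect_gte(e$ensemble_diversity, -1e-12)
      p <- e$pair_probabilities
      expect_true(all(p >= -1e-9 & p <= 1 + 1e-9))
      # row+column marginal: each base pairs with at most one partner
      marg <- rowSums(p) + colSums(p)
      expect_true(all(marg <= 1 + 1e-9))
      expect_valid_structure(s, f$structure, model)
      # fMFE = 1 exactly when the ensemble is the single MFE structure
      if (abs(e$mfe_frequency - 1) < 1e-12)
        expect_equal(e$partition_function * exp(f$energy / model$RT), 1,
                     tolerance = 1e-9)
      # ED = 0 iff every pair probability is 0 or 1
      if (e$ensemble_diversity < 1e-12)
        expect_true(all(p < 1e-9 | abs(p - 1) < 1e-9))
    }
  }
})

test_that("the traceback is deterministic", {
  set.seed(77)
  for (rep in 1:10) {
    s <- random_rna(60)
    for (model in list(bp_min, nn_lite))
      expect_identical(fold_mfe(s, model)$structure,
                       fold_mfe(s, model)$structure)
  }
})

test_that("the max-pairing fast path equals the general DP under bp_min", {
  set.seed(55)
  for (rep in 1:25) {
    s <- random_rna(sample(8:25, 1))
    enc <- foldscan:::encode_sequence(s)
    mod <- foldscan:::model_for_cpp(bp_min)
    fast <- foldscan:::cpp_mfe(enc, mod, TRUE, FALSE)
    gen <- foldscan:::cpp_mfe(enc, mod, FALSE, FALSE)
    expect_equal(fast$energy, gen$energy, tolerance = 1e-9)
  }
})

test_that("N never pairs and scores nothing", {
  r <- fold_mfe("NNGAAAN", bp_min)  # the only G has no partner
  expect_equal(r$energy, 0)
  s <- "GGGNNNAAACCC"
  pairs <- expect_valid_structure(s, fold_mfe(s, bp_min)$structure, bp_min)
  expect_gt(nrow(pairs), 0)
})

test_that("structure_energy validates its input", {
  expect_error(structure_energy("GAAAC", "(....)", bp_min), "lengths differ")
  expect_error(structure_energy("GAAAC", "((..)", bp_min), "unbalanced")
  expect_error(structure_energy("AAAAC", "(...)", bp_min), "disallowed pair")
  expect_error(structure_energy("GAAC", "(..)", bp_min), "below minimum")
})
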