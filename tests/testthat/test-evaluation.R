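random_map <- function(n, density, window = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, n, n)
    sel <- eligible_mask(n, window, upper_only = TRUE)
    idx <- which(sel)
    on <- idx[runif(length(idx)) < density]
    m[on] <- 1L
    m <- m + t(m)
    contact_map(m, window = window)
  })
}

test_that("perfect and hand-computed predictions score as expected", {
  truth <- random_map(20, 0.2, seed = 3)
  same <- score_molecule(truth, truth)
  expect_equal(same$f1_macro, 1)
  expect_equal(same$mcc, 1)

  # truth (1,1,0,0) vs pred (1,0,1,0): TP=FN=FP=TN=1 -> mcc 0, macro-F1 0.5
  m <- binary_pair_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(m$mcc, 0)
  expect_equal(m$f1_macro, 0.5)

  # degenerate all-zero truth and prediction
  z <- contact_map(matrix(0L, 10, 10), window = 2)
  sc <- score_molecule(z, z)
  expect_equal(sc$mcc, 0)        # zero-denominator rule
  expect_equal(sc$f1_macro, 0.5) # contact-class F1 is 0 by the empty-class rule
  expect_true(sc$degenerate)
})

test_that("metrics agree with the textbook confusion-table oracle", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      n <- sample(10:64, 1)
      truth <- runif(n * 4) < runif(1, 0.05, 0.5)
      pred <- runif(n * 4) < runif(1, 0.05, 0.5)
    })
    got <- binary_pair_metrics(as.integer(truth), as.integer(pred))
    want <- oracle_metrics(truth, pred)
    expect_equal(got$f1_macro, want$f1_macro, tolerance = 1e-12)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
  }
  # and on whole maps, restricted to eligible pairs
  for (seed in 1:10) {
    truth <- random_map(30, 0.15, seed = seed)
    pred <- random_map(30, 0.15, seed = seed + 100)
    sel <- eligible_mask(30, 2, upper_only = TRUE)
    want <- oracle_metrics(truth$matrix[sel] == 1, pred$matrix[sel] == 1)
    got <- score_molecule(pred, truth)
    expect_equal(got$f1_macro, want$f1_macro)
    expect_equal(got$mcc, want$mcc)
    expect_equal(got$n_eligible_pairs, sum(sel))
  }
})

test_that("MCC flips sign under prediction inversion on balanced truths", {
  withr::with_seed(9, {
    truth <- rep(c(0L, 1L), 50)
    pred <- as.integer(runif(100) < 0.5)
  })
  m1 <- binary_pair_metrics(truth, pred)
  m2 <- binary_pair_metrics(truth, 1L - pred)
  expect_equal(m1$mcc, -m2$mcc, tolerance = 1e-12)
  # macro-F1 invariant under simultaneous relabeling of both vectors
  m3 <- binary_pair_metrics(1L - truth, 1L - pred)
  expect_equal(m1$f1_macro, m3$f1_macro, tolerance = 1e-12)
})

test_that("random predictions at the truth density have mean MCC near zero", {
  mccs <- vapply(1:200, function(seed) {
    truth <- random_map(24, 0.15, seed = seed)
    d <- mean(truth$matrix[eligible_mask(24, 2, upper_only = TRUE)])
    pred <- random_map(24, d, seed = seed + 5000)
    score_molecule(pred, truth)$mcc
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("dataset-level means are unweighted and order-invariant", {
  t1 <- random_map(16, 0.2, seed = 1); t2 <- random_map(22, 0.2, seed = 2)
  truths <- list(a = t1, b = t2)
  preds <- list(a = t1, b = random_map(22, 0.2, seed = 99))  # perfect + random
  rep1 <- score_dataset(preds, truths)
  expect_equal(rep1$mean_f1_macro, mean(rep1$scores$f1_macro))
  expect_equal(nrow(tidy(rep1)), 2)
  expect_equal(glance(rep1)$n_scored, 2)
  rep2 <- score_dataset(rev(preds), rev(truths))
  expect_equal(rep1$mean_f1_macro, rep2$mean_f1_macro)
  expect_equal(rep1$mean_mcc, rep2$mean_mcc)

  # single molecule: mean equals its score
  rep3 <- score_dataset(preds["a"], truths["a"])
  expect_equal(rep3$mean_f1_macro, rep3$scores$f1_macro[1])

  expect_error(score_dataset(preds["a"], truths), class = "attn_alignment_error")

  # molecules with no eligible pairs are skipped and listed
  tiny <- contact_map(matrix(0L, 3, 3), window = 4)
  rep4 <- score_dataset(c(preds, list(z = tiny)), c(truths, list(z = tiny)))
  expect_equal(rep4$skipped$molecule_id, "z")
  expect_equal(nrow(rep4$scores), 2)
})

test_that("external predictions are converted, scored, and skipped gracefully", {
  db <- "(((....)))...(((....)))"
  n <- nchar(db)
  truth <- apply_exclusion_band(pairs_to_contact_map(dotbracket_to_pairs(db), n), 4)
  truths <- list(m1 = truth)

  # identical dot-bracket prediction scores perfectly
  rep1 <- benchmark_external(list(m1 = db), truths, window = 4)
  expect_equal(rep1$mean_f1_macro, 1)
  expect_equal(rep1$params$window, 4)   # conversion parameters recorded

  # an all-dot prediction misses every contact
  rep2 <- benchmark_external(list(m1 = strrep(".", n)), truths, window = 4)
  expect_lt(rep2$mean_f1_macro, 1)
  expect_equal(rep2$scores$mcc[1], 0)

  # unparsable predictions are skipped per molecule, not fatal
  rep3 <- benchmark_external(list(m1 = db, m2 = "((("),
                             c(truths, list(m2 = truth)), window = 4)
  expect_equal(nrow(rep3$scores), 1)
  expect_true("m2" %in% rep3$skipped$molecule_id)

  # a 3D prediction file identical to the truth structure also scores 1
  st <- gen_coords(tibble::tibble(i = c(1L, 3L), j = c(12L, 18L)), 20, window = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  truth3d <- apply_exclusion_band(coords_to_contact_map(st, 9.5), 4)
  rep4 <- benchmark_external(list(x = path), list(x = truth3d), cutoff = 9.5, window = 4)
  expect_equal(rep4$mean_f1_macro, 1)
})
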