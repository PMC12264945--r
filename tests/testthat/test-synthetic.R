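test_that("generated secondary structures are valid, nested, and deterministic", {
  for (seed in 1:10) {
    db <- gen_secondary(50, pseudoknot_prob = 0, seed = seed)
    expect_equal(nchar(db), 50)
    pairs <- dotbracket_to_pairs(db)          # parses without error
    expect_gt(nrow(pairs), 0)
    expect_identical(pairs_to_dotbracket(pairs, 50), db)  # nested round-trip
    # stems 3-6 bp and loops >= 3: hairpin loops never shorter than 3
    runs <- regmatches(db, gregexpr("\\(\\.+\\)", db))[[1]]
    if (length(runs) > 0) expect_true(all(nchar(runs) - 2 >= 3))
  }
  expect_identical(gen_secondary(40, seed = 5), gen_secondary(40, seed = 5))
})

test_that("pseudoknots appear on the bracket tier and cross the nested stem", {
  hit <- FALSE
  for (seed in 1:30) {
    db <- gen_secondary(60, pseudoknot_prob = 1, seed = seed)
    if (grepl("\\[", db)) {
      hit <- TRUE
      pairs <- dotbracket_to_pairs(db)
      # at least one crossing pair exists
      crossing <- FALSE
      for (a in seq_len(nrow(pairs) - 1)) for (b in (a + 1):nrow(pairs)) {
        if (pairs$i[a] < pairs$i[b] & pairs$i[b] < pairs$j[a] & pairs$j[a] < pairs$j[b])
          crossing <- TRUE
      }
      expect_true(crossing)
    }
  }
  expect_true(hit)
})

test_that("tertiary extras add the requested number of long-range contacts", {
  db <- gen_secondary(60, seed = 2)
  base <- gen_tertiary_map(db, n_extras = 0, seed = 1)
  expect_equal(base$matrix, pairs_to_contact_map(dotbracket_to_pairs(db), 60)$matrix)
  extra <- gen_tertiary_map(db, n_extras = 4, window = 4, seed = 1)
  expect_equal(n_contacts(extra), n_contacts(base) + 4L)
  # extras are long-range and each residue is used at most twice
  added <- extra$matrix - base$matrix
  idx <- which(added == 1 & upper.tri(added), arr.ind = TRUE)
  expect_true(all(idx[, 2] - idx[, 1] > 4))
  expect_identical(gen_tertiary_map(db, 4, seed = 9)$matrix,
                   gen_tertiary_map(db, 4, seed = 9)$matrix)
})

test_that("toy coordinates realize exactly the requested matching", {
  matching <- tibble::tibble(i = c(2L, 4L), j = c(10L, 12L))
  st <- gen_coords(matching, 12, window = 4)
  cm <- apply_exclusion_band(coords_to_contact_map(st, 9.5), 4)
  want <- apply_exclusion_band(pairs_to_contact_map(matching, 12), 4)
  expect_equal(cm$matrix, want$matrix)
  expect_equal(cm$matrix, {
    m <- oracle_contact_matrix(st, 9.5); m[!eligible_mask(12, 4)] <- 0L; m
  })
  # empty matching: no off-band contacts at all
  st0 <- gen_coords(tibble::tibble(i = integer(0), j = integer(0)), 8)
  expect_equal(n_contacts(apply_exclusion_band(coords_to_contact_map(st0, 9.5), 4)), 0L)
  # infeasible matchings are rejected
  expect_error(gen_coords(tibble::tibble(i = 1L, j = 3L), 8, window = 4),
               class = "attn_generation_error")

  # round-trip through the PDB writer/reader preserves the contact map
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  back <- read_structure(path, kind = "rna")
  expect_equal(coords_to_contact_map(back, 9.5)$matrix,
               coords_to_contact_map(st, 9.5)$matrix)
})

test_that("planted attention rows are normalized and carry the signal", {
  spec <- synthetic_spec(n_layers = 2, n_heads = 2,
                         aware_heads = tibble::tibble(layer = 1, head = 1),
                         alpha = 1, window = 4, seed = 3)
  db <- gen_secondary(40, seed = 3)
  map <- apply_exclusion_band(gen_tertiary_map(db, 2, seed = 3), 4)
  st <- gen_attention_stack(map, spec, "m", seed = 3)
  rs <- apply(st$weights, c(1, 2, 3), sum)
  expect_true(all(abs(rs - 1) < 1e-9))
  expect_true(all(st$weights >= 0))

  # alpha = 1: off-band attention of the aware head sits only on contacts,
  # so the band-excluded agreement score is exactly 1
  g <- agreement_scores(list(st), list(map), theta = NULL)
  expect_equal(g$score[g$layer == 1 & g$head == 1], 1, tolerance = 1e-12)
  expect_lt(g$score[g$layer == 2 & g$head == 2], 0.5)
})

test_that("at zero signal fraction aware and unaware heads are indistinguishable", {
  corpus <- tiny_corpus(n_molecules = 60, alpha = 0, seed = 17,
                        length_range = c(30, 40))
  g <- agreement_scores(corpus$stacks, corpus$maps, theta = NULL)
  aware <- corpus$spec$aware_heads
  s_aware <- g$score[g$layer == aware$layer[1] & g$head == aware$head[1]]
  s_other <- mean(g$score[!(g$layer == aware$layer[1] & g$head == aware$head[1])])
  expect_lt(abs(s_aware - s_other), 0.05)
})

test_that("corpora are aligned, stem-complementary, and byte-reproducible", {
  spec <- synthetic_spec(n_molecules = 40, n_layers = 2, n_heads = 2,
                         aware_heads = tibble::tibble(layer = 2, head = 1),
                         length_range = c(30, 40), seed = 13)
  corpus <- gen_corpus(spec)
  expect_equal(nrow(corpus$molecules), 40)
  expect_length(corpus$maps, 40)
  expect_length(corpus$stacks, 40)
  for (k in c(1, 20, 40)) {
    id <- corpus$molecules$id[k]
    expect_equal(corpus$maps[[id]]$n, corpus$molecules$n[k])
    expect_equal(corpus$stacks[[id]]$n, corpus$molecules$n[k])
    # stems carry Watson-Crick partners
    pairs <- dotbracket_to_pairs(corpus$molecules$db[k])
    chars <- strsplit(corpus$molecules$sequence[k], "")[[1]]
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    expect_true(all(chars[pairs$j] == comp[chars[pairs$i]]))
  }
  # same seed, byte-identical serialization
  corpus2 <- gen_corpus(spec)
  expect_identical(serialize(corpus, NULL), serialize(corpus2, NULL))
})
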