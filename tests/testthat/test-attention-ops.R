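test_that("symmetrization is the arithmetic mean of a matrix and its transpose", {
  expect_equal(symmetrize(matrix(c(0, 3, 1, 0), 2, 2)), matrix(c(0, 2, 2, 0), 2, 2))
  s <- matrix(c(1, 5, 5, 2), 2, 2)
  expect_equal(symmetrize(s), s)                      # idempotent on symmetric input
  a <- withr::with_seed(1, matrix(runif(16), 4, 4))
  expect_equal(symmetrize(symmetrize(a)), symmetrize(a))
  expect_equal(symmetrize(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_error(symmetrize(matrix(1, 2, 3)), class = "attn_shape_error")
})

test_that("APC subtracts the rank-1 background exactly", {
  # hand computation: rowsums (3,7), colsums (4,6), total 10
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(apc(m), matrix(c(-0.2, 0.2, 0.2, -0.2), 2, 2))
  # any outer product is annihilated; constants are a special case
  u <- runif(5) + 0.1; v <- runif(5) + 0.1
  expect_equal(max(abs(apc(outer(u, v)))), 0, tolerance = 1e-12)
  expect_equal(max(abs(apc(matrix(2.5, 4, 4)))), 0, tolerance = 1e-12)
  expect_error(apc(matrix(0, 3, 3)), class = "attn_degenerate_error")
})

test_that("stack processing symmetrizes then APC-corrects each head", {
  w <- array(0, dim = c(1, 1, 2, 2))
  w[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)
  st <- process_stack(attention_stack(w, "x"))
  # symmetrization gives [[1, 2.5], [2.5, 4]] with margins (3.5, 6.5) and
  # total 10; APC then leaves +/-0.225
  expect_equal(st$weights[1, 1, , ], matrix(c(-0.225, 0.225, 0.225, -0.225), 2, 2))
  expect_true(st$processed)
  expect_error(process_stack(st), class = "attn_state_error")

  w0 <- array(0, dim = c(1, 2, 3, 3))
  w0[1, 2, , ] <- 1 / 3
  err <- expect_error(process_stack(attention_stack(w0, "z")),
                      class = "attn_degenerate_error")
  expect_match(conditionMessage(err), "layer 1 head 1")

  # already symmetric maps: symmetrization is a no-op, APC still applied
  ws <- array(0, dim = c(1, 1, 3, 3))
  sym <- symmetrize(matrix(runif(9) + 0.1, 3, 3))
  ws[1, 1, , ] <- sym
  expect_equal(process_stack(attention_stack(ws, "s"))$weights[1, 1, , ], apc(sym))
})

make_uniform_stack <- function(n, id = "u") {
  w <- array(1 / n^2, dim = c(1, 1, n, n))
  attention_stack(w, id)
}

test_that("agreement score equals contact density under uniform attention", {
  # N = 4 with one contact pair: 2 of 16 entries -> 0.125 under the all mask
  cm <- pairs_to_contact_map(tibble::tibble(i = 1L, j = 4L), 4)
  g <- agreement_scores(list(make_uniform_stack(4)), list(cm),
                        theta = NULL, mask_policy = "all")
  expect_equal(g$score, 2 / 16)

  # all mass on contact pairs -> exactly 1
  w <- array(0, dim = c(1, 1, 4, 4))
  w[1, 1, 1, 4] <- 0.5; w[1, 1, 4, 1] <- 0.5
  g1 <- agreement_scores(list(attention_stack(w, "c")), list(cm), theta = NULL,
                         mask_policy = "all")
  expect_equal(g1$score, 1)
})

test_that("the 0.3 threshold keeps only confident weights in the statistic", {
  # 0.4 on a contact pair, 0.5 on a non-contact pair, the rest below theta:
  # p(f) = 0.4 / (0.4 + 0.5)
  n <- 6
  cm <- apply_exclusion_band(pairs_to_contact_map(tibble::tibble(i = 1L, j = 6L), n), 0)
  w <- array(0.01, dim = c(1, 1, n, n))
  w[1, 1, 1, 6] <- 0.4
  w[1, 1, 2, 5] <- 0.5
  g <- agreement_scores(list(attention_stack(w, "t")), list(cm), theta = 0.3,
                        mask_policy = "all")
  expect_equal(g$score, 0.4 / 0.9)
  # and matches the direct-summation oracle
  expect_equal(g$score,
               oracle_agreement(list(attention_stack(w, "t")), list(cm), 1, 1, theta = 0.3))
})

test_that("theta = 0 and the threshold-free variant coincide on positive attention", {
  corpus <- tiny_corpus(n_molecules = 4, alpha = 0.6, seed = 11)
  g0 <- agreement_scores(corpus$stacks, corpus$maps, theta = 0)
  gn <- agreement_scores(corpus$stacks, corpus$maps, theta = NULL)
  expect_equal(g0$score, gn$score, tolerance = 1e-12)
})

test_that("scores are permutation-invariant, bounded, and flagged when empty", {
  corpus <- tiny_corpus(n_molecules = 5, alpha = 0.5, seed = 7)
  g <- agreement_scores(corpus$stacks, corpus$maps, theta = NULL)
  perm <- c(3, 1, 5, 2, 4)
  gp <- agreement_scores(corpus$stacks[perm], corpus$maps[perm], theta = NULL)
  expect_equal(g$score, gp$score)
  expect_true(all(g$score >= 0 & g$score <= 1))

  # a theta above every weight empties all denominators: score 0, flagged
  n <- corpus$maps[[1]]$n
  w <- array(1 / n^2, dim = c(1, 1, n, n))
  expect_warning(
    gz <- agreement_scores(list(attention_stack(w, names(corpus$maps)[1])),
                           corpus$maps[1], theta = 0.99),
    "score is defined as 0")
  expect_equal(gz$score, 0)
  expect_true(all(gz$flagged))
})

test_that("agreement matches the direct-summation oracle on synthetic corpora", {
  corpus <- tiny_corpus(n_molecules = 3, alpha = 0.7, seed = 5)
  g <- agreement_scores(corpus$stacks, corpus$maps, theta = NULL)
  w <- corpus$spec$window
  for (l in 1:2) for (h in 1:3) {
    expect_equal(g$score[g$layer == l & g$head == h],
                 oracle_agreement(corpus$stacks, corpus$maps, l, h,
                                  theta = NULL, window = w),
                 tolerance = 1e-12)
  }
})

test_that("head ranking is descending with deterministic tie-breaks", {
  grid <- tidyr::expand_grid(layer = 1:2, head = 1:2) |>
    dplyr::mutate(score = c(0.2, 0.9, 0.2, 0.2), flagged = FALSE)
  class(grid) <- c("head_score_grid", class(grid))
  top <- rank_heads(grid, 3)
  expect_equal(top$score[1], 0.9)
  expect_equal(top[2:3, c("layer", "head")],
               tibble::tibble(layer = c(1L, 2L), head = c(1L, 1L)),
               ignore_attr = TRUE)

  allsame <- grid |> dplyr::mutate(score = 0.5)
  class(allsame) <- class(grid)
  expect_equal(rank_heads(allsame, 3)[, c("layer", "head")],
               tibble::tibble(layer = c(1L, 1L, 2L), head = c(1L, 2L, 1L)),
               ignore_attr = TRUE)
})

test_that("stack invariants are enforced", {
  w <- array(0.5, dim = c(1, 1, 2, 2))
  expect_silent(attention_stack(w, "ok", check_rows = TRUE))
  w[1, 1, 1, 1] <- -0.1
  expect_error(attention_stack(w, "neg"), class = "attn_value_error")
  wb <- array(0.3, dim = c(1, 1, 2, 2))
  expect_error(attention_stack(wb, "rows", check_rows = TRUE),
               class = "attn_value_error")
  expect_error(attention_stack(array(1, dim = c(1, 1, 2, 3)), "shape"),
               class = "attn_shape_error")
})
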