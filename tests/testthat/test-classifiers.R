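# balanced table with a near-separable aware feature: label + tiny noise
separable_dataset <- function(n = 200, noise = 0.01, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), each = n / 2)
    tab <- tibble::tibble(
      molecule_id = "m1", i = seq_len(n), j = seq_len(n) + 10L, label = label,
      layer1_head1 = label + rnorm(n, sd = noise),
      layer1_head2 = rnorm(n)
    )
    structure(tab, class = c("pair_dataset", class(tab)), balanced = TRUE,
              window = 4L, feature_names = c("layer1_head1", "layer1_head2"),
              seed = seed)
  })
}

test_that("a logistic probe separates a signal feature almost perfectly", {
  ds <- separable_dataset()
  model <- train_tabular(ds, predictor_spec("logistic", seed = 1))
  X <- as.matrix(as_tibble(ds)[, attr(ds, "feature_names")])
  acc <- mean((predict_pair_prob(model, X) >= 0.5) == (ds$label == 1))
  expect_gt(acc, 0.99)
  # coefficient mass concentrates on the aware feature
  est <- tidy(model)
  expect_equal(est$term[which.max(abs(est$estimate))], "layer1_head1")
})

test_that("pure-noise features score at chance on balanced held-out pairs", {
  withr::with_seed(42, {
    n <- 1200
    label <- rep(c(0L, 1L), n / 2)
    X <- matrix(rnorm(n * 4), n, 4)
    colnames(X) <- sprintf("layer1_head%d", 1:4)
    tab <- dplyr::bind_cols(tibble::tibble(molecule_id = "m", i = 1:n,
                                           j = 1:n + 20L, label = label),
                            tibble::as_tibble(X))
    ds <- structure(tab, class = c("pair_dataset", class(tab)), balanced = TRUE,
                    window = 4L, feature_names = colnames(X), seed = 1)
    model <- train_tabular(ds[1:600, ] |>
                             (\(d) { attr(d, "feature_names") <- colnames(X)
                                     attr(d, "balanced") <- TRUE; d })(),
                           predictor_spec("logistic", seed = 1))
    held <- 601:1200
    sc <- score_pairs(label[held], predict_pair_prob(model, X[held, ]))
    expect_gt(sc$f1_macro, 0.45)
    expect_lt(sc$f1_macro, 0.55)
  })
})

test_that("all five tabular kinds fit, predict probabilities, and are deterministic", {
  ds <- separable_dataset(n = 120, noise = 0.2, seed = 3)
  X <- as.matrix(as_tibble(ds)[, attr(ds, "feature_names")])
  for (kind in c("logistic", "decision_tree", "random_forest", "mlp",
                 "gradient_boosting")) {
    hy <- if (kind == "gradient_boosting") list(nrounds = 20L) else list()
    spec <- do.call(predictor_spec, c(list(kind = kind, seed = 7), hy))
    m1 <- train_tabular(ds, spec)
    p1 <- predict_pair_prob(m1, X)
    expect_true(all(p1 >= 0 & p1 <= 1), info = kind)
    m2 <- train_tabular(ds, spec)
    expect_equal(p1, predict_pair_prob(m2, X), info = kind)
    expect_gt(mean((p1 >= 0.5) == (ds$label == 1)), 0.8)
  }
  expect_error(train_tabular(ds, predictor_spec("cnn")), class = "attn_config_error")
  expect_error(train_tabular(ds[0, ], predictor_spec("logistic")),
               class = "attn_training_error")
})

test_that("predicted maps are symmetric, in [0,1], and zero on the band", {
  corpus <- tiny_corpus(n_molecules = 8, alpha = 1, seed = 21)
  processed <- lapply(corpus$stacks, process_stack)
  ds <- balance_dataset(build_pair_dataset(processed, corpus$maps), seed = 5)
  w <- corpus$spec$window
  for (kind in c("logistic", "random_forest")) {
    model <- train_tabular(ds, predictor_spec(kind, seed = 2))
    pm <- predict_contact_map(model, processed[[1]], window = w)
    expect_true(all(pm$prob >= 0 & pm$prob <= 1))
    expect_equal(pm$prob, t(pm$prob))
    expect_true(all(pm$prob[!eligible_mask(pm$n, w)] == 0))
    expect_true(all(pm$binary$matrix[!eligible_mask(pm$n, w)] == 0L))
    expect_equal(pm$binary$matrix, (pm$prob >= 0.5) * 1L)
  }
})

test_that("a probe trained on fully aware attention recovers the planted map", {
  corpus <- tiny_corpus(n_molecules = 21, alpha = 1, seed = 8)
  processed <- lapply(corpus$stacks, process_stack)
  ids <- corpus$molecules$id
  train_ids <- ids[1:20]; held <- ids[21]
  ds <- balance_dataset(build_pair_dataset(processed[train_ids], corpus$maps[train_ids]),
                        seed = 1)
  model <- train_tabular(ds, predictor_spec("logistic", seed = 1))
  pm <- predict_contact_map(model, processed[[held]], window = corpus$spec$window)
  expect_equal(pm$binary$matrix, corpus$maps[[held]]$matrix)
})

test_that("held-out macro-F1 is non-decreasing in the planted signal fraction", {
  f1 <- vapply(c(0, 0.5, 1), function(a)
    fewshot_experiment(a, n_train = 8, n_test = 4, seed = 31,
                       spec_args = list(n_layers = 2, n_heads = 3,
                                        aware_heads = tibble::tibble(layer = 2, head = 2),
                                        length_range = c(30, 45)))$f1_macro,
    numeric(1))
  expect_true(all(diff(f1) >= -0.01))
  expect_gt(f1[3], 0.9)
})

test_that("model archives round-trip and reject corruption", {
  ds <- separable_dataset(n = 80, seed = 5)
  model <- train_tabular(ds, predictor_spec("logistic", seed = 1))
  X <- as.matrix(as_tibble(ds)[, attr(ds, "feature_names")])
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict_pair_prob(back, X), predict_pair_prob(model, X))
  expect_equal(back$provenance, model$provenance)  # provenance preserved

  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), class = "attn_load_error")
  saveRDS(list(other = "thing"), bad)
  expect_error(load_model(bad), class = "attn_load_error")
})
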