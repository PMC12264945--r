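feature_names_for <- function(L, H) {
  as.vector(t(outer(seq_len(L), seq_len(H),
                    function(l, h) sprintf("layer%d_head%d", l, h))))
}

#' Token-pair feature table from processed attention
#'
#' Treats each eligible residue pair (i < j, j - i > window) of each molecule
#' as one sample: the feature vector is the processed (symmetrized + APC)
#' attention weight at (i, j) in every (layer, head) map — L*H features in
#' layer-major order — and the label is the contact-map entry at (i, j).
#'
#' @param stacks List of processed [attention_stack()]s.
#' @param maps Named list of [contact_map()]s aligned by molecule id.
#' @param window Exclusion band half-width; defaults to the maps' window.
#' @return A \code{pair_dataset}: tibble with columns \code{molecule_id},
#'   \code{i}, \code{j}, \code{label}, then one column per
#'   \code{layerX_headY} feature; attributes \code{balanced = FALSE},
#'   \code{window}, \code{feature_names}.
#' @export
build_pair_dataset <- function(stacks, maps, window = NULL) {
  stopifnot(length(stacks) == length(maps), length(stacks) >= 1L)
  ids <- vapply(stacks, `[[`, character(1), "molecule_id")
  if (!is.null(names(maps))) maps <- maps[ids]
  L <- stacks[[1]]$L; H <- stacks[[1]]$H
  fnames <- feature_names_for(L, H)
  rows <- vector("list", length(stacks))
  for (k in seq_along(stacks)) {
    st <- stacks[[k]]; mp <- maps[[k]]
    if (!st$processed)
      stop_attn(sprintf("stack '%s' is unprocessed; run process_stack() first",
                        st$molecule_id), "attn_state_error")
    if (st$n != mp$n)
      stop_attn(sprintf("stack '%s': n = %d vs map n = %d", st$molecule_id, st$n, mp$n),
                "attn_alignment_error")
    w <- window %||% mp$window
    pr <- eligible_pairs(st$n, w)
    if (nrow(pr) == 0L) next
    feat <- matrix(0, nrow(pr), L * H)
    col <- 0L
    for (l in seq_len(L)) for (h in seq_len(H)) {
      col <- col + 1L
      feat[, col] <- st$weights[l, h, , ][cbind(pr$i, pr$j)]
    }
    colnames(feat) <- fnames
    rows[[k]] <- dplyr::bind_cols(
      tibble(molecule_id = st$molecule_id, i = pr$i, j = pr$j,
             label = mp$matrix[cbind(pr$i, pr$j)]),
      as_tibble(feat)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    warn("no eligible pairs: dataset is empty")
    out <- tibble(molecule_id = character(0), i = integer(0), j = integer(0),
                  label = integer(0))
    for (fn in fnames) out[[fn]] <- numeric(0)
  }
  structure(out, class = c("pair_dataset", class(out)),
            balanced = FALSE, window = window %||% maps[[1]]$window,
            feature_names = fnames, seed = NULL)
}

#' Balance a pair dataset by undersampling the majority class
#'
#' Contact maps are heavily imbalanced (few contacts among many pairs);
#' training uses an equal number of samples per class, obtained by randomly
#' subsampling the majority class without replacement down to the minority
#' count. Minority samples are never discarded.
#'
#' @param ds A \code{pair_dataset}.
#' @param seed Integer seed; the subsample is deterministic given the seed.
#' @return A balanced \code{pair_dataset} (attribute \code{balanced = TRUE}).
#' @export
balance_dataset <- function(ds, seed) {
  counts <- table(factor(ds$label, levels = c(0, 1)))
  if (any(counts == 0))
    stop_attn("cannot balance a single-class dataset", "attn_balance_error")
  minority <- as.integer(names(counts)[which.min(counts)])
  majority <- 1L - minority
  keep_min <- which(ds$label == minority)
  idx_maj <- which(ds$label == majority)
  keep_maj <- withr::with_seed(as.integer(seed),
                               sort(sample(idx_maj, length(keep_min))))
  out <- ds[sort(c(keep_min, keep_maj)), ]
  attr(out, "balanced") <- TRUE
  attr(out, "seed") <- as.integer(seed)
  attr(out, "window") <- attr(ds, "window")
  attr(out, "feature_names") <- attr(ds, "feature_names")
  class(out) <- class(ds)
  out
}

#' Molecule-level train/test split
#'
#' Splitting happens at the molecule level (never at the pair level), so no
#' pair of a test molecule can leak into training. The test set size is
#' \code{max(1, floor(test_fraction * n))}: an 85-15 split of 425 molecules
#' gives 362 training and 63 test molecules.
#'
#' @param ids Character vector of molecule ids (>= 2).
#' @param test_fraction Fraction of molecules held out, in (0, 1).
#' @param seed Integer seed.
#' @return A \code{split_plan}: list with \code{train_ids}, \code{test_ids},
#'   \code{batches} (empty; see [make_training_batches()]) and \code{seed}.
#' @export
split_molecules <- function(ids, test_fraction = 0.15, seed = 1L) {
  if (length(ids) < 2L) stop_attn("need at least 2 molecules to split", "attn_split_error")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_attn("test_fraction must be in (0, 1)", "attn_config_error")
  n_test <- max(1L, as.integer(floor(test_fraction * length(ids))))
  test_ids <- withr::with_seed(as.integer(seed), sort(sample(ids, n_test)))
  structure(list(train_ids = setdiff(ids, test_ids), test_ids = test_ids,
                 batches = list(), seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test; %d batch(es)\n",
              length(x$train_ids), length(x$test_ids), length(x$batches)))
  invisible(x)
}

#' Nested training batches of increasing size
#'
#' Divides the training molecules into nested batches spanning from a small
#' pilot set (20 molecules by convention) up to the full training set, to
#' study learning convergence as data grows. Each batch contains the previous
#' one. The default schedule interpolates geometrically between 20 and the
#' full size in 5 steps.
#'
#' @param train_ids Training molecule ids.
#' @param schedule Ascending integer batch sizes; last entry at most
#'   \code{length(train_ids)}.
#' @param seed Integer seed.
#' @return List of character vectors, one per batch, nested.
#' @export
make_training_batches <- function(train_ids, schedule = NULL, seed = 1L) {
  n <- length(train_ids)
  schedule <- schedule %||% default_batch_schedule(n)
  schedule <- as.integer(schedule)
  if (any(diff(schedule) <= 0) && length(schedule) > 1)
    stop_attn("batch schedule must be strictly ascending", "attn_config_error")
  if (schedule[length(schedule)] > n)
    stop_attn("largest batch exceeds the training set", "attn_config_error")
  perm <- withr::with_seed(as.integer(seed), sample(train_ids, n))
  lapply(schedule, function(s) sort(perm[seq_len(s)]))
}

#' Default 5-step geometric batch schedule
#' @param n_train Number of training molecules.
#' @param start Pilot batch size (default 20).
#' @param n_batches Number of batches (default 5).
#' @return Integer vector of batch sizes ending at \code{n_train}.
#' @export
default_batch_schedule <- function(n_train, start = 20L, n_batches = 5L) {
  if (n_train <= start) return(n_train)
  sizes <- round(exp(seq(log(start), log(n_train), length.out = n_batches)))
  unique(pmin(as.integer(sizes), n_train))
}

#' Write / read a pair dataset as TSV
#'
#' Columns: molecule_id, i, j (written 0-based on disk), label, then one
#' column per feature.
#' @param ds A \code{pair_dataset}.
#' @param path Output path.
#' @export
write_pair_dataset <- function(ds, path) {
  out <- as_tibble(ds)
  out$i <- out$i - 1L; out$j <- out$j - 1L
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_pair_dataset
#' @param balanced,window Metadata restored on read.
#' @export
read_pair_dataset <- function(path, balanced = FALSE, window = 0L) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab$i <- as.integer(tab$i) + 1L; tab$j <- as.integer(tab$j) + 1L
  tab$label <- as.integer(tab$label)
  fnames <- setdiff(names(tab), c("molecule_id", "i", "j", "label"))
  structure(tab, class = c("pair_dataset", class(tab)),
            balanced = balanced, window = as.integer(window),
            feature_names = fnames, seed = NULL)
}
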