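# Shared fixtures and independent brute-force oracles. Oracles are written
# as plainly as possible (explicit loops, direct formulas) and never call the
# implementation paths they check.

# plain data.frame of a pair table (drops tibble classes and attributes)
pairs_df <- function(p) data.frame(i = as.integer(p$i), j = as.integer(p$j))

tiny_corpus <- function(n_molecules = 6, alpha = 0.8, seed = 1,
                        n_layers = 2, n_heads = 3,
                        aware_heads = tibble::tibble(layer = 2, head = 2),
                        length_range = c(30, 45), ...) {
  gen_corpus(synthetic_spec(
    n_molecules = n_molecules, alpha = alpha, seed = seed,
    n_layers = n_layers, n_heads = n_heads, aware_heads = aware_heads,
    length_range = length_range, ...
  ))
}

# residues on a line at `spacing` Angstrom; selected pairs moved into contact
line_structure <- function(n, close_pairs = NULL, spacing = 20, offset = 3) {
  pos <- cbind(spacing * (seq_len(n) - 1), 0, 0)
  if (!is.null(close_pairs)) {
    for (r in seq_len(nrow(close_pairs))) {
      pos[close_pairs$j[r], ] <- pos[close_pairs$i[r], ] + c(0, offset, 0)
    }
  }
  residues <- lapply(seq_len(n), function(k)
    list(atoms = "C1'", xyz = matrix(pos[k, ], 1, 3)))
  structure_3d(molecule("line", strsplit(paste(rep("ACGU", ceiling(n / 4)),
                                               collapse = ""), "")[[1]][1:n] |>
                          paste(collapse = ""), "rna"),
               residues)
}

# random structure with 1-3 atoms per residue in a compact box
random_structure <- function(n, seed) {
  withr::with_seed(seed, {
    residues <- lapply(seq_len(n), function(k) {
      na <- sample(1:3, 1)
      center <- runif(3, 0, n^(1 / 3) * 6)
      list(atoms = c("C3'", "P", "N1")[seq_len(na)],
           xyz = matrix(rep(center, each = na), na, 3) +
             matrix(runif(na * 3, -1, 1), na, 3))
    })
    structure_3d(molecule("rnd", paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                       collapse = ""), "rna"),
                 residues)
  })
}

# O(N^2 * A^2) all-atom scan: the distance oracle for coords_to_contact_map
oracle_contact_matrix <- function(structure, cutoff) {
  res <- structure$residues
  n <- length(res)
  m <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (a in seq_len(nrow(res[[i]]$xyz))) {
      for (b in seq_len(nrow(res[[j]]$xyz))) {
        if (sqrt(sum((res[[i]]$xyz[a, ] - res[[j]]$xyz[b, ])^2)) <= cutoff) {
          found <- TRUE; break
        }
      }
      if (found) break
    }
    if (found) m[i, j] <- m[j, i] <- 1L
  }
  m
}

# element-wise definition of the average product correction
oracle_apc <- function(m) {
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- m[i, j] - sum(m[i, ]) * sum(m[, j]) / sum(m)
  }
  out
}

# direct textbook formulas from the 2x2 table
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1_neg <- if (2 * tn + fn + fp == 0) 0 else 2 * tn / (2 * tn + fn + fp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(f1_macro = (f1_pos + f1_neg) / 2, mcc = mcc)
}

# stack-machine oracle for nested dot-bracket (single '()' tier)
oracle_nested_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0); out <- NULL
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    if (chars[k] == ")") {
      out <- rbind(out, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (is.null(out)) tibble::tibble(i = integer(0), j = integer(0))
  else tibble::tibble(i = out[, 1], j = out[, 2]) |> dplyr::arrange(i)
}

# direct summation of the agreement statistic over a molecule set
oracle_agreement <- function(stacks, maps, l, h, theta = NULL, window = NULL) {
  num <- 0; den <- 0
  for (k in seq_along(stacks)) {
    a <- stacks[[k]]$weights[l, h, , ]
    f <- maps[[k]]$matrix
    n <- nrow(f)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!is.null(window) && abs(i - j) <= window) next
      la <- if (is.null(theta)) a[i, j] else if (a[i, j] > theta) a[i, j] else 0
      if (f[i, j] == 1) num <- num + la
      den <- den + la
    }
  }
  if (den == 0) 0 else num / den
}
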