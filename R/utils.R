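#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

stop_attn <- function(msg, class, ...) {
  abort(msg, class = c(class, "attnprobe_error"), ...)
}

#' Logical mask of eligible residue pairs
#'
#' Eligible pairs are those outside the near-diagonal exclusion band
#' \code{|i - j| <= window}. The band removes trivially adjacent residues
#' (the primary structure) so that downstream statistics and classifiers
#' see only the longer-range contacts.
#'
#' @param n Sequence length.
#' @param window Exclusion half-width \code{w}; pairs with \code{|i - j| <= w}
#'   are ineligible. \code{window = 0} excludes only the diagonal.
#' @param upper_only If \code{TRUE}, keep only the upper triangle (i < j).
#' @return An \code{n x n} logical matrix.
#' @export
eligible_mask <- function(n, window, upper_only = FALSE) {
  stopifnot(n >= 1, window >= 0)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- d > window
  if (upper_only) m <- m & upper.tri(m)
  m
}

#' Enumerate eligible upper-triangle pairs
#'
#' @inheritParams eligible_mask
#' @return A tibble with columns \code{i}, \code{j} (1-based, i < j) for every
#'   pair with \code{j - i > window}.
#' @export
eligible_pairs <- function(n, window) {
  idx <- which(eligible_mask(n, window, upper_only = TRUE), arr.ind = TRUE)
  tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2])) |>
    dplyr::arrange(.data$i, .data$j)
}

# derive a reproducible child seed from a base seed and a label;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483563
  as.integer(h + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# silence the benign glm chatter (separation / rank deficiency) that is
# expected when features separate the classes perfectly
muffle_glm <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("glm\\.fit|rank-deficient", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)
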