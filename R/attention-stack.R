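#' Attention stack for one molecule
#'
#' Holds the L x H x N x N non-negative attention weights a transformer
#' produces for one sequence: one N x N map per (layer, head). Raw stacks
#' (as emitted by a model, rows of each map summing to 1) are distinguished
#' from processed stacks (symmetrized and average-product-corrected) by the
#' \code{processed} flag. Special-token rows/columns must already be stripped
#' so maps are residue-by-residue.
#'
#' @param weights Numeric 4D array with dimensions (L, H, N, N).
#' @param molecule_id Identifier linking the stack to its molecule.
#' @param processed Logical; \code{TRUE} after [process_stack()].
#' @param check_rows If \code{TRUE} and \code{processed = FALSE}, verify each
#'   row of each map sums to 1 within 1e-6 (the row-normalization a softmax
#'   guarantees).
#' @return An \code{attention_stack}.
#' @export
attention_stack <- function(weights, molecule_id, processed = FALSE,
                            check_rows = FALSE) {
  d <- dim(weights)
  if (length(d) != 4L || d[3] != d[4])
    stop_attn("weights must be an (L, H, N, N) array", "attn_shape_error")
  if (any(is.na(weights)))
    stop_attn("attention weights contain NA", "attn_value_error")
  if (!processed && any(weights < 0)) {
    bad <- which(apply(weights < 0, c(1, 2), any), arr.ind = TRUE)[1, ]
    stop_attn(sprintf("negative attention weight in layer %d head %d",
                      bad[1], bad[2]), "attn_value_error")
  }
  if (check_rows && !processed) {
    rs <- apply(weights, c(1, 2, 3), sum)
    if (any(abs(rs - 1) > 1e-6)) {
      bad <- which(abs(rs - 1) > 1e-6, arr.ind = TRUE)[1, ]
      stop_attn(sprintf("row %d of layer %d head %d sums to %.8f, not 1",
                        bad[3], bad[1], bad[2], rs[bad[1], bad[2], bad[3]]),
                "attn_value_error")
    }
  }
  structure(list(molecule_id = molecule_id, n = d[3], L = d[1], H = d[2],
                 weights = weights, processed = processed),
            class = "attention_stack")
}

#' @export
print.attention_stack <- function(x, ...) {
  cat(sprintf("<attention_stack> %s: L = %d, H = %d, N = %d, %s\n",
              x$molecule_id, x$L, x$H, x$n,
              if (x$processed) "processed (symmetrized + APC)" else "raw"))
  invisible(x)
}

#' Symmetrize a square matrix
#'
#' Attention maps are asymmetric (row i attends to column j); the
#' symmetrized map \code{(A + t(A)) / 2} treats a token pair identically in
#' both orientations. Idempotent.
#'
#' @param m Square numeric matrix.
#' @return The symmetric part of \code{m}.
#' @export
symmetrize <- function(m) {
  if (!is_square(m)) stop_attn("symmetrize needs a square matrix", "attn_shape_error")
  (m + t(m)) / 2
}

#' Average product correction
#'
#' Subtracts the rank-1 background \code{rowsum_i * colsum_j / total} from
#' each entry, removing per-position attention trends (positions that attract
#' attention everywhere) so that residual weight reflects pair-specific
#' signal. Any rank-1 matrix is annihilated exactly.
#'
#' @param m Square numeric matrix with nonzero total sum.
#' @return The corrected matrix (entries may be negative).
#' @export
apc <- function(m) {
  if (!is_square(m)) stop_attn("apc needs a square matrix", "attn_shape_error")
  total <- sum(m)
  if (total == 0)
    stop_attn("apc is undefined for a matrix with zero total sum", "attn_degenerate_error")
  m - outer(rowSums(m), colSums(m)) / total
}

#' Symmetrize and APC-correct every map of a stack
#'
#' Applies [symmetrize()] then [apc()] to each (layer, head) map, in that
#' order, and flags the stack as processed. Feature extraction and map
#' prediction operate on processed stacks.
#'
#' @param stack A raw \code{attention_stack}.
#' @return A processed \code{attention_stack}.
#' @export
process_stack <- function(stack) {
  stopifnot(inherits(stack, "attention_stack"))
  if (stack$processed) stop_attn("stack is already processed", "attn_state_error")
  w <- stack$weights
  degenerate <- character(0)
  for (l in seq_len(stack$L)) for (h in seq_len(stack$H)) {
    m <- symmetrize(w[l, h, , ])
    if (sum(m) == 0) { degenerate <- c(degenerate, sprintf("layer %d head %d", l, h)); next }
    w[l, h, , ] <- apc(m)
  }
  if (length(degenerate) > 0)
    stop_attn(paste0("zero-sum attention maps (APC undefined) in: ",
                     paste(degenerate, collapse = "; ")),
              "attn_degenerate_error", heads = degenerate)
  attention_stack(w, stack$molecule_id, processed = TRUE)
}

#' Write an attention stack to disk
#'
#' The array container is an RDS file holding the (L, H, N, N) array, with a
#' JSON sidecar (\code{<path>.json}) recording molecule id, dimensions,
#' processing state and provenance.
#'
#' @param stack An \code{attention_stack}.
#' @param path Output path (conventionally \code{<id>.rds}).
#' @param provenance Optional named list stored in the sidecar.
#' @export
write_attention_stack <- function(stack, path, provenance = NULL) {
  saveRDS(stack$weights, path, version = 3L)
  sidecar <- list(molecule_id = stack$molecule_id,
                  L = stack$L, H = stack$H, n = stack$n,
                  processed = stack$processed)
  if (!is.null(provenance)) sidecar$provenance <- provenance
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an attention stack written by [write_attention_stack()]
#' @param path Path to the .rds container.
#' @return An \code{attention_stack}, validated on load.
#' @export
read_attention_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- readRDS(path)
  if (!identical(dim(w), as.integer(c(sidecar$L, sidecar$H, sidecar$n, sidecar$n))))
    stop_attn("stack dimensions disagree with sidecar", "attn_shape_error")
  attention_stack(w, sidecar$molecule_id, processed = isTRUE(sidecar$processed))
}

#' Attention provider backed by stored stacks
#'
#' The provider contract abstracts a language model: given a sequence (or an
#' id) it returns a validated [attention_stack()]. The file provider serves
#' stacks previously written to a directory, which is the reference
#' implementation used throughout; adapters wrapping real transformer
#' checkpoints can implement the same contract.
#'
#' @param dir Directory containing \code{<id>.rds} containers and sidecars.
#' @return A list with fields \code{ids}, \code{L}, \code{H},
#'   \code{max_length} and function \code{attention_for(id)}.
#' @export
file_attention_provider <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.rds$", full.names = TRUE))
  if (length(paths) == 0) stop_attn("no attention containers found", "attn_config_error")
  stacks <- lapply(paths, read_attention_stack)
  ids <- vapply(stacks, `[[`, character(1), "molecule_id")
  names(stacks) <- ids
  Ls <- unique(vapply(stacks, `[[`, integer(1), "L"))
  Hs <- unique(vapply(stacks, `[[`, integer(1), "H"))
  if (length(Ls) != 1L || length(Hs) != 1L)
    stop_attn("stacks disagree on (L, H) grid", "attn_shape_error")
  structure(list(
    ids = ids, L = Ls, H = Hs,
    max_length = max(vapply(stacks, `[[`, integer(1), "n")),
    attention_for = function(id, sequence = NULL) {
      if (!(id %in% ids)) stop_attn(sprintf("no stack for '%s'", id), "attn_config_error")
      st <- stacks[[id]]
      if (!is.null(sequence) && nchar(sequence) != st$n)
        stop_attn(sprintf("stack for '%s' has n = %d but sequence length is %d",
                          id, st$n, nchar(sequence)), "attn_alignment_error")
      st
    }
  ), class = "attention_provider")
}
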