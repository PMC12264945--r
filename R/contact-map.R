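#' Binary residue contact maps
#'
#' A contact map is an N x N symmetric 0/1 matrix marking residue pairs that
#' are in structural contact: within a distance cutoff for tertiary structure,
#' or base-paired for secondary structure. Entries inside the near-diagonal
#' exclusion band \code{|i - j| <= window} are zero once the band has been
#' applied.
#'
#' @param matrix Square 0/1 matrix (will be stored as integer).
#' @param window Exclusion band half-width already applied (0 = only the
#'   diagonal is guaranteed zero).
#' @param cutoff Distance cutoff in Angstrom used to derive the map, or
#'   \code{NA} when the map came from base pairs.
#' @return An object of class \code{contact_map}.
#' @export
contact_map <- function(matrix, window = 0L, cutoff = NA_real_) {
  if (!is_square(matrix)) stop_attn("contact map matrix must be square", "attn_shape_error")
  m <- matrix
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m != 0L & m != 1L))
    stop_attn("contact map entries must be 0 or 1", "attn_value_error")
  if (!isTRUE(all(m == t(m))))
    stop_attn("contact map must be symmetric", "attn_value_error")
  diag(m) <- 0L
  structure(
    list(n = nrow(m), matrix = m, window = as.integer(window), cutoff = cutoff),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  nc <- sum(x$matrix[upper.tri(x$matrix)])
  cat(sprintf(
    "<contact_map> n = %d, contacts = %d, window = %d, cutoff = %s\n",
    x$n, nc, x$window, ifelse(is.na(x$cutoff), "none", paste0(x$cutoff, " A"))
  ))
  invisible(x)
}

#' @export
as.matrix.contact_map <- function(x, ...) x$matrix

#' Number of contacts (upper triangle) in a map
#' @param map A \code{contact_map}.
#' @return Integer count of contacting pairs (i < j).
#' @export
n_contacts <- function(map) sum(map$matrix[upper.tri(map$matrix)])

#' Contact map from 3D coordinates
#'
#' Marks a residue pair as contacting when its inter-residue distance is at
#' most \code{cutoff} Angstrom. Two distance conventions are supported:
#' \code{"min_heavy_atom"} takes the minimum over all heavy-atom pairs of the
#' two residues (the most inclusive reading), \code{"representative_atom"}
#' uses one atom per residue (C3' for RNA; CB with CA fallback for protein).
#' The near-diagonal exclusion band is \emph{not} applied here (window is
#' recorded as 0); apply it separately with [apply_exclusion_band()].
#'
#' @param structure A \code{structure_3d} (see [read_structure()] /
#'   [gen_coords()]).
#' @param cutoff Distance cutoff in Angstrom (default 9.5).
#' @param atom_mode \code{"min_heavy_atom"} or \code{"representative_atom"}.
#' @return A \code{contact_map} with \code{window = 0}.
#' @export
coords_to_contact_map <- function(structure, cutoff = 9.5,
                                  atom_mode = c("min_heavy_atom", "representative_atom")) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(inherits(structure, "structure_3d"))
  if (cutoff <= 0) stop_attn("cutoff must be positive", "attn_config_error")
  res <- structure$residues
  n <- length(res)
  for (k in seq_len(n)) {
    if (is.null(res[[k]]$xyz) || nrow(res[[k]]$xyz) == 0L)
      stop_attn(sprintf("residue %d has no coordinates", k), "attn_missing_coords_error",
                residue = k)
  }
  if (atom_mode == "representative_atom") {
    kind <- structure$molecule$kind
    rep_xyz <- t(vapply(seq_len(n), function(k) {
      a <- res[[k]]
      pick <- if (kind == "rna") match("C3'", a$atoms) else match("CB", a$atoms)
      if (is.na(pick)) pick <- match("CA", a$atoms)
      if (is.na(pick)) pick <- 1L  # fall back to first heavy atom
      a$xyz[pick, ]
    }, numeric(3)))
    d <- as.matrix(stats::dist(rep_xyz))
    m <- (d <= cutoff) * 1L
  } else {
    # stack all atoms once; min over atom-pair blocks per residue pair
    all_xyz <- do.call(rbind, lapply(res, `[[`, "xyz"))
    res_of <- rep(seq_len(n), vapply(res, function(r) nrow(r$xyz), integer(1)))
    ad <- as.matrix(stats::dist(all_xyz))
    m <- matrix(0L, n, n)
    hit <- ad <= cutoff
    for (i in seq_len(n - 1)) {
      ri <- res_of == i
      for (j in (i + 1):n) {
        if (any(hit[ri, res_of == j])) m[i, j] <- m[j, i] <- 1L
      }
    }
  }
  diag(m) <- 0L
  contact_map(m, window = 0L, cutoff = cutoff)
}

#' Contact map from a base-pair list
#'
#' @param pairs Tibble/data frame with columns \code{i}, \code{j} (1-based),
#'   e.g. from [dotbracket_to_pairs()].
#' @param n Sequence length.
#' @return A \code{contact_map} with \code{window = 0} and no cutoff.
#' @export
pairs_to_contact_map <- function(pairs, n) {
  m <- matrix(0L, n, n)
  if (nrow(pairs) > 0) {
    if (any(pairs$i < 1L | pairs$j < 1L | pairs$i > n | pairs$j > n))
      stop_attn("pair index out of range", "attn_range_error")
    if (any(pairs$i == pairs$j))
      stop_attn("a position cannot pair with itself", "attn_value_error")
    m[cbind(pairs$i, pairs$j)] <- 1L
    m[cbind(pairs$j, pairs$i)] <- 1L
  }
  contact_map(m, window = 0L, cutoff = NA_real_)
}

#' Zero out near-diagonal contacts
#'
#' Removes contacts within \code{|i - j| <= window}: 4 positions for
#' nucleotides and 6 for amino acids by convention, so that classifiers focus
#' on long-range structure rather than chain adjacency. Idempotent for any
#' window not larger than one already applied.
#'
#' @param map A \code{contact_map}.
#' @param window Band half-width (non-negative integer).
#' @return A \code{contact_map} with the band zeroed and \code{window} set to
#'   the largest band applied so far.
#' @export
apply_exclusion_band <- function(map, window) {
  stopifnot(inherits(map, "contact_map"), window >= 0)
  m <- map$matrix
  m[!eligible_mask(map$n, window)] <- 0L
  contact_map(m, window = max(map$window, as.integer(window)), cutoff = map$cutoff)
}

#' Default exclusion window by molecule kind
#'
#' 4 positions between nucleotides, 6 between amino acids.
#' @param kind \code{"rna"} or \code{"protein"}.
#' @return Integer window.
#' @export
default_window <- function(kind = c("rna", "protein")) {
  switch(match.arg(kind), rna = 4L, protein = 6L)
}
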