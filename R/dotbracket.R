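# Bracket tiers follow the bpRNA convention: nested structure in '()',
# pseudoknot tiers in '[]', '{}', '<>', then letter pairs 'Aa'..'Za'.
# Each tier is parsed with its own stack, so crossings between tiers are legal.
db_open_chars <- c("(", "[", "{", "<", LETTERS)
db_close_chars <- c(")", "]", "}", ">", letters)

#' Parse dot-bracket secondary structure into base pairs
#'
#' Matched brackets denote paired positions, dots unpaired ones; additional
#' bracket tiers ('[]', '\{\}', '<>', 'Aa'..'Za') encode pseudoknots, each tier
#' balanced independently.
#'
#' @param db A dot-bracket string.
#' @return A tibble with columns \code{i}, \code{j} (1-based, i < j), one row
#'   per base pair, ordered by \code{i}; attribute \code{n} holds the length.
#' @export
dotbracket_to_pairs <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "")[[1]]
  bad <- which(!(chars %in% c(".", db_open_chars, db_close_chars)))
  if (length(bad) > 0)
    stop_attn(sprintf("unsupported character '%s' at position %d", chars[bad[1]], bad[1]),
              "attn_parse_error", position = bad[1])
  is <- integer(0); js <- integer(0)
  for (t in seq_along(db_open_chars)) {
    op <- db_open_chars[t]; cl <- db_close_chars[t]
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == op) {
        stack <- c(stack, k)
      } else if (chars[k] == cl) {
        if (length(stack) == 0L)
          stop_attn(sprintf("unbalanced '%s' at position %d", cl, k),
                    "attn_parse_error", position = k)
        is <- c(is, stack[length(stack)]); js <- c(js, k)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L)
      stop_attn(sprintf("unbalanced '%s' at position %d", op, stack[length(stack)]),
                "attn_parse_error", position = stack[length(stack)])
  }
  out <- tibble(i = is, j = js) |> dplyr::arrange(.data$i)
  attr(out, "n") <- length(chars)
  out
}

#' Render base pairs as dot-bracket
#'
#' Pairs are greedily assigned to bracket tiers: a pair goes to the first tier
#' in which it crosses no previously placed pair, so purely nested inputs
#' round-trip through '()' alone and crossings spill into pseudoknot tiers.
#'
#' @param pairs Tibble with columns \code{i}, \code{j} (1-based).
#' @param n Sequence length.
#' @return A dot-bracket string of length \code{n}.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  chars <- rep(".", n)
  if (nrow(pairs) == 0) return(paste(chars, collapse = ""))
  seen <- sort(c(pairs$i, pairs$j))
  if (anyDuplicated(seen) || any(seen < 1L) || any(seen > n))
    stop_attn("pairs must form a matching with indices in 1..n", "attn_value_error")
  ord <- order(pairs$i)
  tiers <- list()
  for (r in ord) {
    i <- pairs$i[r]; j <- pairs$j[r]
    placed <- FALSE
    for (t in seq_along(tiers)) {
      cross <- vapply(tiers[[t]], function(p)
        (p[1] < i & i < p[2] & p[2] < j) | (i < p[1] & p[1] < j & j < p[2]),
        logical(1))
      if (!any(cross)) {
        tiers[[t]] <- c(tiers[[t]], list(c(i, j))); placed <- TRUE
        chars[i] <- db_open_chars[t]; chars[j] <- db_close_chars[t]
        break
      }
    }
    if (!placed) {
      t <- length(tiers) + 1L
      if (t > length(db_open_chars))
        stop_attn("too many crossing tiers to render", "attn_value_error")
      tiers[[t]] <- list(c(i, j))
      chars[i] <- db_open_chars[t]; chars[j] <- db_close_chars[t]
    }
  }
  paste(chars, collapse = "")
}

#' A sequence record
#'
#' @param id Molecule identifier.
#' @param sequence Residue string; RNA uses the ACGU alphabet, protein the 20
#'   standard one-letter codes. Modified or unknown residues are rejected.
#' @param kind \code{"rna"} or \code{"protein"}.
#' @return A \code{molecule} object (list with id, sequence, kind, n).
#' @export
molecule <- function(id, sequence, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop_attn("sequence must be non-empty", "attn_value_error")
  alphabet <- if (kind == "rna") c("A", "C", "G", "U") else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% alphabet))
  if (length(bad) > 0)
    stop_attn(sprintf("residue '%s' at position %d is outside the %s alphabet",
                      chars[bad[1]], bad[1], kind), "attn_value_error")
  structure(list(id = id, sequence = sequence, kind = kind, n = length(chars)),
            class = "molecule")
}

#' Read dot-bracket (.dbn) files
#'
#' Accepts plain dot-bracket lines or FASTA-style records of the form
#' \code{>id}, sequence line, structure line.
#'
#' @param path Path to a .dbn file.
#' @return A tibble with columns \code{id}, \code{sequence} (may be \code{NA}),
#'   \code{db}.
#' @export
read_dbn <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); seqs <- character(0); dbs <- character(0)
  k <- 1L; auto <- 0L
  while (k <= length(lines)) {
    ln <- trimws(lines[k])
    if (startsWith(ln, ">")) {
      id <- sub("^>\\s*", "", ln)
      if (k + 2L > length(lines))
        stop_attn("truncated dbn record", "attn_parse_error")
      seqs <- c(seqs, trimws(lines[k + 1L])); dbs <- c(dbs, trimws(lines[k + 2L]))
      ids <- c(ids, id); k <- k + 3L
    } else {
      auto <- auto + 1L
      ids <- c(ids, paste0("structure_", auto))
      seqs <- c(seqs, NA_character_); dbs <- c(dbs, ln)
      k <- k + 1L
    }
  }
  tibble(id = ids, sequence = seqs, db = dbs)
}

#' Read a CT (connectivity table) file
#'
#' CT files are 1-based: each row gives position, base, and the paired
#' position (0 when unpaired).
#'
#' @param path Path to a .ct file.
#' @return A list with \code{sequence} and a pair tibble (\code{i}, \code{j}).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop_attn("malformed CT header", "attn_parse_error")
  body <- utils::read.table(text = lines[2:(n + 1L)], stringsAsFactors = FALSE)
  pos <- body[[1]]; base <- body[[2]]; mate <- body[[5]]
  if (!all(pos == seq_len(n))) stop_attn("CT positions not consecutive", "attn_parse_error")
  keep <- mate > 0 & mate > pos
  list(sequence = paste(base, collapse = ""),
       pairs = tibble(i = as.integer(pos[keep]), j = as.integer(mate[keep])))
}

#' Write a pair list as a CT file
#' @param pairs Pair tibble (1-based \code{i}, \code{j}).
#' @param sequence Residue string.
#' @param path Output path.
#' @param id Record name for the header.
#' @export
write_ct <- function(pairs, sequence, path, id = "molecule") {
  n <- nchar(sequence)
  mate <- integer(n)
  mate[pairs$i] <- pairs$j; mate[pairs$j] <- pairs$i
  chars <- strsplit(sequence, "")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %s", n, id), con)
  writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), chars,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L), mate, seq_len(n)), con)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file path.
#' @param kind Molecule kind for validation.
#' @return A tibble with columns \code{id}, \code{sequence}.
#' @export
read_fasta_sequences <- function(path, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(set)), sequence = unname(as.character(set)))
}

#' Write contact map to disk
#'
#' Two plain-text formats: \code{"edges"} writes one line per contact as
#' \code{i<TAB>j} with 0-based indices and i < j; \code{"dense"} writes the
#' full 0/1 matrix, space-separated, one row per line.
#'
#' @param map A \code{contact_map}.
#' @param path Output path.
#' @param format \code{"edges"} or \code{"dense"}.
#' @export
write_contact_map <- function(map, path, format = c("edges", "dense")) {
  format <- match.arg(format)
  if (format == "edges") {
    idx <- which(map$matrix == 1L & upper.tri(map$matrix), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(c(sprintf("# n=%d window=%d", map$n, map$window),
                 sprintf("%d\t%d", idx[, 1] - 1L, idx[, 2] - 1L)), path)
  } else {
    writeLines(apply(map$matrix, 1, paste, collapse = " "), path)
  }
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#' @param path File path.
#' @param n Length (required for edge lists without a header).
#' @param format \code{"edges"} or \code{"dense"}.
#' @return A \code{contact_map}.
#' @export
read_contact_map <- function(path, n = NULL, format = c("edges", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    return(contact_map(m))
  }
  lines <- readLines(path)
  window <- 0L
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) > 0) {
    nm <- regmatches(hdr[1], regexec("n=(\\d+) window=(\\d+)", hdr[1]))[[1]]
    if (length(nm) == 3) { n <- n %||% as.integer(nm[2]); window <- as.integer(nm[3]) }
  }
  if (is.null(n)) stop_attn("edge-list contact map needs n", "attn_config_error")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    pairs <- tibble(i = integer(0), j = integer(0))
  } else {
    tab <- utils::read.table(text = lines)
    pairs <- tibble(i = as.integer(tab[[1]]) + 1L, j = as.integer(tab[[2]]) + 1L)
  }
  map <- pairs_to_contact_map(pairs, n)
  contact_map(map$matrix, window = window, cutoff = NA_real_)
}
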