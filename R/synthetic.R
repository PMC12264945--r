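#' Specification of a synthetic probing corpus
#'
#' The generator stands in for a pretrained language model plus a curated
#' structure set: it emulates (i) nested RNA secondary structures with
#' optional pseudoknots and sparse long-range tertiary contacts and (ii)
#' attention stacks in which a designated subset of heads mixes the true
#' contact pattern with noise at a controlled signal fraction \code{alpha}.
#' \code{alpha = 1} gives perfectly structure-aware heads (the protein-like
#' regime), \code{alpha = 0} pure noise (the RNA-like regime).
#'
#' @param n_molecules Number of molecules.
#' @param length_range Inclusive range of sequence lengths.
#' @param n_layers,n_heads Attention grid (default 6 x 12, the size of a
#'   small RNA language model).
#' @param aware_heads Tibble with columns \code{layer}, \code{head} naming
#'   the structurally aware heads. The default plants up to 3 aware heads in
#'   the last layers of the grid, mirroring the observation that structural
#'   information concentrates in a model's upper layers.
#' @param alpha Signal fraction in \eqn{[0, 1]} mixed into aware heads.
#' @param pseudoknot_prob Probability a molecule receives one crossing stem.
#' @param n_tertiary_extras Long-range non-nested contacts added per molecule.
#' @param window Exclusion band half-width used for map generation (4 for
#'   RNA).
#' @param seed Master seed; every downstream draw derives from it.
#' @return A \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_molecules = 50L, length_range = c(40L, 80L),
                           n_layers = 6L, n_heads = 12L,
                           aware_heads = NULL, alpha = 0.8,
                           pseudoknot_prob = 0.1, n_tertiary_extras = 2L,
                           window = 4L, seed = 1L) {
  if (is.null(aware_heads)) {
    k <- min(3L, n_layers * n_heads)
    cell <- n_layers * n_heads - (k - 1L):0L  # last cells, layer-major
    aware_heads <- tibble(layer = as.integer(ceiling(cell / n_heads)),
                          head = as.integer(cell - (ceiling(cell / n_heads) - 1L) * n_heads))
  }
  stopifnot(alpha >= 0, alpha <= 1,
            all(aware_heads$layer >= 1L & aware_heads$layer <= n_layers),
            all(aware_heads$head >= 1L & aware_heads$head <= n_heads))
  structure(list(n_molecules = as.integer(n_molecules),
                 length_range = as.integer(length_range),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 aware_heads = aware_heads, alpha = alpha,
                 pseudoknot_prob = pseudoknot_prob,
                 n_tertiary_extras = as.integer(n_tertiary_extras),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# recursively fill [lo, hi] with stem-loop elements; stems 3-6 bp, loops >= 3
gen_nested_region <- function(lo, hi, chars) {
  len <- hi - lo + 1L
  if (len < 2L * 3L + 3L) return(chars)  # too short for a stem + hairpin loop
  s_max <- min(6L, (len - 3L) %/% 2L)
  s <- sample(3L:s_max, 1L)
  chars[lo:(lo + s - 1L)] <- "("
  chars[(hi - s + 1L):hi] <- ")"
  in_lo <- lo + s; in_hi <- hi - s
  in_len <- in_hi - in_lo + 1L
  if (in_len >= 2L * (2L * 3L + 3L) + 1L && stats::runif(1) < 0.35) {
    cut <- sample((in_lo + 2L * 3L + 3L - 1L):(in_hi - (2L * 3L + 3L)), 1L)
    chars <- gen_nested_region(in_lo, cut, chars)
    chars <- gen_nested_region(cut + 1L, in_hi, chars)
  } else if (in_len >= 2L * 3L + 3L + 3L && stats::runif(1) < 0.5) {
    # interior loop: leave a short bulge then continue the helix inward
    bulge <- sample(1L:3L, 1L)
    chars <- gen_nested_region(in_lo + bulge, in_hi, chars)
  } else {
    chars <- gen_nested_region(in_lo, in_hi, chars)
  }
  chars
}

#' Generate a synthetic secondary structure
#'
#' Builds a valid nested dot-bracket string by recursive stem-loop placement
#' (stem length 3-6 bp, loops of at least 3 nt), optionally adding one
#' crossing stem on the '[' tier to emulate a pseudoknot. Deterministic for
#' a fixed seed.
#'
#' @param n Sequence length (>= 10).
#' @param pseudoknot_prob Probability of adding a crossing stem.
#' @param seed Integer seed.
#' @return A dot-bracket string of length \code{n}.
#' @export
gen_secondary <- function(n, pseudoknot_prob = 0, seed = 1L) {
  stopifnot(n >= 10L)
  withr::with_seed(as.integer(seed), {
    margin <- sample(0L:2L, 2L, replace = TRUE)
    chars <- rep(".", n)
    chars <- gen_nested_region(1L + margin[1], n - margin[2], chars)
    if (stats::runif(1) < pseudoknot_prob) {
      # pair two unpaired runs across an existing stem boundary so the new
      # '[' tier genuinely crosses a '(' pair (e.g. hairpin loop to exterior)
      existing <- local({
        stack <- integer(0); out <- NULL
        for (k in seq_along(chars)) {
          if (chars[k] == "(") stack <- c(stack, k)
          if (chars[k] == ")") { out <- rbind(out, c(stack[length(stack)], k))
                                 stack <- stack[-length(stack)] }
        }
        out
      })
      unp <- which(chars == ".")
      runs <- unname(split(unp, cumsum(c(1, diff(unp) != 1))))
      runs <- Filter(function(r) length(r) >= 2L, runs)
      placed <- FALSE
      if (length(runs) >= 2L && !is.null(existing)) {
        for (ra in seq_len(length(runs) - 1L)) {
          for (rb in (ra + 1L):length(runs)) {
            a <- max(runs[[ra]]); b <- min(runs[[rb]])
            crosses <- any((existing[, 1] < a & a < existing[, 2] & existing[, 2] < b) |
                           (a < existing[, 1] & existing[, 1] < b & b < existing[, 2]))
            if (crosses) {
              k <- min(2L, length(runs[[ra]]), length(runs[[rb]]))
              ra_pos <- utils::tail(runs[[ra]], k)
              rb_pos <- utils::head(runs[[rb]], k)
              for (t in seq_len(k)) {
                chars[ra_pos[t]] <- "["
                chars[rb_pos[k - t + 1L]] <- "]"
              }
              placed <- TRUE; break
            }
          }
          if (placed) break
        }
      }
    }
    paste(chars, collapse = "")
  })
}

#' Secondary pairs plus sparse long-range tertiary contacts
#'
#' Starts from the base pairs of a dot-bracket string and adds
#' \code{n_extras} random long-range contacts (\code{j - i > window}, each
#' residue participating in at most 2 extras), emulating the tertiary
#' contacts a distance cutoff picks up beyond the secondary structure.
#'
#' @param db Dot-bracket string.
#' @param n_extras Number of extra contacts.
#' @param window Band half-width the extras must clear.
#' @param seed Integer seed.
#' @return A [contact_map()] (band not yet applied; window recorded as 0).
#' @export
gen_tertiary_map <- function(db, n_extras = 0L, window = 4L, seed = 1L) {
  pairs <- dotbracket_to_pairs(db)
  n <- attr(pairs, "n")
  if (n_extras > 0L) {
    extras <- withr::with_seed(as.integer(seed), {
      cand <- eligible_pairs(n, window)
      have <- paste(pairs$i, pairs$j)
      cand <- cand[!(paste(cand$i, cand$j) %in% have), ]
      picked <- tibble(i = integer(0), j = integer(0))
      use_count <- integer(n)
      ord <- sample(nrow(cand))
      for (r in ord) {
        if (nrow(picked) == n_extras) break
        i <- cand$i[r]; j <- cand$j[r]
        if (use_count[i] < 2L && use_count[j] < 2L) {
          picked <- dplyr::bind_rows(picked, tibble(i = i, j = j))
          use_count[i] <- use_count[i] + 1L; use_count[j] <- use_count[j] + 1L
        }
      }
      if (nrow(picked) < n_extras)
        stop_attn("not enough eligible positions for the requested extras",
                  "attn_generation_error")
      picked
    })
    pairs <- dplyr::bind_rows(as_tibble(pairs), extras)
  }
  pairs_to_contact_map(pairs, n)
}

#' Toy coordinates realizing a given matching
#'
#' Places residues on a line at 20 Angstrom spacing, then translates each
#' matched partner to 3 Angstrom from its mate, guaranteeing that the
#' contact map at the 9.5 Angstrom cutoff (after band filtering) is exactly
#' the supplied matching. Each residue gets two heavy atoms (C3' and P) so
#' both atom modes are exercised.
#'
#' @param matching Tibble of pairs (\code{i}, \code{j}), each index used at
#'   most once, all with \code{j - i > window}.
#' @param n Number of residues.
#' @param window Band half-width the matching must clear.
#' @param id Molecule id.
#' @param seed Unused (placement is deterministic); kept for interface
#'   uniformity.
#' @return A \code{structure_3d} with an RNA molecule of \code{n} A's... the
#'   sequence is random ACGU.
#' @export
gen_coords <- function(matching, n, window = 4L, id = "synthetic", seed = 1L) {
  idx <- c(matching$i, matching$j)
  if (anyDuplicated(idx) || any(idx < 1L | idx > n))
    stop_attn("matching must use each index at most once, within 1..n",
              "attn_generation_error")
  if (nrow(matching) > 0 && any(matching$j - matching$i <= window))
    stop_attn("matched pair falls inside the exclusion band", "attn_generation_error")
  pos <- cbind(20 * (seq_len(n) - 1), 0, 0)
  for (r in seq_len(nrow(matching))) {
    pos[matching$j[r], ] <- pos[matching$i[r], ] + c(0, 3, 0)
  }
  seqn <- withr::with_seed(as.integer(seed),
                           paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = ""))
  residues <- lapply(seq_len(n), function(k) list(
    atoms = c("C3'", "P"),
    xyz = rbind(pos[k, ], pos[k, ] + c(0, 0, 1.2))
  ))
  structure_3d(molecule(id, seqn, "rna"), residues)
}

#' Simulated attention stack with planted structural signal
#'
#' Aware heads distribute each row's attention as
#' \code{alpha * C(i, .) / deg(i) + (1 - alpha) * noise} (rows without
#' contacts put the signal share on the diagonal, i.e. self-attention);
#' unaware heads follow a locality kernel \code{exp(-|i - j| / 2)} plus
#' noise. Noise is Dirichlet-style (normalized Gamma draws) so every row is
#' non-negative and renormalized to sum to 1, matching the softmax contract.
#'
#' @param map A [contact_map()] providing the planted contacts (typically
#'   after [apply_exclusion_band()], so that at \code{alpha = 1} all off-band
#'   mass sits on contacts).
#' @param spec A [synthetic_spec()] (grid, aware heads, alpha).
#' @param molecule_id Id stored in the stack.
#' @param seed Integer seed.
#' @return A raw [attention_stack()].
#' @export
gen_attention_stack <- function(map, spec, molecule_id = "synthetic", seed = 1L) {
  L <- spec$n_layers; H <- spec$n_heads; n <- map$n
  aware <- matrix(FALSE, L, H)
  aware[cbind(spec$aware_heads$layer, spec$aware_heads$head)] <- TRUE
  C <- map$matrix
  deg <- rowSums(C)
  signal <- C / pmax(deg, 1)
  nosig <- deg == 0
  if (any(nosig)) signal[cbind(which(nosig), which(nosig))] <- 1
  kernel <- exp(-abs(outer(seq_len(n), seq_len(n), "-")) / 2)
  kernel <- kernel / rowSums(kernel)
  w <- array(0, dim = c(L, H, n, n))
  withr::with_seed(as.integer(seed), {
    for (l in seq_len(L)) for (h in seq_len(H)) {
      g <- matrix(stats::rgamma(n * n, shape = 1), n, n)
      noise <- g / rowSums(g)
      m <- if (aware[l, h]) spec$alpha * signal + (1 - spec$alpha) * noise
           else 0.8 * kernel + 0.2 * noise
      w[l, h, , ] <- m / rowSums(m)
    }
  })
  attention_stack(w, molecule_id, processed = FALSE)
}

#' Generate a full synthetic corpus
#'
#' Produces aligned triplets (molecule, contact map, attention stack) for
#' every molecule of the spec: a nested secondary structure with optional
#' pseudoknot, added tertiary extras, a stem-complementary ACGU sequence
#' (A-U / G-C under stems), the band-filtered contact map, and a raw
#' attention stack planted from that map. Fully deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An \code{attn_corpus}: list with \code{molecules} (tibble: id,
#'   sequence, kind, db, n), \code{maps} and \code{stacks} (named lists),
#'   and \code{spec}.
#' @export
gen_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- sprintf("mol_%03d", seq_len(spec$n_molecules))
  lens <- withr::with_seed(derive_seed(spec$seed, "lengths"),
    sample(seq(spec$length_range[1], spec$length_range[2]), spec$n_molecules, TRUE))
  maps <- list(); stacks <- list()
  rows <- vector("list", spec$n_molecules)
  for (k in seq_len(spec$n_molecules)) {
    id <- ids[k]; n <- lens[k]
    db <- gen_secondary(n, spec$pseudoknot_prob, seed = derive_seed(spec$seed, paste0("db_", id)))
    map <- gen_tertiary_map(db, spec$n_tertiary_extras, spec$window,
                            seed = derive_seed(spec$seed, paste0("map_", id)))
    map <- apply_exclusion_band(map, spec$window)
    seqn <- gen_paired_sequence(db, seed = derive_seed(spec$seed, paste0("seq_", id)))
    stack <- gen_attention_stack(map, spec, molecule_id = id,
                                 seed = derive_seed(spec$seed, paste0("attn_", id)))
    maps[[id]] <- map; stacks[[id]] <- stack
    rows[[k]] <- tibble(id = id, sequence = seqn, kind = "rna", db = db, n = n)
  }
  structure(list(molecules = dplyr::bind_rows(rows), maps = maps,
                 stacks = stacks, spec = spec),
            class = "attn_corpus")
}

# random ACGU sequence whose stem positions carry Watson-Crick partners
gen_paired_sequence <- function(db, seed = 1L) {
  pairs <- dotbracket_to_pairs(db)
  n <- attr(pairs, "n")
  withr::with_seed(as.integer(seed), {
    chars <- sample(c("A", "C", "G", "U"), n, TRUE)
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    for (r in seq_len(nrow(pairs))) chars[pairs$j[r]] <- comp[[chars[pairs$i[r]]]]
    paste(chars, collapse = "")
  })
}

#' @export
print.attn_corpus <- function(x, ...) {
  cat(sprintf("<attn_corpus> %d molecules, L = %d, H = %d, alpha = %.2f, %d aware head(s)\n",
              nrow(x$molecules), x$spec$n_layers, x$spec$n_heads, x$spec$alpha,
              nrow(x$spec$aware_heads)))
  invisible(x)
}

#' Write a corpus to a directory
#'
#' Layout: \code{sequences.fasta}, \code{structures.dbn}, contact-map edge
#' lists under \code{maps/}, attention containers under \code{attention/},
#' and \code{manifest.json} with the full generating spec.
#'
#' @param corpus An \code{attn_corpus}.
#' @param dir Output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "attention"), showWarnings = FALSE)
  mol <- corpus$molecules
  writeLines(as.vector(rbind(paste0(">", mol$id), mol$sequence)),
             file.path(dir, "sequences.fasta"))
  writeLines(as.vector(rbind(paste0(">", mol$id), mol$sequence, mol$db)),
             file.path(dir, "structures.dbn"))
  for (id in mol$id) {
    write_contact_map(corpus$maps[[id]], file.path(dir, "maps", paste0(id, ".tsv")))
    write_attention_stack(corpus$stacks[[id]],
                          file.path(dir, "attention", paste0(id, ".rds")))
  }
  sp <- corpus$spec
  manifest <- list(n_molecules = sp$n_molecules, length_range = sp$length_range,
                   n_layers = sp$n_layers, n_heads = sp$n_heads,
                   aware_heads = as.data.frame(sp$aware_heads), alpha = sp$alpha,
                   pseudoknot_prob = sp$pseudoknot_prob,
                   n_tertiary_extras = sp$n_tertiary_extras,
                   window = sp$window, seed = sp$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#' @param dir Corpus directory.
#' @return An \code{attn_corpus}.
#' @export
read_corpus <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  spec <- synthetic_spec(n_molecules = man$n_molecules,
                         length_range = man$length_range,
                         n_layers = man$n_layers, n_heads = man$n_heads,
                         aware_heads = as_tibble(man$aware_heads),
                         alpha = man$alpha, pseudoknot_prob = man$pseudoknot_prob,
                         n_tertiary_extras = man$n_tertiary_extras,
                         window = man$window, seed = man$seed)
  dbn <- read_dbn(file.path(dir, "structures.dbn"))
  mols <- tibble(id = dbn$id, sequence = dbn$sequence, kind = "rna",
                 db = dbn$db, n = nchar(dbn$db))
  maps <- list(); stacks <- list()
  for (id in mols$id) {
    maps[[id]] <- read_contact_map(file.path(dir, "maps", paste0(id, ".tsv")))
    stacks[[id]] <- read_attention_stack(file.path(dir, "attention", paste0(id, ".rds")))
  }
  structure(list(molecules = mols, maps = maps, stacks = stacks, spec = spec),
            class = "attn_corpus")
}
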