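aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")
rna1 <- c(A = "A", C = "C", G = "G", U = "U")

#' A 3D structure aligned to a molecule
#'
#' @param molecule A [molecule()].
#' @param residues List of residue records, each a list with \code{atoms}
#'   (character vector of atom names) and \code{xyz} (matrix of coordinates in
#'   Angstrom, one row per atom).
#' @return A \code{structure_3d} object.
#' @export
structure_3d <- function(molecule, residues) {
  stopifnot(inherits(molecule, "molecule"))
  if (length(residues) != molecule$n)
    stop_attn(sprintf("structure has %d residues but sequence length is %d",
                      length(residues), molecule$n), "attn_alignment_error")
  for (k in seq_along(residues)) {
    r <- residues[[k]]
    if (length(r$atoms) == 0L || is.null(r$xyz) || nrow(r$xyz) != length(r$atoms))
      stop_attn(sprintf("residue %d has no atoms or mismatched coordinates", k),
                "attn_value_error")
  }
  structure(list(molecule = molecule, residues = residues), class = "structure_3d")
}

#' @export
print.structure_3d <- function(x, ...) {
  cat(sprintf("<structure_3d> %s (%s), %d residues, %d atoms\n",
              x$molecule$id, x$molecule$kind, x$molecule$n,
              sum(vapply(x$residues, function(r) length(r$atoms), integer(1)))))
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' Uses the first model; hydrogens and HETATM records are dropped. Residues
#' whose names fall outside the standard alphabet (modified or unknown
#' residues) cause an error, mirroring strict cleaning of training structures.
#'
#' @param path Path to a .pdb or .cif file (format chosen by extension).
#' @param kind \code{"rna"} or \code{"protein"}.
#' @param chain Chain identifier; defaults to the first chain present. An
#'   absent chain is an error.
#' @param id Molecule id; defaults to the file base name.
#' @return A \code{structure_3d}.
#' @export
read_structure <- function(path, kind = c("rna", "protein"), chain = NULL, id = NULL) {
  kind <- match.arg(kind)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$elesy) | !(at$elesy %in% c("H", "D")), , drop = FALSE]
  at <- at[!grepl("^H", trimws(at$elety)) | !is.na(at$elesy), , drop = FALSE]
  chains <- unique(at$chain)
  chain <- chain %||% chains[1]
  if (!(chain %in% chains))
    stop_attn(sprintf("chain '%s' not present (available: %s)", chain,
                      paste(chains, collapse = ", ")), "attn_config_error")
  at <- at[at$chain == chain, , drop = FALSE]
  key <- paste(at$resno, at$insert %||% "", sep = "_")
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  letters1 <- character(length(groups))
  residues <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    rows <- at[groups[[k]], , drop = FALSE]
    resid <- trimws(rows$resid[1])
    letter <- if (kind == "rna") unname(rna1[resid]) else unname(aa3to1[resid])
    if (is.na(letter) || is.null(letter))
      stop_attn(sprintf("non-standard residue '%s' at position %d", resid, k),
                "attn_value_error")
    letters1[k] <- letter
    residues[[k]] <- list(atoms = trimws(rows$elety),
                          xyz = cbind(rows$x, rows$y, rows$z))
  }
  mol <- molecule(id %||% sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE),
                  paste(letters1, collapse = ""), kind)
  structure_3d(mol, residues)
}

#' Write a structure to PDB
#' @param structure A \code{structure_3d}.
#' @param path Output path.
#' @export
write_structure_pdb <- function(structure, path) {
  res <- structure$residues
  kind <- structure$molecule$kind
  chars <- strsplit(structure$molecule$sequence, "")[[1]]
  resid3 <- if (kind == "rna") chars else names(aa3to1)[match(chars, aa3to1)]
  xyz <- do.call(rbind, lapply(res, `[[`, "xyz"))
  nat <- vapply(res, function(r) length(r$atoms), integer(1))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    resno = rep(seq_along(res), nat),
    resid = rep(resid3, nat),
    elety = unlist(lapply(res, `[[`, "atoms")),
    chain = rep("A", sum(nat))
  )
  invisible(path)
}
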