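## structio: structure/sequence data model and I/O.
##
## A `bh3_structure` is a light S3 wrapper around a flat atom table --
## the representation used throughout the package. Columns:
##   chain  character, single-letter chain id
##   resno  integer, author residue number (1-based, as cited in the field)
##   insert character, insertion code ("" if none)
##   resid  character, 3-letter residue name
##   elety  character, atom name (PDB convention: N, CA, C, O, CB, ...)
##   elem   character, element symbol
##   x,y,z  numeric, Cartesian coordinates in Angstrom
##   occ,b  numeric, occupancy and B-factor
##   het    logical, TRUE for HETATM records

AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)
AA123 <- stats::setNames(names(AA321)[1:20], AA321[1:20])

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   elem, x, y, z, occ, b, het (missing optional columns are filled).
#' @param metadata list of free-text header fields (e.g. `remarks`, `entry`).
#' @return An object of class `bh3_structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$elem)) atoms$elem <- substr(trimws(atoms$elety), 1, 1)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "bh3_structure")
}

#' @export
print.bh3_structure <- function(x, ...) {
  a <- x$atoms
  pol <- a[!a$het, , drop = FALSE]
  ch <- unique(pol$chain)
  cat("bh3_structure:", nrow(a), "atoms,", length(ch), "polymer chain(s)\n")
  for (cc in ch) {
    r <- pol[pol$chain == cc, ]
    cat(sprintf("  chain %s: %d residues (%d-%d)\n", cc,
                length(unique(paste(r$resno, r$insert))),
                min(r$resno), max(r$resno)))
  }
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s A `bh3_structure`.
#' @param polymer Restrict to polymer (ATOM-record) chains.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(s, polymer = TRUE) {
  a <- s$atoms
  if (polymer) a <- a[!a$het, , drop = FALSE]
  unique(a$chain)
}

## Residue table for one chain, in file (author) order: one row per residue.
residue_table <- function(s, chain) {
  a <- s$atoms
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (!nrow(a)) stop("chain '", chain, "' not found or has no polymer atoms")
  key <- paste(a$resno, a$insert, sep = "|")
  idx <- !duplicated(key)
  data.frame(resno = a$resno[idx], insert = a$insert[idx],
             resid = a$resid[idx], key = key[idx], stringsAsFactors = FALSE)
}

## Coordinates of one named atom per residue of a chain; NA rows where absent.
atom_coords <- function(s, chain, elety = "CA") {
  rt <- residue_table(s, chain)
  a <- s$atoms
  a <- a[a$chain == chain & !a$het & trimws(a$elety) == elety, , drop = FALSE]
  akey <- paste(a$resno, a$insert, sep = "|")
  m <- matrix(NA_real_, nrow(rt), 3)
  hit <- match(rt$key, akey)
  ok <- !is.na(hit)
  m[ok, ] <- as.matrix(a[hit[ok], c("x", "y", "z")])
  m
}

#' Read a macromolecular structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' letter, 'A' first); heteroatoms are retained and flagged `het`.
#' `REMARK  99` lines are collected into `metadata$remarks` so that
#' provenance written by [write_structure()] survives a round trip.
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb"` is supported.
#' @return A [new_structure()] object.
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ", conditionMessage(e))
  )
  a <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    elem = ifelse(is.na(a$elesy) | a$elesy == "", substr(trimws(a$elety), 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    het = a$type == "HETATM",
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
  if (!any(!atoms$het)) stop("empty structure: no polymer (ATOM) records in '", path, "'")
  ## altloc resolution: highest occupancy wins, then earliest altloc letter
  key <- paste(atoms$chain, atoms$resno, atoms$insert, trimws(atoms$elety), sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occ, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$alt <- NULL
  remarks <- grep("^REMARK  99", readLines(path, warn = FALSE), value = TRUE)
  remarks <- sub("^REMARK  99 ?", "", remarks)
  new_structure(atoms, metadata = list(remarks = remarks, source = path))
}

#' Write a structure to a PDB file
#'
#' Atom records are emitted through [bio3d::write.pdb()]; serial numbers
#' above 99999 follow bio3d's convention (wrap). Any `metadata$remarks`
#' entries are prepended as `REMARK  99` lines.
#'
#' @param s A `bh3_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, trimws(a$elety), a$het, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate atom identifiers (chain/residue/atom collision); ",
         "re-chain before writing")
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
    o = a$occ, b = a$b, elesy = a$elem
  )
  con <- file(path, "w")
  on.exit(close(con))
  rem <- s$metadata$remarks
  if (length(rem)) writeLines(paste("REMARK  99", rem), con)
  writeLines(readLines(tmp, warn = FALSE), con)
  unlink(tmp)
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' Nonstandard residues map to `X`, except selenomethionine (MSE) which is
#' read as `M` (noted in the result's `substitutions` attribute).
#'
#' @param s A `bh3_structure`.
#' @param chain Chain id.
#' @return A `protein_sequence`: list with `id` and `residues` (string).
#' @export
extract_sequence <- function(s, chain) {
  rt <- residue_table(s, chain)
  one <- unname(AA321[rt$resid])
  subs <- rt$resid[rt$resid == "MSE"]
  one[is.na(one)] <- "X"
  seq <- protein_sequence(paste0(one, collapse = ""), id = chain)
  if (length(subs)) attr(seq, "substitutions") <- "MSE read as M"
  seq
}

#' Protein sequence object
#'
#' @param residues One-letter sequence string (20 canonical codes plus X).
#' @param id Identifier.
#' @return A `protein_sequence` list.
#' @export
protein_sequence <- function(residues, id = "seq") {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA321[1:20], "X"))
  if (length(bad)) stop("invalid residue code(s): ", paste(unique(bad), collapse = ""))
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(">", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  cat(x$residues, "\n")
  invisible(x)
}

as_sequence_string <- function(x) {
  if (inherits(x, "protein_sequence")) x$residues
  else if (is.character(x) && length(x) == 1) protein_sequence(x)$residues
  else stop("expected a protein_sequence or a single sequence string")
}

#' Count point mutations between two equal-length sequences
#'
#' Positional Hamming distance over point-mutation lineages, plus the
#' percentage of the aligned length rounded to the nearest integer (the
#' reporting convention used for designed-binder lineages).
#'
#' @param a,b `protein_sequence` objects or sequence strings of equal length.
#' @return List with `count`, `percent` (rounded), and `positions` (1-based).
#' @export
mutation_count <- function(a, b) {
  sa <- as_sequence_string(a)
  sb <- as_sequence_string(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty sequence")
  if (nchar(sa) != nchar(sb))
    stop("sequence lengths differ (", nchar(sa), " vs ", nchar(sb),
         "); mutation_count is defined on point-mutation lineages only")
  va <- strsplit(sa, "")[[1]]
  vb <- strsplit(sb, "")[[1]]
  pos <- which(va != vb)
  list(count = length(pos),
       percent = round(100 * length(pos) / length(va)),
       positions = pos)
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named list of `protein_sequence` objects.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1, length(lines))
  out <- lapply(seq_along(hdr), function(i) {
    id <- sub("^>\\s*", "", lines[hdr[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    protein_sequence(paste0(lines[(hdr[i] + 1):ends[i]], collapse = ""), id = id)
  })
  stats::setNames(out, vapply(out, function(s) s$id, ""))
}

#' Write sequences to a FASTA file
#' @param seqs List of `protein_sequence` objects (or strings).
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (!inherits(s, "protein_sequence"))
      s <- protein_sequence(s, id = names(seqs)[i] %||% paste0("seq", i))
    writeLines(paste0(">", s$id), con)
    writeLines(substring(s$residues,
                         seq(1, nchar(s$residues), width),
                         pmin(seq(1, nchar(s$residues), width) + width - 1,
                              nchar(s$residues))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Backbone dihedrals of a chain
#'
#' Computes phi, psi and omega per residue from coordinates. `omega[i]` is
#' the CA(i)-C(i)-N(i+1)-CA(i+1) peptide-bond torsion to the following
#' residue and is `NA` for the final residue.
#'
#' @param s A `bh3_structure`.
#' @param chain Chain id.
#' @return data.frame with resno, resid, phi, psi, omega (degrees).
#' @export
backbone_dihedrals <- function(s, chain) {
  rt <- residue_table(s, chain)
  n <- nrow(rt)
  N <- atom_coords(s, chain, "N")
  CA <- atom_coords(s, chain, "CA")
  C <- atom_coords(s, chain, "C")
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && all(is.finite(c(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))))
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n) {
      if (all(is.finite(c(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))))
        psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      if (all(is.finite(c(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ]))))
        omega[i] <- dihedral_angle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
    }
  }
  data.frame(resno = rt$resno, insert = rt$insert, resid = rt$resid,
             phi = phi, psi = psi, omega = omega, stringsAsFactors = FALSE)
}

## Subset a structure to given chains (polymer + their het atoms).
subset_chains <- function(s, chains) {
  a <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  if (!nrow(a)) stop("no atoms in chains: ", paste(chains, collapse = ","))
  new_structure(a, s$metadata)
}

## Merge structures; chain ids must not collide.
merge_structures <- function(...) {
  parts <- list(...)
  ids <- unlist(lapply(parts, chain_ids, polymer = FALSE))
  if (anyDuplicated(ids))
    stop("chain id collision on merge: ", paste(unique(ids[duplicated(ids)]), collapse = ","))
  new_structure(do.call(rbind, lapply(parts, function(p) p$atoms)),
                metadata = parts[[1]]$metadata)
}
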