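#' Protein chain structure table
#'
#' A `cp_structure` holds one protein chain as an ordered per-residue table
#' plus a heavy-atom table. Residues are renumbered 1..n (`seq_position`,
#' gap-free) regardless of author numbering; the author numbering
#' (`resno` + `icode`) is retained for traceability. Every residue is
#' guaranteed to have a C-alpha atom.
#'
#' @param protein_id identifier for the protein
#' @param chain_id chain identifier
#' @param residues data.frame with one row per residue: `seq_position`,
#'   `resno`, `icode`, `aa` (one-letter), `x`, `y`, `z` (C-alpha, Angstrom),
#'   `b_factor_ca`, `sse8`, `phi`, `psi`
#' @param atoms data.frame of heavy atoms: `seq_position`, `elety` (atom
#'   name), `elesy` (element), `x`, `y`, `z`, `o` (occupancy), `b`
#' @param source_path origin of the data (file path or a tag)
#' @return object of class `cp_structure`
#' @export
cp_structure <- function(protein_id, chain_id, residues, atoms,
                         source_path = NA_character_) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  if (nrow(residues) < 2L) {
    stop("a cp_structure needs at least 2 residues")
  }
  key <- paste(residues$resno, residues$icode)
  if (anyDuplicated(key)) {
    stop("duplicated (resno, icode) pairs in residue table")
  }
  if (!identical(residues$seq_position, seq_len(nrow(residues)))) {
    stop("seq_position must be the contiguous sequence 1..n")
  }
  structure(
    list(protein_id = protein_id, chain_id = chain_id,
         residues = residues, atoms = atoms, source_path = source_path),
    class = "cp_structure"
  )
}

#' @export
print.cp_structure <- function(x, ...) {
  cat(sprintf("cp_structure: %s chain %s, %d residues, %d heavy atoms\n",
              x$protein_id, x$chain_id, nrow(x$residues), nrow(x$atoms)))
  cat(sprintf("sequence: %s\n", structure_sequence(x)))
  invisible(x)
}

n_residues <- function(structure) nrow(structure$residues)

ca_coords <- function(structure) {
  as.matrix(structure$residues[, c("x", "y", "z")])
}

#' Chain sequence as a one-letter string
#' @param structure a [cp_structure]
#' @return single character string
#' @export
structure_sequence <- function(structure) {
  paste(structure$residues$aa, collapse = "")
}

#' Read a protein chain from a PDB file or text
#'
#' Parses ATOM records (via bio3d), selects one chain and one model, resolves
#' alternate locations to the highest-occupancy conformer, drops waters,
#' hetero ligands and hydrogens, and renumbers residues contiguously.
#' Residues lacking a C-alpha are dropped with a warning. Backbone dihedrals
#' and a dihedral-based secondary structure fallback are filled in; supply
#' DSSP output to [assign_sse()] for the full 8-state assignment.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines
#' @param chain_id chain to extract; required when the file has several chains
#' @param model_index model to use for multi-model (e.g. NMR) files; only a
#'   single model is ever analysed
#' @param protein_id identifier; defaults to the file base name
#' @return a [cp_structure]
#' @export
read_structure <- function(pdb, chain_id = NULL, model_index = 1L,
                           protein_id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  parsed <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                            verbose = FALSE)
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in input")
  if (model_index > 1L) {
    xyz <- parsed$xyz
    if (nrow(xyz) < model_index) {
      stop(sprintf("model %d requested but file has %d model(s)",
                   model_index, nrow(xyz)))
    }
    m <- matrix(xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- m[at$eleno, 1]; at$y <- m[at$eleno, 2]; at$z <- m[at$eleno, 3]
  }
  chains <- unique(at$chain)
  if (is.null(chain_id)) {
    if (length(chains) > 1L) {
      stop(sprintf("file has several chains (%s); specify chain_id",
                   paste(chains, collapse = ", ")))
    }
    chain_id <- chains
  }
  if (!chain_id %in% chains) {
    stop(sprintf("chain %s not found; available chains: %s",
                 chain_id, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain_id, , drop = FALSE]
  # drop hydrogens; everything in this package is heavy-atom based
  elesy <- at$elesy
  guess <- is.na(elesy) | elesy == ""
  elesy[guess] <- substr(gsub("[^A-Za-z].*$", "", at$elety[guess]), 1, 1)
  at$elesy <- toupper(elesy)
  at <- at[at$elesy != "H" & at$elesy != "D", , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  # altloc: keep highest occupancy per (residue, atom name); ties -> first
  at$o[is.na(at$o)] <- 1
  rid <- paste(at$resno, at$insert, at$elety)
  ord <- order(match(rid, unique(rid)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]

  res_key <- paste(at$resno, at$insert)
  res_order <- unique(res_key)
  has_ca <- vapply(res_order, function(k) {
    any(at$elety[res_key == k] == "CA")
  }, logical(1))
  if (any(!has_ca)) {
    warning(sprintf("dropping %d residue(s) without a C-alpha atom: %s",
                    sum(!has_ca),
                    paste(res_order[!has_ca], collapse = ", ")))
    keep <- res_key %in% res_order[has_ca]
    at <- at[keep, , drop = FALSE]
    res_key <- res_key[keep]
    res_order <- res_order[has_ca]
  }
  if (length(res_order) < 2L) stop("fewer than 2 usable residues in chain")
  seq_position <- match(res_key, res_order)

  ca_rows <- at[at$elety == "CA", , drop = FALSE]
  ca_rows <- ca_rows[order(match(paste(ca_rows$resno, ca_rows$insert),
                                 res_order)), , drop = FALSE]
  aa1 <- bio3d::aa321(ca_rows$resid)
  aa1[is.na(aa1) | !aa1 %in% AA_ALPHABET] <- "X"

  residues <- data.frame(
    seq_position = seq_along(res_order),
    resno = ca_rows$resno,
    icode = ca_rows$insert,
    aa = aa1,
    x = ca_rows$x, y = ca_rows$y, z = ca_rows$z,
    b_factor_ca = ca_rows$b,
    sse8 = "-", phi = NA_real_, psi = NA_real_,
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    seq_position = seq_position,
    elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z,
    o = at$o, b = at$b,
    stringsAsFactors = FALSE
  )
  st <- cp_structure(protein_id, chain_id, residues, atoms,
                     source_path = path)
  st <- compute_dihedrals(st)
  st$residues$sse8 <- sse_fallback(st)
  st
}

#' Write a structure back to PDB text
#'
#' @param structure a [cp_structure]
#' @param path output file; when `NULL` the PDB lines are returned
#' @return invisibly, the path or the text lines
#' @export
write_structure <- function(structure, path = NULL) {
  at <- structure$atoms
  res <- structure$residues
  resno <- res$resno[at$seq_position]
  aa3 <- bio3d::aa123(res$aa[at$seq_position])
  aa3[is.na(aa3)] <- "UNK"
  out <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  bio3d::write.pdb(
    file = out,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = resno, resid = aa3,
    eleno = seq_len(nrow(at)), elety = at$elety,
    chain = rep(structure$chain_id, nrow(at)),
    insert = res$icode[at$seq_position],
    o = at$o, b = at$b, elesy = at$elesy
  )
  if (is.null(path)) {
    lines <- readLines(out)
    unlink(out)
    return(invisible(lines))
  }
  invisible(out)
}

#' Compute backbone phi/psi dihedrals
#'
#' Standard IUPAC convention; undefined (NA) at chain termini or where a
#' backbone atom (N, CA, C) is missing.
#'
#' @param structure a [cp_structure]
#' @return the structure with `phi`, `psi` columns filled in
#' @export
compute_dihedrals <- function(structure) {
  n <- n_residues(structure)
  at <- structure$atoms
  bb <- function(i, name) {
    row <- which(at$seq_position == i & at$elety == name)
    if (length(row) == 0L) return(NULL)
    as.numeric(at[row[1], c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- bb(i, "N"); CAi <- bb(i, "CA"); Ci <- bb(i, "C")
    if (i > 1L) {
      Cp <- bb(i - 1L, "C")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
        phi[i] <- dihedral_angle(Cp, Ni, CAi, Ci)
      }
    }
    if (i < n) {
      Nn <- bb(i + 1L, "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn)) {
        psi[i] <- dihedral_angle(Ni, CAi, Ci, Nn)
      }
    }
  }
  structure$residues$phi <- phi
  structure$residues$psi <- psi
  structure
}

# Dihedral-window fallback assigner: H / E / '-' only. An approximation,
# overridable by supplying DSSP output to assign_sse().
sse_fallback <- function(structure) {
  phi <- structure$residues$phi
  psi <- structure$residues$psi
  sse <- rep("-", n_residues(structure))
  h <- !is.na(phi) & !is.na(psi) &
    phi > -100 & phi < -30 & psi > -80 & psi < -5
  e <- !is.na(phi) & !is.na(psi) &
    phi > -180 & phi < -60 & psi > 60 & psi <= 180
  sse[e] <- "E"
  sse[h] <- "H"
  sse
}

#' Assign 8-state secondary structure codes
#'
#' When DSSP output text is supplied its 8-state summary column is ingested
#' verbatim (blank becomes `-`). Without DSSP, an internal dihedral-window
#' fallback assigns `H`, `E` or `-` only.
#'
#' @param structure a [cp_structure]
#' @param dssp_text DSSP output as a file path or character vector of lines,
#'   or `NULL` for the fallback
#' @return the structure with the `sse8` column set
#' @export
assign_sse <- function(structure, dssp_text = NULL) {
  if (is.null(dssp_text)) {
    structure$residues$sse8 <- sse_fallback(structure)
    return(structure)
  }
  dssp <- parse_dssp(dssp_text)
  dssp <- dssp[dssp$chain == structure$chain_id, , drop = FALSE]
  key_st <- paste(structure$residues$resno,
                  ifelse(structure$residues$icode == "", " ",
                         structure$residues$icode))
  key_dssp <- paste(dssp$resno, dssp$icode)
  idx <- match(key_st, key_dssp)
  if (anyNA(idx)) {
    miss <- structure$residues$seq_position[is.na(idx)]
    stop(sprintf("DSSP/structure residue mismatch at seq_position(s): %s",
                 paste(miss, collapse = ", ")))
  }
  structure$residues$sse8 <- dssp$sse[idx]
  structure
}

# Classic fixed-column DSSP dialect: data lines follow the '  #  RESIDUE'
# header; author residue number in cols 6-10, insertion code col 11, chain
# col 12, 8-state code col 17. Chain-break rows ('!') are skipped.
parse_dssp <- function(dssp_text) {
  lines <- if (length(dssp_text) == 1L && !grepl("\n", dssp_text) &&
               file.exists(dssp_text)) {
    readLines(dssp_text)
  } else {
    unlist(strsplit(paste(dssp_text, collapse = "\n"), "\n"))
  }
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not DSSP output: header line not found")
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  resno <- as.integer(substr(body, 6, 10))
  icode <- substr(body, 11, 11)
  chain <- sub(" ", "", substr(body, 12, 12))
  sse <- substr(body, 17, 17)
  sse[sse == " "] <- "-"
  data.frame(resno = resno, icode = icode, chain = chain, sse = sse,
             stringsAsFactors = FALSE)
}

#' Read a circular-permutation site label table
#'
#' Expects tab-separated text with a header row and columns `protein_id`,
#' `chain`, `position`, `viability` (tokens `viable` / `inviable`). The
#' position is the 1-based `seq_position` of the first residue of the
#' permuted sequence; position 1 is rejected (the identity permutation).
#'
#' @param tsv path or character vector of TSV lines
#' @param structure optional [cp_structure] to validate positions against
#' @return data.frame with `protein_id`, `chain_id`, `site_position`,
#'   `viable` (logical), `source`
#' @export
read_cp_labels <- function(tsv, structure = NULL) {
  txt <- if (length(tsv) == 1L && !grepl("\n", tsv) && file.exists(tsv)) {
    readLines(tsv)
  } else {
    unlist(strsplit(paste(tsv, collapse = "\n"), "\n"))
  }
  txt <- txt[!startsWith(txt, "#")]
  df <- utils::read.delim(text = paste(txt, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "chain", "position", "viability")
  if (!all(need %in% names(df))) {
    stop(sprintf("label table must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  bad_tok <- setdiff(unique(df$viability), c("viable", "inviable"))
  if (length(bad_tok) > 0L) {
    stop(sprintf("unknown viability token(s): %s",
                 paste(bad_tok, collapse = ", ")))
  }
  if (any(df$position <= 1L)) {
    stop("site position 1 is the identity permutation; positions must be > 1")
  }
  if (!is.null(structure)) {
    n <- n_residues(structure)
    sel <- df$protein_id == structure$protein_id
    if (any(df$position[sel] > n)) {
      stop(sprintf("site position(s) beyond chain length %d: %s", n,
                   paste(df$position[sel][df$position[sel] > n],
                         collapse = ", ")))
    }
  }
  data.frame(
    protein_id = df$protein_id,
    chain_id = df$chain,
    site_position = as.integer(df$position),
    viable = df$viability == "viable",
    source = if ("source" %in% names(df)) df$source else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write CP-site labels as TSV text
#' @param labels data.frame as returned by [read_cp_labels()]
#' @param path output file, or `NULL` to return the lines
#' @export
write_cp_labels <- function(labels, path = NULL) {
  df <- data.frame(
    protein_id = labels$protein_id,
    chain = labels$chain_id,
    position = labels$site_position,
    viability = ifelse(labels$viable, "viable", "inviable")
  )
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Export the chain sequence as FASTA
#' @param structure a [cp_structure]
#' @param path output file
#' @export
export_fasta <- function(structure, path) {
  seqinr::write.fasta(
    sequences = strsplit(structure_sequence(structure), "")[[1]],
    names = sprintf("%s_%s", structure$protein_id, structure$chain_id),
    file.out = path
  )
  invisible(path)
}
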