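# PDB-format reading and writing, plus the structural data model shared by
# the rest of the package.
#
# A `pep_structure` is a list with:
#   pdb_id, chain_id : identifiers
#   residues         : data.frame (res_index, name, seq_id, icode,
#                      is_standard, mapped_name)
#   atoms            : data.frame (res_index, atom, element, x, y, z,
#                      occupancy)
#   resolution       : Angstrom, or NA when the header carries none
#   ssbond           : list of sorted integer pairs (res_index positions)
#                      declared by SSBOND records

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

cyc_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

substr_trim <- function(x, start, stop) {
  trimws(substr(x, start, min(stop, nchar(x))))
}

parse_num_field <- function(x, start, stop, lineno, what) {
  s <- substr_trim(x, start, stop)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    cyc_error("cycpep_parse_error",
              sprintf("malformed ATOM record at line %d: non-numeric %s field '%s'",
                      lineno, what, s))
  v
}

#' Parse a protein chain from PDB-format text
#'
#' Reads ATOM/HETATM records for one chain (first MODEL only), resolving
#' alternate locations to the highest-occupancy conformer (ties broken by the
#' alphabetically first altloc), dropping hydrogens and non-polymer hetero
#' groups (residues without a CA atom).  The crystallographic resolution is
#' taken from REMARK 2 when present, SSBOND records are kept as disulfide
#' candidates, and MODRES annotations provide the mapping of modified
#' residues to their standard parent.
#'
#' @param pdb_text A single string or character vector of PDB lines.
#' @param chain_id One-character chain identifier.
#' @param pdb_id Optional identifier; defaults to the HEADER id or "XXXX".
#' @return A `pep_structure` object.
#' @export
parse_structure <- function(pdb_text, chain_id, pdb_id = NULL) {
  if (length(pdb_text) == 1 && grepl("\n", pdb_text))
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  lines <- pdb_text
  if (!is.character(chain_id) || nchar(chain_id) != 1)
    stop("chain_id must be a single character")

  rec <- substr(lines, 1, 6)

  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  endmdl <- which(trimws(rec) == "ENDMDL")
  atom_ok <- rep(TRUE, length(lines))
  if (length(model_starts) > 0 && length(endmdl) > 0)
    atom_ok[(endmdl[1] + 1):length(lines)] <- FALSE

  if (is.null(pdb_id)) {
    hdr <- lines[rec == "HEADER"]
    pdb_id <- if (length(hdr) > 0 && nchar(hdr[1]) >= 66)
      substr_trim(hdr[1], 63, 66) else "XXXX"
    if (!nzchar(pdb_id)) pdb_id <- "XXXX"
  }

  resolution <- NA_real_
  rem2 <- lines[rec == "REMARK" & grepl("^REMARK   2 RESOLUTION", lines)]
  if (length(rem2) > 0) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m) == 1) resolution <- as.numeric(m)
  }

  # MODRES: (chain, seq, icode) -> standard parent name
  modres <- list()
  for (ln in lines[rec == "MODRES"]) {
    ch <- substr_trim(ln, 17, 17)
    if (ch != chain_id) next
    seq <- suppressWarnings(as.integer(substr_trim(ln, 19, 22)))
    ic <- substr_trim(ln, 23, 23)
    std <- substr_trim(ln, 25, 27)
    if (!is.na(seq) && std %in% STANDARD_AA)
      modres[[paste0(seq, "|", ic)]] <- std
  }

  # SSBOND candidates within this chain
  ss_raw <- list()
  for (ln in lines[rec == "SSBOND"]) {
    ch1 <- substr_trim(ln, 16, 16)
    ch2 <- substr_trim(ln, 30, 30)
    if (ch1 != chain_id || ch2 != chain_id) next
    s1 <- suppressWarnings(as.integer(substr_trim(ln, 18, 21)))
    s2 <- suppressWarnings(as.integer(substr_trim(ln, 32, 35)))
    i1 <- substr_trim(ln, 22, 22)
    i2 <- substr_trim(ln, 36, 36)
    if (!is.na(s1) && !is.na(s2))
      ss_raw[[length(ss_raw) + 1]] <- list(a = c(s1, i1), b = c(s2, i2))
  }

  is_atom <- (rec == "ATOM  " | rec == "HETATM") & atom_ok
  idx <- which(is_atom)
  rows <- vector("list", length(idx))
  k <- 0
  for (i in idx) {
    ln <- lines[i]
    if (substr_trim(ln, 22, 22) != chain_id) next
    if (nchar(ln) < 54)
      cyc_error("cycpep_parse_error",
                sprintf("malformed ATOM record at line %d: line too short", i))
    name <- substr_trim(ln, 13, 16)
    if (!nzchar(name))
      cyc_error("cycpep_parse_error",
                sprintf("malformed ATOM record at line %d: empty atom name", i))
    altloc <- substr_trim(ln, 17, 17)
    res_name <- substr_trim(ln, 18, 20)
    seq_id <- suppressWarnings(as.integer(substr_trim(ln, 23, 26)))
    if (is.na(seq_id))
      cyc_error("cycpep_parse_error",
                sprintf("malformed ATOM record at line %d: bad residue number", i))
    icode <- substr_trim(ln, 27, 27)
    x <- parse_num_field(ln, 31, 38, i, "x")
    y <- parse_num_field(ln, 39, 46, i, "y")
    z <- parse_num_field(ln, 47, 54, i, "z")
    occ <- if (nchar(ln) >= 60) suppressWarnings(as.numeric(substr_trim(ln, 55, 60))) else NA
    if (is.na(occ)) occ <- 1.0
    elem <- if (nchar(ln) >= 78) substr_trim(ln, 77, 78) else ""
    if (!nzchar(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
    if (toupper(elem) %in% c("H", "D")) next
    het <- rec[i] == "HETATM"
    k <- k + 1
    rows[[k]] <- data.frame(name = name, altloc = altloc, res_name = res_name,
                            seq_id = seq_id, icode = icode, x = x, y = y, z = z,
                            occupancy = occ, element = toupper(elem), het = het,
                            stringsAsFactors = FALSE)
  }
  if (k == 0)
    cyc_error("cycpep_not_found",
              sprintf("chain '%s' not found in PDB text", chain_id))
  at <- do.call(rbind, rows[seq_len(k)])
  if (any(at$res_name == "HOH")) at <- at[at$res_name != "HOH", , drop = FALSE]

  # order residues by (seq_id, icode); "" sorts before insertion letters
  rkey <- paste0(at$seq_id, "|", at$icode)
  ukey <- unique(rkey)
  useq <- as.integer(sub("\\|.*$", "", ukey))
  uic <- sub("^.*\\|", "", ukey)
  ord <- order(useq, uic)
  ukey <- ukey[ord]

  res_rows <- list()
  atom_rows <- list()
  for (ri in seq_along(ukey)) {
    sub <- at[rkey == ukey[ri], , drop = FALSE]
    if (!"CA" %in% sub$name) next  # non-polymer hetero group
    # altloc resolution per atom name: max occupancy, then first altloc;
    # surviving atoms keep their original file order
    ord0 <- seq_len(nrow(sub))
    pick <- order(sub$name, -sub$occupancy, sub$altloc)
    keep <- pick[!duplicated(sub$name[pick])]
    sub <- sub[sort(ord0[keep]), , drop = FALSE]
    res_name <- sub$res_name[1]
    is_std <- res_name %in% STANDARD_AA
    mkey <- paste0(sub$seq_id[1], "|", sub$icode[1])
    mapped <- if (!is_std && !is.null(modres[[mkey]])) modres[[mkey]] else NA_character_
    ri_new <- length(res_rows) + 1L
    res_rows[[ri_new]] <- data.frame(
      res_index = ri_new, name = res_name, seq_id = sub$seq_id[1],
      icode = sub$icode[1], is_standard = is_std, mapped_name = mapped,
      stringsAsFactors = FALSE)
    atom_rows[[ri_new]] <- data.frame(
      res_index = ri_new, atom = sub$name, element = sub$element,
      x = sub$x, y = sub$y, z = sub$z, occupancy = sub$occupancy,
      stringsAsFactors = FALSE)
  }
  if (length(res_rows) == 0)
    cyc_error("cycpep_not_found",
              sprintf("chain '%s' has no polymer residues", chain_id))
  residues <- do.call(rbind, res_rows)
  atoms <- do.call(rbind, atom_rows)

  # map SSBOND (seq, icode) pairs to residue positions; keep CYS pairs only
  pos_of <- function(si) {
    w <- which(residues$seq_id == as.integer(si[1]) & residues$icode == si[2])
    if (length(w) == 1) w else NA_integer_
  }
  ssbond <- list()
  for (p in ss_raw) {
    i1 <- pos_of(p$a); i2 <- pos_of(p$b)
    if (is.na(i1) || is.na(i2) || i1 == i2) next
    if (effective_resname(residues, i1) != "CYS") next
    if (effective_resname(residues, i2) != "CYS") next
    ssbond[[length(ssbond) + 1]] <- sort(c(i1, i2))
  }
  ssbond <- unique(ssbond)

  structure(list(pdb_id = pdb_id, chain_id = chain_id, residues = residues,
                 atoms = atoms, resolution = resolution, ssbond = ssbond),
            class = "pep_structure")
}

# residue name after MODRES mapping
effective_resname <- function(residues, i) {
  if (!is.na(residues$mapped_name[i])) residues$mapped_name[i] else residues$name[i]
}

#' @export
print.pep_structure <- function(x, ...) {
  cat(sprintf("<pep_structure> %s chain %s: %d residues, %d atoms, resolution %s\n",
              x$pdb_id, x$chain_id, nrow(x$residues), nrow(x$atoms),
              ifelse(is.na(x$resolution), "NA", sprintf("%.2f A", x$resolution))))
  invisible(x)
}

# coordinates of one named atom in residue `res_index`, or NULL
atom_coord <- function(s, res_index, name) {
  a <- s$atoms
  w <- which(a$res_index == res_index & a$atom == name)
  if (length(w) == 0) return(NULL)
  c(a$x[w[1]], a$y[w[1]], a$z[w[1]])
}

#' Backbone completeness per residue
#' @param structure a `pep_structure`.
#' @return Logical vector, TRUE where the residue has all of N, CA, C, O.
#' @export
backbone_complete <- function(structure) {
  vapply(seq_len(nrow(structure$residues)), function(i) {
    nm <- structure$atoms$atom[structure$atoms$res_index == i]
    all(BACKBONE_ATOMS %in% nm)
  }, logical(1))
}

#' Detect disulfide bonds in a parsed chain
#'
#' Returns the union of SSBOND-declared cysteine pairs and CYS pairs whose
#' SG-SG distance is at most `max_dist` (2.5 Angstrom by default, covering the
#' ~2.05 Angstrom bond plus refinement noise).  Each cysteine appears in at
#' most one pair; conflicting distance candidates are resolved closest-first.
#' Cysteines lacking an SG atom are excluded from the distance search.
#'
#' @param structure a `pep_structure`.
#' @param max_dist SG-SG distance threshold in Angstrom.
#' @return List of sorted integer pairs (1-based residue positions).
#' @export
detect_disulfides <- function(structure, max_dist = 2.5) {
  res <- structure$residues
  cys <- which(vapply(seq_len(nrow(res)), function(i)
    effective_resname(res, i) == "CYS", logical(1)))
  used <- integer(0)
  pairs <- list()
  for (p in structure$ssbond) {
    if (any(p %in% used)) next
    pairs[[length(pairs) + 1]] <- p
    used <- c(used, p)
  }
  sg <- lapply(cys, function(i) atom_coord(structure, i, "SG"))
  has_sg <- !vapply(sg, is.null, logical(1))
  cys <- cys[has_sg]
  sg <- sg[has_sg]
  if (length(cys) >= 2) {
    cand <- list()
    for (a in seq_along(cys)) for (b in seq_along(cys)) {
      if (a >= b) next
      d <- vnorm(sg[[a]] - sg[[b]])
      if (d <= max_dist)
        cand[[length(cand) + 1]] <- list(pair = c(cys[a], cys[b]), d = d)
    }
    if (length(cand) > 0) {
      cand <- cand[order(vapply(cand, function(z) z$d, numeric(1)))]
      for (z in cand) {
        if (any(z$pair %in% used)) next
        pairs[[length(pairs) + 1]] <- sort(z$pair)
        used <- c(used, z$pair)
      }
    }
  }
  if (length(pairs) == 0) return(list())
  pairs <- lapply(pairs, as.integer)
  ord <- order(vapply(pairs, `[`, integer(1), 1), vapply(pairs, `[`, integer(1), 2))
  pairs[ord]
}

fmt_atom_line <- function(serial, name, res_name, chain, seq_id, icode,
                          x, y, z, occ, element) {
  if (nchar(name) > 4) cyc_error("cycpep_format_error",
                                 paste0("atom name longer than 4 characters: ", name))
  # standard PDB alignment: 1-3 char names start in column 14
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, res_name, chain, seq_id,
          ifelse(nzchar(icode), icode, " "), x, y, z, occ, 0, element)
}

#' Serialize a structure or model to PDB-format text
#'
#' Emits REMARK 2 (when a resolution is known), SSBOND records for annotated
#' disulfides, fixed-column ATOM records with three-decimal coordinates, TER
#' and END.  `parse_structure(write_structure(x))` preserves residue names,
#' numbering, atom names and coordinates to 0.001 Angstrom.
#'
#' @param x a `pep_structure` or `pep_model`.
#' @return Character vector of PDB lines.
#' @export
write_structure <- function(x) {
  if (inherits(x, "pep_model")) x <- model_as_structure(x)
  if (!inherits(x, "pep_structure")) stop("x must be a pep_structure or pep_model")
  if (!all(is.finite(c(x$atoms$x, x$atoms$y, x$atoms$z))))
    stop("all atom coordinates must be finite")
  out <- character(0)
  out <- c(out, sprintf("HEADER    CYCLIC PEPTIDE                          01-JAN-00   %-4s", x$pdb_id))
  if (!is.na(x$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", x$resolution))
  res <- x$residues
  si <- 0
  for (p in x$ssbond) {
    si <- si + 1
    out <- c(out, sprintf("SSBOND %3d CYS %s %4d%1s   CYS %s %4d%1s",
                          si, x$chain_id, res$seq_id[p[1]],
                          ifelse(nzchar(res$icode[p[1]]), res$icode[p[1]], " "),
                          x$chain_id, res$seq_id[p[2]],
                          ifelse(nzchar(res$icode[p[2]]), res$icode[p[2]], " ")))
  }
  serial <- 0
  for (i in seq_len(nrow(res))) {
    a <- x$atoms[x$atoms$res_index == i, , drop = FALSE]
    for (j in seq_len(nrow(a))) {
      serial <- serial + 1
      out <- c(out, fmt_atom_line(serial, a$atom[j], res$name[i], x$chain_id,
                                  res$seq_id[i], res$icode[i],
                                  a$x[j], a$y[j], a$z[j],
                                  if (is.null(a$occupancy)) 1 else a$occupancy[j],
                                  a$element[j]))
    }
  }
  c(out, "TER", "END")
}

#' One-letter sequence of a parsed chain
#' @param structure a `pep_structure`.
#' @return One-letter string (modified residues use their mapped parent;
#'   unmapped nonstandard residues become "X").
#' @export
structure_sequence <- function(structure) {
  res <- structure$residues
  letters1 <- vapply(seq_len(nrow(res)), function(i) {
    nm <- effective_resname(res, i)
    v <- aa_three_to_one(nm)
    if (is.na(v)) "X" else v
  }, character(1))
  paste(letters1, collapse = "")
}
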