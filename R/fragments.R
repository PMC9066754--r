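# Cyclic backbone fragment extraction, length-dependent clustering, and the
# backbone library container.
#
# A `cyclic_fragment` is a list with:
#   length      : residue count of the cyclic span (3..30)
#   sequence    : one-letter string (modified residues mapped to parents)
#   bb          : (4*length) x 3 matrix, rows N, CA, C, O per residue
#   cys_first, cys_last : matrices of the terminal cysteines' side-chain
#                 heavy atoms (rownames CB, SG)
#   source_pdb, source_chain, source_span, resolution

fragment_atom_order <- function(n) rep(BACKBONE_ATOMS, n)

new_cyclic_fragment <- function(length, sequence, bb, cys_first, cys_last,
                                source_pdb, source_chain, source_span,
                                resolution) {
  structure(list(length = length, sequence = sequence, bb = bb,
                 cys_first = cys_first, cys_last = cys_last,
                 source_pdb = source_pdb, source_chain = source_chain,
                 source_span = source_span, resolution = resolution),
            class = "cyclic_fragment")
}

#' @export
print.cyclic_fragment <- function(x, ...) {
  cat(sprintf("<cyclic_fragment> %s/%s %d-%d: n_cyc=%d seq=%s\n",
              x$source_pdb, x$source_chain, x$source_span[1], x$source_span[2],
              x$length, x$sequence))
  invisible(x)
}

validate_cyclic_fragment <- function(f, max_ss = 2.5) {
  stopifnot(inherits(f, "cyclic_fragment"))
  n <- f$length
  if (n < 3 || n > 30) stop("cyclic fragment length outside [3, 30]")
  if (nchar(f$sequence) != n) stop("sequence length does not match fragment length")
  if (substr(f$sequence, 1, 1) != "C" || substr(f$sequence, n, n) != "C")
    stop("fragment endpoints must be cysteine")
  if (grepl("C", substr(f$sequence, 2, n - 1), fixed = TRUE))
    stop("fragment has an interior cysteine")
  if (nrow(f$bb) != 4 * n || !all(is.finite(f$bb)))
    stop("fragment backbone must be a complete finite (4n x 3) matrix")
  for (m in list(f$cys_first, f$cys_last))
    if (!all(c("CB", "SG") %in% rownames(m)))
      stop("terminal cysteines must carry CB and SG")
  d <- vnorm(f$cys_first["SG", ] - f$cys_last["SG", ])
  if (d > max_ss) stop(sprintf("SG-SG distance %.2f exceeds %.2f A", d, max_ss))
  invisible(TRUE)
}

#' Extract disulfide-closed cyclic backbone fragments from a structure
#'
#' For every detected disulfide pair (i, j) the span i..j becomes a fragment
#' iff no other cysteine lies strictly inside it, its length is within
#' \[3, 30\], every residue has a complete backbone (N, CA, C, O), and both
#' terminal cysteines carry CB and SG.  Modified residues with a MODRES
#' mapping are renamed to their standard parent; unmapped nonstandard
#' residues disqualify the span.  Non-qualifying spans are skipped with a
#' reason code recorded in the `"skipped"` attribute.
#'
#' @param structure a `pep_structure`.
#' @param min_len,max_len allowed cyclic-span lengths.
#' @return List of `cyclic_fragment` objects (possibly empty).
#' @export
extract_cyclic_fragments <- function(structure, min_len = 3, max_len = 30) {
  pairs <- detect_disulfides(structure)
  res <- structure$residues
  complete <- backbone_complete(structure)
  frags <- list()
  skipped <- data.frame(from = integer(0), to = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  skip <- function(i, j, why) {
    skipped[nrow(skipped) + 1, ] <<- list(i, j, why)
  }
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    n <- j - i + 1
    span <- i:j
    eff <- vapply(span, function(k) effective_resname(res, k), character(1))
    if (n < min_len || n > max_len) { skip(i, j, "length"); next }
    if (any(eff[-c(1, n)] == "CYS")) { skip(i, j, "interior_cys"); next }
    if (!all(eff %in% STANDARD_AA)) { skip(i, j, "unmapped_nonstandard"); next }
    if (!all(complete[span])) { skip(i, j, "incomplete_backbone"); next }
    cys_sc <- lapply(c(i, j), function(k) {
      a <- structure$atoms[structure$atoms$res_index == k, , drop = FALSE]
      a <- a[!a$atom %in% BACKBONE_ATOMS & a$element != "H", , drop = FALSE]
      m <- as.matrix(a[, c("x", "y", "z")])
      rownames(m) <- a$atom
      m
    })
    if (!all(c("CB", "SG") %in% rownames(cys_sc[[1]])) ||
        !all(c("CB", "SG") %in% rownames(cys_sc[[2]]))) {
      skip(i, j, "cys_missing_sidechain"); next
    }
    if (vnorm(cys_sc[[1]]["SG", ] - cys_sc[[2]]["SG", ]) > 2.5) {
      skip(i, j, "sg_distance"); next
    }
    bb <- do.call(rbind, lapply(span, function(k) {
      do.call(rbind, lapply(BACKBONE_ATOMS, function(nm) atom_coord(structure, k, nm)))
    }))
    frag <- new_cyclic_fragment(
      length = n,
      sequence = paste(aa_three_to_one(eff), collapse = ""),
      bb = bb, cys_first = cys_sc[[1]], cys_last = cys_sc[[2]],
      source_pdb = structure$pdb_id, source_chain = structure$chain_id,
      source_span = c(res$seq_id[i], res$seq_id[j]),
      resolution = structure$resolution)
    validate_cyclic_fragment(frag)
    frags[[length(frags) + 1]] <- frag
  }
  attr(frags, "skipped") <- skipped
  frags
}

#' Length-dependent clustering cutoff
#'
#' The backbone-RMSD cutoff used when clustering cyclic fragments of length
#' `n_cyc`: 0.1 * sqrt(n_cyc) Angstrom, i.e. 0.17 A at length 3 up to 0.55 A
#' at length 30 (two-decimal rounding).  Longer fragments get a larger cutoff
#' to compensate for RMSD growing with size.
#'
#' @param n_cyc integer cyclic-fragment length in \[3, 30\].
#' @return Cutoff in Angstrom (unrounded).
#' @export
cluster_cutoff <- function(n_cyc) {
  if (!is.numeric(n_cyc) || any(n_cyc != round(n_cyc)) ||
      any(n_cyc < 3) || any(n_cyc > 30))
    cyc_error("cycpep_domain_error", "n_cyc must be an integer in [3, 30]")
  0.1 * sqrt(n_cyc)
}

# backbone RMSD between two same-length fragments after optimal superposition
fragment_brmsd <- function(fa, fb) {
  if (fa$length != fb$length) cyc_error("cycpep_domain_error",
                                        "fragments differ in length")
  superposed_rmsd(fa$bb, fb$bb)
}

fragment_order_key <- function(fragments, default_resolution = 3.0) {
  resv <- vapply(fragments, function(f)
    ifelse(is.na(f$resolution), default_resolution, f$resolution), numeric(1))
  pdb <- vapply(fragments, function(f) f$source_pdb, character(1))
  span <- vapply(fragments, function(f) f$source_span[1], numeric(1))
  order(resv, pdb, span)
}

#' Cluster same-length fragments by backbone RMSD
#'
#' Deterministic greedy leader clustering: fragments are visited in a fixed
#' order (ascending resolution, ties by source id then span start); each
#' fragment joins the first existing cluster whose leader is within `cutoff`
#' backbone RMSD (computed after optimal superposition over all 4n backbone
#' atoms), otherwise it founds a new cluster.  The representative of each
#' cluster is its centroid: the member minimizing the summed backbone RMSD to
#' all other members, ties broken by the visiting order.
#'
#' @param fragments list of `cyclic_fragment` objects sharing one length.
#' @param cutoff positive RMSD cutoff in Angstrom.
#' @param ordering optional integer permutation overriding the default
#'   visiting order.
#' @return List of clusters, each a list with `length`, `members`
#'   (fragments), `representative` (a member), `leader_index`.
#' @export
cluster_fragments <- function(fragments, cutoff, ordering = NULL) {
  if (length(fragments) == 0) return(list())
  lens <- vapply(fragments, function(f) f$length, numeric(1))
  if (length(unique(lens)) != 1)
    cyc_error("cycpep_domain_error", "all fragments must share one length")
  if (cutoff <= 0) cyc_error("cycpep_domain_error", "cutoff must be positive")
  if (is.null(ordering)) ordering <- fragment_order_key(fragments)
  clusters <- list()   # each: list(leader = frag, member_ids = indices into `fragments`)
  for (fi in ordering) {
    f <- fragments[[fi]]
    joined <- FALSE
    for (ci in seq_along(clusters)) {
      if (fragment_brmsd(clusters[[ci]]$leader, f) <= cutoff) {
        clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, fi)
        joined <- TRUE
        break
      }
    }
    if (!joined)
      clusters[[length(clusters) + 1]] <- list(leader = f, member_ids = fi)
  }
  lapply(clusters, function(cl) {
    members <- fragments[cl$member_ids]
    m <- length(members)
    if (m == 1) {
      rep_i <- 1
    } else {
      dm <- matrix(0, m, m)
      for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        dm[a, b] <- dm[b, a] <- fragment_brmsd(members[[a]], members[[b]])
      }
      sums <- rowSums(dm)
      # members are already in visiting order, so which.min breaks ties by it
      rep_i <- which.min(sums)
    }
    list(length = members[[1]]$length, members = members,
         representative = members[[rep_i]],
         leader_index = cl$member_ids[1])
  })
}

#' Build a length-stratified backbone library
#'
#' Extracts cyclic fragments from every structure, groups them by length and
#' clusters each length with [cluster_cutoff()].  At most 28 sub-libraries
#' (lengths 3 to 30) result.  The build is deterministic for a given input
#' set.
#'
#' @param structures list of `pep_structure` objects.
#' @param min_len,max_len allowed cyclic-span lengths.
#' @return A `backbone_library`: list with `sub_libraries` (named by length,
#'   each a list of clusters) and `provenance`.
#' @export
build_library <- function(structures, min_len = 3, max_len = 30) {
  if (length(structures) < 1) stop("need at least one structure")
  frags <- list()
  for (s in structures)
    frags <- c(frags, extract_cyclic_fragments(s, min_len, max_len))
  if (length(frags) == 0)
    warning("no qualifying cyclic fragments found; library is empty")
  lens <- vapply(frags, function(f) f$length, numeric(1))
  sub <- list()
  for (n in sort(unique(lens))) {
    sub[[as.character(n)]] <-
      cluster_fragments(frags[lens == n], cluster_cutoff(n))
  }
  structure(list(
    sub_libraries = sub,
    provenance = list(
      min_len = min_len, max_len = max_len,
      n_structures = length(structures), n_fragments = length(frags),
      sources = vapply(structures, function(s)
        paste0(s$pdb_id, "_", s$chain_id), character(1)))),
    class = "backbone_library")
}

#' @export
print.backbone_library <- function(x, ...) {
  ns <- vapply(x$sub_libraries, length, integer(1))
  cat(sprintf("<backbone_library> %d sub-libraries, %d clusters total\n",
              length(ns), sum(ns)))
  invisible(x)
}

# convert a fragment to a pep_structure so it can be serialized
fragment_as_structure <- function(f) {
  n <- f$length
  res <- data.frame(res_index = seq_len(n),
                    name = aa_one_to_three(strsplit(f$sequence, "")[[1]]),
                    seq_id = seq_len(n), icode = "",
                    is_standard = TRUE, mapped_name = NA_character_,
                    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    bb <- f$bb[(4 * (i - 1) + 1):(4 * i), , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      res_index = i, atom = BACKBONE_ATOMS,
      element = substr(BACKBONE_ATOMS, 1, 1),
      x = bb[, 1], y = bb[, 2], z = bb[, 3], occupancy = 1,
      stringsAsFactors = FALSE)
    if (i == 1 || i == n) {
      sc <- if (i == 1) f$cys_first else f$cys_last
      rows[[length(rows) + 1]] <- data.frame(
        res_index = i, atom = rownames(sc),
        element = substr(rownames(sc), 1, 1),
        x = sc[, 1], y = sc[, 2], z = sc[, 3], occupancy = 1,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pdb_id = f$source_pdb, chain_id = f$source_chain,
                 residues = res, atoms = do.call(rbind, rows),
                 resolution = if (is.na(f$resolution)) NA_real_ else f$resolution,
                 ssbond = list(c(1L, n))),
            class = "pep_structure")
}

structure_as_fragment <- function(s, source_pdb, source_chain, source_span,
                                  resolution) {
  frs <- extract_cyclic_fragments(s)
  if (length(frs) != 1) stop("stored fragment file does not contain exactly one cyclic fragment")
  f <- frs[[1]]
  f$source_pdb <- source_pdb
  f$source_chain <- source_chain
  f$source_span <- source_span
  f$resolution <- resolution
  f
}

#' Persist / load a backbone library
#'
#' On-disk layout: one PDB file per cluster representative plus a JSON index
#' recording lengths, sequences, resolutions, cluster sizes and provenance.
#' `load_library(save_library(L, path))` reproduces all representative
#' coordinates to 0.001 Angstrom and all metadata; cluster members other than
#' the representative are not persisted.
#'
#' @param library a `backbone_library`.
#' @param path directory to write to / read from.
#' @return `save_library` returns `path` invisibly; `load_library` returns a
#'   `backbone_library`.
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "backbone_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (len in names(library$sub_libraries)) {
    cls <- library$sub_libraries[[len]]
    for (k in seq_along(cls)) {
      f <- cls[[k]]$representative
      file <- sprintf("frag_L%02d_c%03d.pdb", as.integer(len), k)
      writeLines(write_structure(fragment_as_structure(f)), file.path(path, file))
      entries[[length(entries) + 1]] <- list(
        file = file, length = as.integer(len), sequence = f$sequence,
        resolution = if (is.na(f$resolution)) NULL else f$resolution,
        cluster_size = length(cls[[k]]$members),
        source_pdb = f$source_pdb, source_chain = f$source_chain,
        source_span = f$source_span)
    }
  }
  index <- list(format = "cycpepgen-library-1",
                provenance = library$provenance, fragments = entries)
  jsonlite::write_json(index, file.path(path, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  index_file <- file.path(path, "index.json")
  if (!file.exists(index_file))
    cyc_error("cycpep_load_error", paste0("no library index found at ", path))
  index <- tryCatch(jsonlite::read_json(index_file),
                    error = function(e) cyc_error("cycpep_load_error",
                                                  paste0("corrupt index: ", conditionMessage(e))))
  for (key in c("format", "fragments"))
    if (is.null(index[[key]]))
      cyc_error("cycpep_load_error", paste0("corrupt index: missing key '", key, "'"))
  sub <- list()
  for (e in index$fragments) {
    fp <- file.path(path, e$file)
    if (!file.exists(fp))
      cyc_error("cycpep_load_error", paste0("index references missing file: ", e$file))
    s <- parse_structure(readLines(fp), chain_id = e$source_chain)
    f <- structure_as_fragment(
      s, e$source_pdb, e$source_chain,
      as.numeric(unlist(e$source_span)),
      if (is.null(e$resolution)) NA_real_ else as.numeric(e$resolution))
    validate_cyclic_fragment(f)
    if (f$length != e$length)
      cyc_error("cycpep_load_error", paste0("length mismatch for ", e$file))
    key <- as.character(e$length)
    cl <- list(length = f$length, members = list(f), representative = f,
               leader_index = NA_integer_, cluster_size = e$cluster_size)
    sub[[key]] <- c(sub[[key]], list(cl))
  }
  structure(list(sub_libraries = sub, provenance = index$provenance),
            class = "backbone_library")
}

#' Cluster representatives for one cyclic length
#' @param library a `backbone_library`.
#' @param n_cyc cyclic length.
#' @return List of `cyclic_fragment` representatives (possibly empty).
#' @export
sub_library <- function(library, n_cyc) {
  cls <- library$sub_libraries[[as.character(n_cyc)]]
  if (is.null(cls)) return(list())
  lapply(cls, function(cl) cl$representative)
}
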