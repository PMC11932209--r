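STANDARD_NT <- c("A", "C", "G", "U")
PURINES <- c("A", "G", "N")

#' RNA chain record
#'
#' Constructs the internal representation of one RNA chain: its sequence and
#' the per-nucleotide backbone coordinates used to build geometric graphs.
#' The three tracked atoms are the phosphate P, the ribose C4' (whose
#' position defines the node coordinate), and the glycosidic nitrogen (N1
#' for pyrimidines, N9 for purines).
#'
#' @param chain_id chain identifier.
#' @param sequence character scalar over `A,C,G,U,N`.
#' @param P,C4,N numeric L x 3 coordinate matrices (Angstrom); rows of
#'   missing atoms may hold zeros and must be flagged in `atom_ok`.
#' @param residue_numbers integer author residue numbers (metadata only).
#' @param atom_ok logical L x 3 matrix (columns P, C4, N): TRUE where the
#'   atom was observed.
#' @return an object of class `rna_structure`.
#' @export
rna_structure <- function(chain_id, sequence, P, C4, N, residue_numbers = NULL,
                          atom_ok = NULL) {
  seq_chars <- strsplit(sequence, "")[[1]]
  L <- length(seq_chars)
  stopifnot(all(seq_chars %in% c(STANDARD_NT, "N")))
  P <- as.matrix(P); C4 <- as.matrix(C4); N <- as.matrix(N)
  stopifnot(nrow(P) == L, nrow(C4) == L, nrow(N) == L,
            ncol(P) == 3, ncol(C4) == 3, ncol(N) == 3)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(L)
  stopifnot(length(residue_numbers) == L)
  if (is.null(atom_ok)) atom_ok <- matrix(TRUE, L, 3)
  colnames(atom_ok) <- c("P", "C4", "N")
  ok_coords <- rbind(P[atom_ok[, 1], ], C4[atom_ok[, 2], ], N[atom_ok[, 3], ])
  if (length(ok_coords) && !all(is.finite(ok_coords))) {
    stop("non-finite coordinates for atoms flagged as present")
  }
  structure(list(chain_id = chain_id, sequence = sequence, P = P, C4 = C4,
                 N = N, residue_numbers = as.integer(residue_numbers),
                 atom_ok = atom_ok),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  L <- nchar(x$sequence)
  nmiss <- sum(!apply(x$atom_ok, 1, all))
  cat(sprintf("RNA chain %s: %d nt", x$chain_id, L))
  if (nmiss > 0) cat(sprintf(" (%d positions with missing backbone atoms)", nmiss))
  cat("\n", substr(x$sequence, 1, 60), if (L > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.rna_structure <- function(x) nchar(x$sequence)

residue_letter <- function(resid) {
  r <- toupper(trimws(resid))
  if (r %in% STANDARD_NT) r else "N"
}

glyco_atom <- function(letter) if (letter %in% c("C", "U")) "N1" else "N9"

# Shared assembly from a per-atom table (one row per atom) with columns
# chain, resno, ins, resid, atom, x, y, z, occ, alt, model.
assemble_chain <- function(atoms, chain_id) {
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  if (nrow(atoms) == 0L) stop(sprintf("chain '%s' not found", chain_id))
  # first model only
  if (!is.null(atoms$model) && length(unique(atoms$model)) > 1L) {
    atoms <- atoms[atoms$model == atoms$model[1L], , drop = FALSE]
  }
  # residues keep their order of appearance in the file
  file_order <- unique(paste(atoms$resno, atoms$ins, sep = "|"))
  # altloc policy: highest occupancy, ties by first occurrence
  key <- paste(atoms$resno, atoms$ins, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$resno, atoms$ins, atoms$atom, sep = "|")), , drop = FALSE]
  atoms <- atoms[order(match(paste(atoms$resno, atoms$ins, sep = "|"), file_order)), , drop = FALSE]

  reskey <- paste(atoms$resno, atoms$ins, sep = "|")
  residues <- unique(reskey)
  recs <- list()
  for (rk in residues) {
    sub <- atoms[reskey == rk, , drop = FALSE]
    anames <- sub$atom
    # a ribonucleotide-like residue must expose a C4' and a glycosidic N
    if (!any(anames %in% c("C4'", "C4*"))) next
    if (!any(anames %in% c("N1", "N9"))) next
    letter <- residue_letter(sub$resid[1L])
    want_n <- glyco_atom(letter)
    getxyz <- function(nm) {
      i <- match(nm, anames)
      if (is.na(i)) NULL else as.numeric(sub[i, c("x", "y", "z")])
    }
    p <- getxyz("P")
    c4 <- getxyz("C4'"); if (is.null(c4)) c4 <- getxyz("C4*")
    nn <- getxyz(want_n)
    if (is.null(nn)) nn <- getxyz(if (want_n == "N1") "N9" else "N1")
    recs[[length(recs) + 1L]] <- list(letter = letter, resno = sub$resno[1L],
                                      P = p, C4 = c4, N = nn)
  }
  if (length(recs) == 0L) {
    stop(sprintf("chain '%s' contains no ribonucleotides", chain_id))
  }
  L <- length(recs)
  P <- C4 <- N <- matrix(0, L, 3)
  ok <- matrix(FALSE, L, 3)
  for (i in seq_len(L)) {
    r <- recs[[i]]
    if (!is.null(r$P)) { P[i, ] <- r$P; ok[i, 1] <- TRUE }
    if (!is.null(r$C4)) { C4[i, ] <- r$C4; ok[i, 2] <- TRUE }
    if (!is.null(r$N)) { N[i, ] <- r$N; ok[i, 3] <- TRUE }
  }
  rna_structure(chain_id = chain_id,
                sequence = paste(vapply(recs, `[[`, "", "letter"), collapse = ""),
                P = P, C4 = C4, N = N,
                residue_numbers = vapply(recs, `[[`, 1L, "resno"),
                atom_ok = ok)
}

#' Parse an RNA chain from PDB or mmCIF text
#'
#' Reads one chain from a structure file and extracts, per ribonucleotide,
#' the P, C4' and N1/N9 coordinates. Modified or unknown residues map to
#' sequence letter `N`; residues lacking a C4' or glycosidic nitrogen
#' (ions, ligands, amino acids) are dropped. Only the first model of a
#' multi-model file is read. Alternate locations resolve to the
#' highest-occupancy conformer (ties: first occurrence). Positions missing
#' any of the three atoms are flagged in `atom_ok`.
#'
#' @param file_text character scalar (or vector of lines) with the file
#'   contents.
#' @param chain_id chain identifier to extract.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @return an [rna_structure()].
#' @export
parse_structure <- function(file_text, chain_id, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  lines <- if (length(file_text) == 1L) strsplit(file_text, "\n", fixed = TRUE)[[1]] else file_text
  if (format == "auto") {
    format <- if (any(grepl("^loop_|^_atom_site\\.", lines))) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") pdb_atom_table(lines) else mmcif_atom_table(lines)
  assemble_chain(atoms, chain_id)
}

# PDB dialect via bio3d; altlocs retained so the occupancy policy above
# applies uniformly.
pdb_atom_table <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  data.frame(chain = a$chain, resno = a$resno,
             ins = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
             resid = a$resid, atom = a$elety,
             x = a$x, y = a$y, z = a$z,
             occ = ifelse(is.na(a$o), 1, a$o),
             alt = ifelse(is.na(a$alt), "", a$alt),
             model = 1L, stringsAsFactors = FALSE)
}

# Minimal mmCIF atom_site loop reader (no installed R package reads mmCIF).
mmcif_atom_table <- function(lines) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L) stop("no _atom_site loop found in mmCIF text")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  rows <- list()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (grepl("^(#|loop_|_)", ln)) break
    toks <- scan(text = ln, what = "", quiet = TRUE)
    if (length(toks) != length(fields)) next
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0L) stop("empty _atom_site loop in mmCIF text")
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  grp <- pick("group_PDB")
  keep <- is.na(grp) | grp %in% c("ATOM", "HETATM")
  occ <- suppressWarnings(as.numeric(pick("occupancy")))
  data.frame(chain = pick("auth_asym_id", "label_asym_id")[keep],
             resno = as.integer(pick("auth_seq_id", "label_seq_id")[keep]),
             ins = {
               z <- pick("pdbx_PDB_ins_code")[keep]
               ifelse(is.na(z) | z %in% c("?", "."), "", z)
             },
             resid = pick("auth_comp_id", "label_comp_id")[keep],
             atom = gsub('"', "", pick("auth_atom_id", "label_atom_id")[keep]),
             x = as.numeric(pick("Cartn_x")[keep]),
             y = as.numeric(pick("Cartn_y")[keep]),
             z = as.numeric(pick("Cartn_z")[keep]),
             occ = ifelse(is.na(occ[keep]), 1, occ[keep]),
             alt = {
               z <- pick("label_alt_id")[keep]
               ifelse(is.na(z) | z %in% c("?", "."), "", z)
             },
             model = {
               z <- suppressWarnings(as.integer(pick("pdbx_PDB_model_num")[keep]))
               ifelse(is.na(z), 1L, z)
             },
             stringsAsFactors = FALSE)
}

#' Base-pair set
#'
#' Unordered, deduplicated base pairs over positions `1..L` (canonical and
#' non-canonical alike), optionally tagged with Leontis-Westhof classes.
#'
#' @param pairs two-column integer matrix (1-based positions) or empty.
#' @param L chain length the pairs refer to.
#' @param class_label optional character vector of per-pair tags.
#' @return object of class `basepair_set` with a normalised `pairs` matrix
#'   (`i < j`, sorted, unique).
#' @export
basepair_set <- function(pairs, L, class_label = NULL) {
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), 0, 2)
    class_label <- character(0)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pair (i == j) not allowed")
    if (any(pairs < 1L) || any(pairs > L)) {
      bad <- which(pairs < 1L | pairs > L, arr.ind = TRUE)[1, 1]
      stop(sprintf("pair (%d, %d) out of range for L = %d",
                   pairs[bad, 1], pairs[bad, 2], L))
    }
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (is.null(class_label)) class_label <- rep(NA_character_, nrow(pairs))
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    class_label <- class_label[ord]
    dup <- duplicated(pairs)
    pairs <- pairs[!dup, , drop = FALSE]
    class_label <- class_label[!dup]
  } else if (is.null(class_label)) class_label <- character(0)
  structure(list(pairs = pairs, L = as.integer(L), class_label = class_label),
            class = "basepair_set")
}

#' @export
print.basepair_set <- function(x, ...) {
  cat(sprintf("basepair_set: %d pairs over L = %d\n", nrow(x$pairs), x$L))
  invisible(x)
}

#' Read base-pair annotations
#'
#' Two dialects: `"tsv"` — whitespace-separated 1-based ordinal pairs, one
#' per line, `#` comments allowed; `"dssr"` — the `pairs` block of DSSR-style
#' JSON (fields `nt1`, `nt2` as `chain.letter+number` ids, optional `LW`
#' class). DSSR residue numbers map to positions through `residue_numbers`
#' when given, else they are taken as 1-based ordinals.
#'
#' @param annotation_text file contents.
#' @param format `"tsv"` or `"dssr"`.
#' @param L chain length.
#' @param residue_numbers optional author numbering of the chain.
#' @return [basepair_set()]
#' @export
read_basepairs <- function(annotation_text, format = c("tsv", "dssr"), L,
                           residue_numbers = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- if (length(annotation_text) == 1L) strsplit(annotation_text, "\n", fixed = TRUE)[[1]] else annotation_text
    lines_raw <- lines
    pairs <- matrix(integer(0), 0, 2)
    for (k in seq_along(lines_raw)) {
      ln <- sub("#.*$", "", lines_raw[k])
      if (trimws(ln) == "") next
      toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      ij <- suppressWarnings(as.integer(toks))
      if (length(ij) != 2L || any(is.na(ij))) {
        stop(sprintf("malformed pair line %d: '%s'", k, lines_raw[k]))
      }
      pairs <- rbind(pairs, ij)
    }
    basepair_set(pairs, L)
  } else {
    js <- jsonlite::fromJSON(paste(annotation_text, collapse = "\n"),
                             simplifyDataFrame = TRUE)
    pb <- js$pairs
    if (is.null(pb) || NROW(pb) == 0L) return(basepair_set(NULL, L))
    num_of <- function(ids) as.integer(sub("^.*?([0-9]+)$", "\\1", ids))
    i <- num_of(pb$nt1); j <- num_of(pb$nt2)
    if (!is.null(residue_numbers)) {
      i <- match(i, residue_numbers)
      j <- match(j, residue_numbers)
      if (anyNA(i) || anyNA(j)) stop("DSSR pair references a residue number absent from the chain")
    }
    lw <- if (!is.null(pb$LW)) as.character(pb$LW) else NULL
    basepair_set(cbind(i, j), L, class_label = lw)
  }
}

#' Write sequences as FASTA text
#'
#' @param records named character vector, or list of `c(name, sequence)`
#'   pairs.
#' @param path optional file to write to.
#' @param width line wrap width (default 60).
#' @return the FASTA text, invisibly when `path` is given.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  if (is.list(records)) {
    nms <- vapply(records, `[[`, "", 1L)
    seqs <- vapply(records, `[[`, "", 2L)
  } else {
    nms <- names(records)
    seqs <- unname(records)
  }
  out <- character(0)
  for (k in seq_along(seqs)) {
    s <- seqs[k]
    pos <- regexpr("[^ACGUN]", s)
    if (pos > 0) {
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   substr(s, pos, pos), pos, nms[k]))
    }
    out <- c(out, paste0(">", nms[k]))
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  txt <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Read FASTA text into a named character vector
#' @param text FASTA text or vector of lines.
#' @export
read_fasta <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA input")
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA input does not start with '>'")
  ids <- cumsum(hdr)
  nms <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], ids[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  stats::setNames(unname(seqs), nms)
}

#' Serialize a structure as PDB text
#'
#' Writes the three tracked atoms per nucleotide so generated fixtures
#' round-trip through [parse_structure()].
#' @param struct an [rna_structure()].
#' @param path optional output file.
#' @export
write_pdb_structure <- function(struct, path = NULL) {
  L <- length(struct)
  letters_ <- strsplit(struct$sequence, "")[[1]]
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(L)) {
    res <- letters_[i]
    resname <- if (res == "N") "UNK" else res
    atoms <- list(c("P", "P"), c("C4'", "C"), c(glyco_atom(res), "N"))
    xyz <- list(struct$P[i, ], struct$C4[i, ], struct$N[i, ])
    for (a in 1:3) {
      if (!struct$atom_ok[i, a]) next
      serial <- serial + 1L
      nm <- atoms[[a]][1]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, resname, substr(struct$chain_id, 1, 1),
        struct$residue_numbers[i],
        xyz[[a]][1], xyz[[a]][2], xyz[[a]][3], 1.00, 0.00, atoms[[a]][2]))
    }
  }
  txt <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Write a base-pair set as pairs-TSV text
#' @param bp a [basepair_set()].
#' @param path optional output file.
#' @export
write_pairs_tsv <- function(bp, path = NULL) {
  txt <- if (nrow(bp$pairs)) {
    paste0(paste(apply(bp$pairs, 1, paste, collapse = "\t"), collapse = "\n"), "\n")
  } else ""
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Conformer group: several structures sharing one sequence
#'
#' @param structures list of `list(structure = <rna_structure>,
#'   pairs = <basepair_set>)` members, all with identical sequence length.
#' @param sequence optional explicit shared sequence (defaults to the first
#'   member's).
#' @return object of class `conformer_group`.
#' @export
conformer_group <- function(structures, sequence = NULL) {
  stopifnot(length(structures) >= 1L)
  for (m in structures) {
    stopifnot(inherits(m$structure, "rna_structure"), inherits(m$pairs, "basepair_set"))
  }
  lens <- vapply(structures, function(m) length(m$structure), 1L)
  if (length(unique(lens)) != 1L) stop("all member structures must share one sequence length")
  if (is.null(sequence)) sequence <- structures[[1]]$structure$sequence
  stopifnot(nchar(sequence) == lens[1])
  structure(list(sequence = sequence, structures = structures),
            class = "conformer_group")
}

#' @export
print.conformer_group <- function(x, ...) {
  cat(sprintf("conformer_group: %d structures, L = %d\n",
              length(x$structures), nchar(x$sequence)))
  invisible(x)
}

#' Fetch a PDB entry from RCSB (requires network)
#'
#' Convenience helper for the worked examples on real accessions; downloads
#' are cached under `dir`.
#' @param id 4-character PDB id.
#' @param dir cache directory.
#' @return path to the downloaded file.
#' @export
fetch_pdb <- function(id, dir = tempdir()) {
  dest <- file.path(dir, paste0(toupper(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    old <- options(timeout = 30); on.exit(options(old))
    tryCatch(utils::download.file(url, dest, quiet = TRUE),
             error = function(e) {
               unlink(dest)
               stop(e)
             })
    if (!file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop(sprintf("download of %s failed", toupper(id)))
    }
  }
  dest
}
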