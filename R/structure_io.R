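#' protonpath: proton transfer pathway search and conservation analysis
#'
#' Tools to trace candidate proton transfer pathways (chains of
#' protonatable/polar side chains linking a buried cofactor site to the
#' protein surface) in PDB structures, to batch-measure atom-pair
#' distances, and to score group-wise sequence conservation of pathway
#' positions in a reference numbering.
#'
#' @keywords internal
#' @aliases protonpath-package
"_PACKAGE"

# ---- PDB fixed-width I/O -------------------------------------------------

#' Read a protein structure from PDB-format text
#'
#' Parses `ATOM` and `HETATM` records of the fixed-width PDB format into a
#' structure object holding one row per atom. Alternate-location duplicates
#' are retained as parsed; call [resolve_altlocs()] to reduce them to one
#' atom per name. Only the first `MODEL` of a multi-model file is kept (a
#' warning is issued for the rest): downstream geometric analyses operate
#' on single models.
#'
#' @param text character scalar (or vector of lines) of PDB-format text.
#'   Exactly one of `text`/`file` must be given.
#' @param file path to a PDB file.
#' @param id structure identifier; defaults to the file name or
#'   `"structure"`.
#' @return An object of class `ptp_structure`: a list with elements `id`,
#'   `atoms` (data.frame with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resnum`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`, `is_hetero`) and `source`.
#' @examples
#' s <- read_pdb(text = paste0(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000",
#'   "  1.00  0.00           N"))
#' nrow(s$atoms)
#' @export
read_pdb <- function(text = NULL, file = NULL, id = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    src <- file
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(file))
  } else {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
    src <- "text"
    if (is.null(id)) id <- "structure"
  }

  rec <- substr(lines, 1L, 6L)
  # first MODEL only
  model_idx <- which(trimws(rec) == "MODEL")
  if (length(model_idx) > 1L) {
    warning("multi-model file: keeping first MODEL only (",
            length(model_idx), " models present)")
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl)) endmdl[1L] else model_idx[2L]
    keep_lines <- seq_len(stop_at)
    lines <- lines[keep_lines]
    rec <- rec[keep_lines]
  }

  sel <- rec %in% c("ATOM  ", "HETATM")
  if (!any(sel))
    stop("no ATOM or HETATM records found: empty structure")
  ln <- which(sel)
  al <- lines[sel]

  num_field <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    blank <- which(!nzchar(trimws(s)))
    if (length(bad))
      stop(sprintf("malformed %s field in PDB record at line %d: '%s'",
                   what, ln[bad[1L]], trimws(s[bad[1L]])))
    if (length(blank))
      stop(sprintf("malformed %s field in PDB record at line %d: empty",
                   what, ln[blank[1L]]))
    v
  }

  atoms <- data.frame(
    record    = trimws(substr(al, 1L, 6L)),
    serial    = suppressWarnings(as.integer(substr(al, 7L, 11L))),
    name      = trimws(substr(al, 13L, 16L)),
    altloc    = trimws(substr(al, 17L, 17L)),
    resname   = trimws(substr(al, 18L, 20L)),
    chain     = trimws(substr(al, 22L, 22L)),
    resnum    = as.integer(num_field(substr(al, 23L, 26L), "residue-number")),
    icode     = trimws(substr(al, 27L, 27L)),
    x         = num_field(substr(al, 31L, 38L), "x-coordinate"),
    y         = num_field(substr(al, 39L, 46L), "y-coordinate"),
    z         = num_field(substr(al, 47L, 54L), "z-coordinate"),
    occupancy = {
      o <- trimws(substr(al, 55L, 60L))
      o[!nzchar(o)] <- "1.00"
      num_field(o, "occupancy")
    },
    bfactor   = {
      b <- trimws(substr(al, 61L, 66L))
      b[!nzchar(b)] <- "0.00"
      num_field(b, "B-factor")
    },
    element   = trimws(substr(al, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  atoms$is_hetero <- atoms$record == "HETATM"
  # infer element from atom name where the element columns are blank
  miss <- !nzchar(atoms$element)
  if (any(miss)) atoms$element[miss] <- guess_element(atoms$name[miss])
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinate parsed")

  new_structure(id = id, atoms = atoms, source = src)
}

new_structure <- function(id, atoms, source = "constructed") {
  stopifnot(nrow(atoms) >= 1L)
  atoms$resnum <- as.integer(atoms$resnum)
  atoms$serial <- as.integer(atoms$serial)
  structure(list(id = id, atoms = atoms, source = source),
            class = "ptp_structure")
}

#' @export
print.ptp_structure <- function(x, ...) {
  rk <- residue_keys(x$atoms)
  cat(sprintf("ptp_structure '%s': %d atoms, %d residues (source: %s)\n",
              x$id, nrow(x$atoms), length(unique(rk)), x$source))
  invisible(x)
}

# element from PDB atom-name conventions: names starting in column 13 with a
# two-character element (e.g. FE) vs. one-character elements padded to col 14
guess_element <- function(name) {
  nm <- toupper(name)
  el <- substr(nm, 1L, 1L)
  two <- c("FE", "ZN", "MG", "MN", "CU", "NI", "NA", "CL", "BR", "SE", "CA")
  first2 <- substr(nm, 1L, 2L)
  el[first2 %in% two & nchar(nm) >= 2L] <- first2[first2 %in% two & nchar(nm) >= 2L]
  # digit-leading hydrogen names like 1HB
  el[grepl("^[0-9]", nm)] <- substr(sub("^[0-9]+", "", nm), 1L, 1L)
  el
}

residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
}

#' Write a structure as PDB-format text
#'
#' Emits fixed-width `ATOM`/`HETATM` records followed by `END`. Coordinates
#' are written at the PDB precision of 3 decimals; a round trip through
#' [read_pdb()] reproduces names, numbering and coordinates to that
#' precision.
#'
#' @param s a `ptp_structure`.
#' @param file optional path; when given, text is written there invisibly.
#' @return character scalar of PDB text (invisibly when `file` is given).
#' @export
write_pdb <- function(s, file = NULL) {
  stopifnot(inherits(s, "ptp_structure"))
  a <- s$atoms
  if (any(nchar(a$name) > 4L))
    stop("atom name longer than 4 characters cannot be formatted: ",
         a$name[which(nchar(a$name) > 4L)[1L]])
  if (any(abs(c(a$x, a$y, a$z)) >= 10000 - 5e-4) ||
      any(c(a$x, a$y, a$z) <= -1000 + 5e-4))
    stop("coordinate exceeds the PDB 8.3 fixed-width field")
  # column-13 alignment: short names of 1-char elements start in column 14
  nm <- a$name
  pad <- nchar(nm) <= 3L & nchar(a$element) <= 1L
  nm[pad] <- paste0(" ", nm[pad])
  nm <- formatC(nm, width = -4L)
  rows <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  a$record, a$serial, nm, a$altloc, a$resname, a$chain,
                  a$resnum, a$icode, a$x, a$y, a$z, a$occupancy, a$bfactor,
                  a$element)
  txt <- paste(c(rows, "END"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Resolve alternate atom locations
#'
#' Keeps, for every (chain, residue, insertion code, atom name) group, the
#' altloc with the highest occupancy; ties go to the lexicographically
#' first altloc code. The blank altloc sorts first.
#'
#' @param s a `ptp_structure`.
#' @return a `ptp_structure` with at most one atom per name per residue.
#' @export
resolve_altlocs <- function(s) {
  stopifnot(inherits(s, "ptp_structure"))
  a <- s$atoms
  key <- paste(residue_keys(a), a$name, sep = "|")
  ord <- order(key, -a$occupancy, a$altloc)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  # restore original record order
  a <- a[order(a$serial), , drop = FALSE]
  rownames(a) <- NULL
  s$atoms <- a
  s
}

#' Construct an atom selector
#'
#' A selector names one atom by chain, residue number, optional insertion
#' code and atom name. `chain = "*"` is a wildcard matching any chain.
#'
#' @param chain chain identifier or `"*"`.
#' @param resnum integer residue number (author numbering).
#' @param atom atom name, e.g. `"OE1"`.
#' @param icode insertion code, default empty.
#' @return an object of class `ptp_selector`.
#' @export
atom_selector <- function(chain, resnum, atom, icode = "") {
  stopifnot(is.character(chain), length(chain) == 1L,
            length(resnum) == 1L, is.finite(resnum),
            is.character(atom), length(atom) == 1L)
  structure(list(chain = chain, resnum = as.integer(resnum),
                 atom = atom, icode = icode),
            class = "ptp_selector")
}

#' Resolve an atom selector against a structure
#'
#' Altlocs are resolved (max occupancy) before matching; the selector must
#' identify exactly one atom.
#'
#' @param s a `ptp_structure`.
#' @param sel a `ptp_selector` from [atom_selector()].
#' @return one-row data.frame (the atom record).
#' @export
select_atom <- function(s, sel) {
  stopifnot(inherits(s, "ptp_structure"), inherits(sel, "ptp_selector"))
  a <- resolve_altlocs(s)$atoms
  hit <- a$resnum == sel$resnum & a$icode == sel$icode & a$name == sel$atom
  if (sel$chain != "*") hit <- hit & a$chain == sel$chain
  n <- sum(hit)
  if (n == 0L)
    stop(sprintf("no atom matches selector %s/%d%s/%s in structure '%s'",
                 sel$chain, sel$resnum, sel$icode, sel$atom, s$id))
  if (n > 1L)
    stop(sprintf("selector %s/%d%s/%s is ambiguous (%d matches)",
                 sel$chain, sel$resnum, sel$icode, sel$atom, n))
  a[hit, , drop = FALSE]
}

# split an atom table into residues, preserving record order
split_residues <- function(atoms) {
  key <- residue_keys(atoms)
  split(atoms, factor(key, levels = unique(key)))
}
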