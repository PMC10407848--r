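# Candidate proton-relay heavy atoms per residue type. Only side-chain
# N/O/S atoms qualify; backbone amides and carbonyls never relay here.

#' Default relay-atom table
#'
#' Maps residue names to candidate proton-relay side-chain heavy atoms and
#' an eligibility class. Classes: `protonatable` (carboxylates, His ring
#' nitrogens, Lys/Arg nitrogens, Cys thiol, Tyr hydroxyl), `hydroxyl_polar`
#' (Ser/Thr hydroxyls), `amide_polar` (Asn/Gln amides, excluded from the
#' default search), `water` (the water oxygen). All 20 standard residues
#' have an entry; purely hydrophobic ones map to an empty atom set.
#'
#' @param overrides optional named list `resname -> list(atoms =, class =)`
#'   merged over the defaults (e.g. to admit a noncanonical residue).
#' @return named list of class `ptp_relay_table`; each element has `atoms`
#'   (character) and `class` (scalar).
#' @examples
#' tab <- default_relay_table()
#' tab$GLU
#' @export
default_relay_table <- function(overrides = NULL) {
  e <- function(atoms, cls) list(atoms = atoms, class = cls)
  none <- e(character(0), NA_character_)
  tab <- list(
    ASP = e(c("OD1", "OD2"), "protonatable"),
    GLU = e(c("OE1", "OE2"), "protonatable"),
    HIS = e(c("ND1", "NE2"), "protonatable"),
    LYS = e("NZ",            "protonatable"),
    ARG = e(c("NE", "NH1", "NH2"), "protonatable"),
    CYS = e("SG",            "protonatable"),
    TYR = e("OH",            "protonatable"),
    SER = e("OG",            "hydroxyl_polar"),
    THR = e("OG1",           "hydroxyl_polar"),
    ASN = e(c("OD1", "ND2"), "amide_polar"),
    GLN = e(c("OE1", "NE2"), "amide_polar"),
    HOH = e("O",             "water"),
    ALA = none, GLY = none, VAL = none, LEU = none, ILE = none,
    PHE = none, PRO = none, MET = none, TRP = none
  )
  if (!is.null(overrides)) {
    for (rn in names(overrides)) tab[[rn]] <- overrides[[rn]]
  }
  structure(tab, class = "ptp_relay_table")
}

#' Read a relay-atom table override from YAML or JSON
#'
#' The file maps residue names to `atoms` and `class`; entries are merged
#' over [default_relay_table()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `ptp_relay_table`.
#' @export
read_relay_table <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  ov <- lapply(raw, function(x)
    list(atoms = as.character(x$atoms), class = as.character(x$class)))
  default_relay_table(overrides = ov)
}

#' Extract the relay site of one residue
#'
#' Returns the residue's candidate relay atoms, or `NULL` when the residue
#' type has none (or is water while `include_waters` is off), or when none
#' of the tabulated atoms is present in the model.
#'
#' @param residue one-residue atom table (rows of a `ptp_structure`'s
#'   `atoms` with resolved altlocs).
#' @param table a `ptp_relay_table`.
#' @param include_waters admit HOH oxygens as relay sites.
#' @return a `ptp_relay_site` (list: `chain`, `resnum`, `icode`, `resname`,
#'   `class`, `atoms` data.frame with `name`, `x`, `y`, `z`) or `NULL`.
#' @export
relay_atoms <- function(residue, table = default_relay_table(),
                        include_waters = FALSE) {
  rn <- residue$resname[1L]
  entry <- table[[rn]]
  if (is.null(entry) || length(entry$atoms) == 0L) return(NULL)
  if (identical(entry$class, "water") && !include_waters) return(NULL)
  pres <- residue[residue$name %in% entry$atoms, , drop = FALSE]
  if (nrow(pres) == 0L) return(NULL)
  structure(list(
    chain = residue$chain[1L], resnum = residue$resnum[1L],
    icode = residue$icode[1L], resname = rn, class = entry$class,
    atoms = pres[, c("name", "x", "y", "z"), drop = FALSE]
  ), class = "ptp_relay_site")
}

#' @export
print.ptp_relay_site <- function(x, ...) {
  cat(sprintf("relay site %s %s%d%s [%s]: %s\n", x$resname, x$chain,
              x$resnum, x$icode, x$class,
              paste(x$atoms$name, collapse = ", ")))
  invisible(x)
}

site_key <- function(site) {
  paste(site$chain, site$resnum, site$icode, sep = "|")
}

site_label <- function(site) {
  sprintf("%s%s%d%s", site$resname, site$chain, site$resnum, site$icode)
}

#' Enumerate all relay sites of a structure
#'
#' @param s a `ptp_structure` (altlocs are resolved internally).
#' @param table a `ptp_relay_table`.
#' @param eligible_classes classes admitted to the search; sites of other
#'   classes are dropped.
#' @param include_waters admit HOH.
#' @return list of `ptp_relay_site`, in record order.
#' @export
relay_sites <- function(s, table = default_relay_table(),
                        eligible_classes = c("protonatable", "hydroxyl_polar"),
                        include_waters = FALSE) {
  res <- split_residues(resolve_altlocs(s)$atoms)
  sites <- lapply(res, relay_atoms, table = table,
                  include_waters = include_waters)
  sites <- sites[!vapply(sites, is.null, logical(1))]
  keep <- vapply(sites, function(x) x$class %in% eligible_classes ||
                   (include_waters && x$class == "water"), logical(1))
  unname(sites[keep])
}
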