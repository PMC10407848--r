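# Fixture builders and independent brute-force oracles used across tests.

# compact structure builder: one row per atom
make_structure <- function(..., id = "fixture") {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(record = r$record %||% "ATOM", serial = i,
               name = r$name, altloc = r$altloc %||% "",
               resname = r$resname, chain = r$chain %||% "A",
               resnum = r$resnum, icode = r$icode %||% "",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occupancy = r$occ %||% 1.0, bfactor = 0.0,
               element = r$element %||% substr(r$name, 1, 1),
               is_hetero = identical(r$record, "HETATM"),
               stringsAsFactors = FALSE)
  }))
  protonpath:::new_structure(id, df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

at <- function(name, resname, resnum, xyz, ...) {
  c(list(name = name, resname = resname, resnum = resnum, xyz = xyz),
    list(...))
}

# independent relay-atom definition for the brute-force oracles (kept
# separate from the package's table on purpose)
oracle_relay_atom_names <- list(
  GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"), SER = "OG", THR = "OG1",
  LYS = "NZ", TYR = "OH", HIS = c("ND1", "NE2"), CYS = "SG",
  ARG = c("NE", "NH1", "NH2"))

# brute-force minimum distance between the relay atoms of two residues
# (or from a bare point to a residue): plain double loop
oracle_min_dist <- function(s, from, to_resnum, to_chain = "A") {
  a <- protonpath::resolve_altlocs(s)$atoms
  bt <- a[a$chain == to_chain & a$resnum == to_resnum, , drop = FALSE]
  bt <- bt[bt$name %in% oracle_relay_atom_names[[bt$resname[1]]], ,
           drop = FALSE]
  from_xyz <- if (is.numeric(from)) matrix(from, nrow = 1) else {
    ft <- a[a$chain == from["chain"] & a$resnum == as.integer(from["resnum"]),
            , drop = FALSE]
    ft <- ft[ft$name %in% oracle_relay_atom_names[[ft$resname[1]]], ,
             drop = FALSE]
    as.matrix(ft[, c("x", "y", "z")])
  }
  best <- Inf
  for (i in seq_len(nrow(from_xyz)))
    for (j in seq_len(nrow(bt)))
      best <- min(best, sqrt(sum((from_xyz[i, ] -
                                    c(bt$x[j], bt$y[j], bt$z[j]))^2)))
  best
}

path_signature <- function(p) {
  paste(p$steps$chain, p$steps$resnum, sep = "|", collapse = ">")
}

# a lone residue structure at a given minimum distance from the origin
lone_glu_structure <- function(dist) {
  make_structure(
    at("OE1", "GLU", 10, c(dist, 0, 0)),
    at("OE2", "GLU", 10, c(dist + 1.0, 1.8, 0)),
    at("CB", "GLU", 10, c(dist + 1.5, -1.2, 0), element = "C"))
}
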