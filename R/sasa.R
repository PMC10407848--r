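# Shrake-Rupley solvent accessible surface area with a deterministic
# golden-spiral point set, and relative side-chain accessibility against
# published per-residue maxima.

#' Van der Waals radii used for SASA (Angstrom)
#'
#' @param overrides named numeric vector merged over the defaults.
#' @return named numeric vector.
#' @export
vdw_radii <- function(overrides = NULL) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, FE = 2.00)
  if (!is.null(overrides)) r[names(overrides)] <- overrides
  r
}

# deterministic quasi-uniform points on the unit sphere (golden spiral);
# no RNG so SASA values are bit-stable across runs
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom accessible area from spherical point sampling: each atom's
#' solvent-accessible sphere (van der Waals radius + probe radius) is
#' covered with a deterministic golden-spiral point set and a point counts
#' as accessible when it lies outside every neighbouring atom's accessible
#' sphere.
#'
#' @param s a `ptp_structure` (altlocs resolved internally).
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @param vdw named radius table, see [vdw_radii()].
#' @return numeric vector of per-atom areas (Angstrom^2), aligned with the
#'   rows of the altloc-resolved atom table (returned as attribute
#'   `"atoms"`).
#' @export
shrake_rupley_sasa <- function(s, probe = 1.4, n_points = 960,
                               vdw = vdw_radii()) {
  stopifnot(inherits(s, "ptp_structure"), probe >= 0, n_points >= 12)
  a <- resolve_altlocs(s)$atoms
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(vdw))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " (supply an override via 'vdw')")
  r <- unname(vdw[el]) + probe
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  area <- numeric(n)
  # neighbour pruning via squared center distances; occlusion test as one
  # sample-points x neighbours distance matrix per atom
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    sp <- pts * r[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    cn <- xyz[nb, , drop = FALSE]
    cross <- sp %*% t(cn)
    dd <- outer(rowSums(sp^2), rowSums(cn^2), `+`) - 2 * cross
    occluded <- dd < matrix(r[nb]^2, nrow = n_points, ncol = length(nb),
                            byrow = TRUE)
    acc <- rowSums(occluded) == 0L
    area[i] <- sum(acc) / n_points * 4 * pi * r[i]^2
  }
  attr(area, "atoms") <- a
  area
}

#' Reference maximum side-chain accessibilities (Angstrom^2)
#'
#' Standard-state side-chain accessibilities of residue X in extended
#' Gly-X-Gly tripeptides, from Miller, Janin, Lesk & Chothia (1987)
#' J Mol Biol 196:641. `HOH` is assigned the analytic free-sphere area of
#' a water oxygen (4 * pi * (1.52 + 1.4)^2); `GLY`, having no side chain,
#' is NA.
#'
#' @return named numeric vector.
#' @export
max_sidechain_sasa <- function() {
  c(ALA = 67, ARG = 196, ASN = 113, ASP = 106, CYS = 104,
    GLN = 144, GLU = 138, GLY = NA, HIS = 151, ILE = 140,
    LEU = 137, LYS = 167, MET = 160, PHE = 175, PRO = 105,
    SER = 80, THR = 102, TRP = 217, TYR = 187, VAL = 117,
    HOH = 4 * pi * 2.92^2)
}

backbone_atom_names <- c("N", "CA", "C", "O", "OXT")

#' Relative side-chain solvent accessibility of one residue
#'
#' Side-chain SASA (all non-backbone heavy atoms, hydrogens excluded)
#' divided by the residue's tabulated maximum ([max_sidechain_sasa()]),
#' clipped to \[0, 1.2\]. This operationalises "surface-exposed": a residue
#' counts as at the surface when its relative accessibility reaches the
#' search threshold (default 0.20).
#'
#' @param chain,resnum,icode residue identity.
#' @param s a `ptp_structure`.
#' @param sasa optional precomputed result of [shrake_rupley_sasa()] for
#'   `s` (recomputed otherwise).
#' @param reference named maxima table.
#' @return scalar fraction in \[0, 1.2\].
#' @export
relative_sasa <- function(s, chain, resnum, icode = "", sasa = NULL,
                          reference = max_sidechain_sasa()) {
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(s)
  a <- attr(sasa, "atoms")
  row <- a$chain == chain & a$resnum == resnum & a$icode == icode
  if (!any(row)) stop("residue not found: ", chain, resnum, icode)
  rn <- a$resname[row][1L]
  if (!rn %in% names(reference))
    stop("no reference maximum accessibility for residue type ", rn)
  ref <- reference[[rn]]
  if (is.na(ref)) return(0)
  sc <- row & !(a$name %in% backbone_atom_names) & toupper(a$element) != "H"
  if (rn == "HOH") sc <- row & a$name == "O"
  val <- sum(sasa[sc]) / ref
  min(max(val, 0), 1.2)
}

# relative SASA for every relay site at once (shared SASA evaluation)
site_relative_sasa <- function(s, sites, params) {
  sasa <- shrake_rupley_sasa(s, probe = params$probe,
                             n_points = params$n_points,
                             vdw = params$vdw)
  vapply(sites, function(st)
    relative_sasa(s, st$chain, st$resnum, st$icode, sasa = sasa,
                  reference = params$reference_sasa),
    numeric(1))
}
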