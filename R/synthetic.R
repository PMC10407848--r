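# Seeded generators: toy structures with a planted relay chain at exact
# spacings inside a decoy shell, and per-group alignments with planted
# conserved columns. These provide ground truth for validating the search
# and the conservation calls.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Specification of a synthetic planted-relay structure
#'
#' The default plan reproduces the geometry of a four-relay chain —
#' carboxylate, carboxylate, hydroxyl, carboxylate — at spacings of
#' 3.4, 3.5, 4.1 and 5.2 Angstrom from a buried anchor, the arrangement
#' studied for the Group D hydrogenase pathway, with the last spacing
#' deliberately beyond the base 5.0 A cutoff so recovery exercises the
#' adaptive extension.
#'
#' @param relay_plan data.frame with columns `resname`, `spacing`
#'   (Angstrom between consecutive relay-atom sets; first value is the
#'   anchor-to-first-relay distance).
#' @param anchor_point xyz of the buried anchor (azadithiolate bridgehead
#'   amine analog).
#' @param n_decoys decoy residues attempted around the chain.
#' @param decoy_shell_radius how far from the chain decoys may sit,
#'   Angstrom.
#' @param bury_anchor fill decoys around the anchor end.
#' @param expose_terminal keep an open hemisphere (no decoys within
#'   `open_radius`) around the last relay so it is solvent-exposed.
#' @param open_radius radius of the decoy-free zone at the exposed end.
#' @param jitter maximum random displacement applied to every atom,
#'   Angstrom (direction uniform, magnitude uniform on \[0, jitter\]).
#' @param seed RNG seed; all output is a pure function of the spec.
#' @param renumber_relays give 4-relay plans the residue numbers
#'   252/289/249/265 (reference-style numbering) instead of sequential
#'   numbers.
#' @return list of class `ptp_structure_spec`.
#' @export
relay_structure_spec <- function(
    relay_plan = data.frame(
      resname = c("GLU", "GLU", "SER", "ASP"),
      spacing = c(3.4, 3.5, 4.1, 5.2),
      stringsAsFactors = FALSE),
    anchor_point = c(0, 0, 0), n_decoys = 160L,
    decoy_shell_radius = 6.0, bury_anchor = TRUE,
    expose_terminal = TRUE, open_radius = 4.5,
    jitter = 0, seed = 1L, renumber_relays = TRUE) {
  stopifnot(nrow(relay_plan) >= 1L, all(relay_plan$spacing > 0),
            jitter >= 0, decoy_shell_radius > 0)
  tab <- default_relay_table()
  bad <- vapply(relay_plan$resname,
                function(r) is.null(tab[[r]]) || !length(tab[[r]]$atoms),
                logical(1))
  if (any(bad))
    stop("relay plan contains residues without relay atoms: ",
         paste(relay_plan$resname[bad], collapse = ", "))
  structure(list(relay_plan = relay_plan,
                 anchor_point = as.numeric(anchor_point),
                 n_decoys = as.integer(n_decoys),
                 decoy_shell_radius = decoy_shell_radius,
                 bury_anchor = isTRUE(bury_anchor),
                 expose_terminal = isTRUE(expose_terminal),
                 open_radius = open_radius,
                 jitter = jitter, seed = as.integer(seed),
                 renumber_relays = isTRUE(renumber_relays)),
            class = "ptp_structure_spec")
}

# primary relay-atom positions on a gentle planar arc (20 degree turn per
# step): far enough from collinear shortcuts, close enough that k and k+2
# relays stay well beyond the cutoff
relay_arc_positions <- function(anchor, spacings, turn = 20 * pi / 180) {
  pos <- matrix(NA_real_, nrow = length(spacings), ncol = 3L)
  p <- anchor
  ang <- 0
  for (k in seq_along(spacings)) {
    t <- c(cos(ang), sin(ang), 0)
    p <- p + spacings[k] * t
    pos[k, ] <- p
    ang <- ang + turn
  }
  pos
}

# per-residue-type atom layout around the primary relay-atom position.
# side_dir: +z/-z alternation for the secondary carboxylate oxygen keeps
# min-over-pairs distances equal to the planted primary-primary spacings.
relay_residue_atoms <- function(resname, p, tdir, side) {
  z <- c(0, 0, 1) * side
  b <- -c(0, 0, 1) * side           # backbone on the opposite side
  prim <- switch(resname,
                 GLU = "OE1", ASP = "OD1", SER = "OG", THR = "OG1",
                 TYR = "OH", LYS = "NZ", CYS = "SG", HIS = "ND1",
                 stop("no layout for relay residue ", resname))
  sec <- switch(resname, GLU = "OE2", ASP = "OD2", HIS = "NE2", NULL)
  nm <- c("N", "CA", "CB", prim)
  xyz <- rbind(p + 2.9 * b + 1.46 * (-tdir),  # N
               p + 2.9 * b,                   # CA
               p + 1.5 * b,                   # CB
               p)                             # primary relay atom
  el <- c("N", "C", "C", substr(prim, 1L, 1L))
  if (!is.null(sec)) {
    nm <- c(nm, sec)
    xyz <- rbind(xyz, p + 2.2 * z)
    el <- c(el, substr(sec, 1L, 1L))
  }
  list(names = nm, xyz = xyz, element = el)
}

dist_point_segment <- function(q, a, b) {
  ab <- b - a
  t <- sum((q - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((q - (a + t * ab))^2))
}

#' Generate a synthetic structure with a planted relay chain
#'
#' Relay side chains are laid along a gentle outward arc at exactly the
#' spacings of the plan (before jitter); hydrophobic decoy residues
#' (ALA/VAL/LEU, carrying no relay atoms) fill a shell around the chain by
#' Poisson-disk-like rejection sampling (3.0 A minimum separation), burying
#' the anchor end while an open zone around the last relay leaves it
#' solvent-exposed. A hetero group provides an anchor nitrogen (analog of
#' the azadithiolate bridgehead amine) plus an iron 2.5 A away (distal-iron
#' analog). Deterministic given the spec.
#'
#' @param spec a [relay_structure_spec()].
#' @return list with `structure` (a `ptp_structure`), and `ground_truth`
#'   (list: `relay_resnums`, `relay_labels`, `relay_keys`, `spacings`,
#'   `anchor_point`, `anchor_selector`, `seed`).
#' @export
generate_relay_structure <- function(spec = relay_structure_spec()) {
  stopifnot(inherits(spec, "ptp_structure_spec"))
  with_seed(spec$seed, {
    plan <- spec$relay_plan
    nrel <- nrow(plan)
    anchor <- spec$anchor_point
    prim <- relay_arc_positions(anchor, plan$spacing)
    turn <- 20 * pi / 180

    resnums <- if (spec$renumber_relays && nrel == 4L)
      c(252L, 289L, 249L, 265L) else 500L + seq_len(nrel)

    atoms <- list()
    serial <- 0L
    add_res <- function(resname, resnum, layout, record = "ATOM") {
      n <- length(layout$names)
      df <- data.frame(
        record = record, serial = serial + seq_len(n),
        name = layout$names, altloc = "", resname = resname,
        chain = "A", resnum = resnum, icode = "",
        x = layout$xyz[, 1], y = layout$xyz[, 2], z = layout$xyz[, 3],
        occupancy = 1.0, bfactor = 0.0, element = layout$element,
        is_hetero = record == "HETATM", stringsAsFactors = FALSE)
      serial <<- serial + n
      atoms[[length(atoms) + 1L]] <<- df
    }

    # anchor hetero group: bridgehead-amine analog + distal-iron analog
    t0 <- c(1, 0, 0)
    add_res("ADT", 900L, list(
      names = c("N1", "FE1"),
      xyz = rbind(anchor, anchor - 2.5 * t0),
      element = c("N", "FE")), record = "HETATM")

    relay_atom_xyz <- NULL
    for (k in seq_len(nrel)) {
      tdir <- c(cos((k - 1) * turn), sin((k - 1) * turn), 0)
      side <- if (k %% 2L == 1L) 1 else -1
      lay <- relay_residue_atoms(plan$resname[k], prim[k, ], tdir, side)
      add_res(plan$resname[k], resnums[k], lay)
      relay_atom_xyz <- rbind(relay_atom_xyz, lay$xyz)
    }

    # decoy shell: Poisson-disk rejection sampling around the chain
    segs <- rbind(anchor, prim)
    lo <- apply(segs, 2L, min) - spec$decoy_shell_radius
    hi <- apply(segs, 2L, max) + spec$decoy_shell_radius
    # the decoy-free zone is measured from every relay atom of the last
    # residue, so both carboxylate oxygens stay exposed
    term_lay <- relay_residue_atoms(plan$resname[nrel], prim[nrel, ],
                                    c(cos((nrel - 1) * turn),
                                      sin((nrel - 1) * turn), 0),
                                    if (nrel %% 2L == 1L) 1 else -1)
    term_relay_xyz <- term_lay$xyz[!term_lay$names %in%
                                     c("N", "CA", "CB"), , drop = FALSE]
    t_last <- c(cos((nrel - 1) * turn), sin((nrel - 1) * turn), 0)
    # open hemisphere: decoys may not sit outward of the terminal relay,
    # nor within open_radius of its relay atoms
    term_excluded <- function(q)
      sum((q - prim[nrel, ]) * t_last) > -0.5 ||
      min(sqrt(rowSums(sweep(term_relay_xyz, 2L, q)^2))) < spec$open_radius
    decoy_names <- c("ALA", "VAL", "LEU")
    decoy_numbers <- setdiff(seq_len(spec$n_decoys + nrel + 1L),
                             c(resnums, 900L))

    # batch-vectorized candidate generation, then sequential Poisson-disk
    # acceptance against already-placed decoys
    M <- spec$n_decoys * 200L
    cand <- cbind(lo[1] + stats::runif(M) * (hi[1] - lo[1]),
                  lo[2] + stats::runif(M) * (hi[2] - lo[2]),
                  lo[3] + stats::runif(M) * (hi[3] - lo[3]))
    cname <- sample(decoy_names, M, replace = TRUE)
    mind_to <- function(pts, targets) {
      # per-candidate minimum distance to a small set of target points
      out <- rep(Inf, nrow(pts))
      for (i in seq_len(nrow(targets))) {
        d <- sqrt((pts[, 1] - targets[i, 1])^2 +
                    (pts[, 2] - targets[i, 2])^2 +
                    (pts[, 3] - targets[i, 3])^2)
        out <- pmin(out, d)
      }
      out
    }
    seg_dist <- rep(Inf, M)
    nearest_seg_pt <- matrix(NA_real_, M, 3L)
    for (i in seq_len(nrow(segs) - 1L)) {
      a0 <- segs[i, ]; b0 <- segs[i + 1L, ]
      ab <- b0 - a0
      t <- ((cand[, 1] - a0[1]) * ab[1] + (cand[, 2] - a0[2]) * ab[2] +
              (cand[, 3] - a0[3]) * ab[3]) / sum(ab * ab)
      t <- pmin(pmax(t, 0), 1)
      px <- a0[1] + t * ab[1]; py <- a0[2] + t * ab[2]; pz <- a0[3] + t * ab[3]
      d <- sqrt((cand[, 1] - px)^2 + (cand[, 2] - py)^2 + (cand[, 3] - pz)^2)
      upd <- d < seg_dist
      seg_dist[upd] <- d[upd]
      nearest_seg_pt[upd, ] <- cbind(px, py, pz)[upd, , drop = FALSE]
    }
    keep <- seg_dist <= spec$decoy_shell_radius &
      mind_to(cand, relay_atom_xyz) >= 2.8 &
      mind_to(cand, matrix(anchor, 1L)) >= 2.8
    if (!spec$bury_anchor)
      keep <- keep & mind_to(cand, matrix(anchor, 1L)) >= spec$open_radius
    away <- cand - nearest_seg_pt
    awn <- pmax(sqrt(rowSums(away^2)), 1e-8)
    away <- away / awn
    ca_all <- cand + 1.5 * away
    nn_all <- cand + 2.96 * away
    keep <- keep & mind_to(ca_all, relay_atom_xyz) >= 2.0
    if (spec$expose_terminal) {
      outward <- function(pts)
        (pts[, 1] - prim[nrel, 1]) * t_last[1] +
        (pts[, 2] - prim[nrel, 2]) * t_last[2] +
        (pts[, 3] - prim[nrel, 3]) * t_last[3] > -0.5
      near_term <- function(pts)
        mind_to(pts, term_relay_xyz) < spec$open_radius
      keep <- keep & !(outward(cand) | near_term(cand)) &
        !(outward(ca_all) | near_term(ca_all)) &
        !(outward(nn_all) | near_term(nn_all))
    }
    idx <- which(keep)
    placed <- 0L
    decoy_cb <- matrix(NA_real_, spec$n_decoys, 3L)
    for (i in idx) {
      if (placed >= spec$n_decoys) break
      if (placed > 0L) {
        d2 <- (decoy_cb[seq_len(placed), 1] - cand[i, 1])^2 +
          (decoy_cb[seq_len(placed), 2] - cand[i, 2])^2 +
          (decoy_cb[seq_len(placed), 3] - cand[i, 3])^2
        if (min(d2) < 9.0) next
      }
      placed <- placed + 1L
      decoy_cb[placed, ] <- cand[i, ]
      add_res(cname[i], decoy_numbers[placed], list(
        names = c("N", "CA", "CB"),
        xyz = rbind(nn_all[i, ], ca_all[i, ], cand[i, ]),
        element = c("N", "C", "C")))
    }

    a <- do.call(rbind, atoms)
    # packing validation: decoys must keep clear of the planted relays
    dec <- a$resname %in% decoy_names
    if (any(dec)) {
      dd <- as.matrix(a[dec, c("x", "y", "z")])
      mind <- min(apply(relay_atom_xyz, 1L, function(p)
        min(sqrt(rowSums(sweep(dd, 2L, p)^2)))))
      if (mind < 1.5)
        stop("infeasible decoy packing: decoy atom within 1.5 A of a relay")
    }

    if (spec$jitter > 0) {
      for (i in seq_len(nrow(a))) {
        d <- rand_unit() * stats::runif(1, 0, spec$jitter)
        a$x[i] <- a$x[i] + d[1]
        a$y[i] <- a$y[i] + d[2]
        a$z[i] <- a$z[i] + d[3]
      }
    }

    s <- new_structure(
      id = sprintf("synthetic_relay_seed%d", spec$seed), atoms = a,
      source = sprintf("synthetic: planted relay chain, seed %d", spec$seed))

    # ground-truth fidelity check (pre-jitter geometry): the min-over-pairs
    # distances between consecutive planted sites equal the plan spacings
    if (spec$jitter == 0) {
      sites <- relay_sites(s, eligible_classes = c("protonatable",
                                                   "hydroxyl_polar",
                                                   "amide_polar"))
      key <- vapply(sites, site_key, character(1))
      want <- paste("A", resnums, "", sep = "|")
      ss <- sites[match(want, key)]
      prev <- list(anchor)
      for (k in seq_len(nrel)) {
        d <- min_site_distance(prev[[1L]], ss[[k]])$distance
        stopifnot(abs(d - plan$spacing[k]) < 1e-9)
        prev <- list(ss[[k]])
      }
    }

    list(structure = s,
         ground_truth = list(
           relay_resnums = resnums,
           relay_labels = sprintf("%s%d", plan$resname, resnums),
           relay_keys = paste("A", resnums, "", sep = "|"),
           spacings = plan$spacing,
           anchor_point = anchor,
           anchor_selector = atom_selector("A", 900L, "N1"),
           n_decoys_placed = placed,
           seed = spec$seed))
  })
}

#' Random small screening structure (for search validation)
#'
#' Scatters a mix of relay-capable and hydrophobic residues uniformly in a
#' cubic box, each residue a compact side-chain cluster. Used to audit the
#' greedy search against brute-force oracles on many random geometries.
#'
#' @param seed RNG seed.
#' @param n_res number of residues (default drawn in 12..26).
#' @param box box edge, Angstrom; the default density yields a mix of
#'   traceable chains, dead ends and immediate surface hits.
#' @param p_eligible probability a residue is relay-capable.
#' @return list with `structure` and `anchor_point` (box centre).
#' @export
generate_random_structure <- function(seed, n_res = NULL, box = 16,
                                      p_eligible = 0.6) {
  with_seed(seed, {
    if (is.null(n_res)) n_res <- sample(12:26, 1L)
    eligible_names <- c("GLU", "ASP", "SER", "THR", "LYS", "TYR", "HIS")
    decoy_names <- c("ALA", "VAL", "LEU", "PHE")
    rows <- list()
    serial <- 0L
    for (i in seq_len(n_res)) {
      rn <- if (stats::runif(1) < p_eligible)
        sample(eligible_names, 1L) else sample(decoy_names, 1L)
      p <- stats::runif(3, 0, box)
      tdir <- rand_unit()
      side <- sample(c(-1, 1), 1L)
      lay <- if (rn %in% eligible_names)
        relay_residue_atoms(rn, p, tdir, side)
      else list(names = c("N", "CA", "CB"),
                xyz = rbind(p + 2.9 * tdir, p + 1.5 * tdir, p),
                element = c("N", "C", "C"))
      n <- length(lay$names)
      rows[[i]] <- data.frame(
        record = "ATOM", serial = serial + seq_len(n), name = lay$names,
        altloc = "", resname = rn, chain = "A", resnum = i, icode = "",
        x = lay$xyz[, 1], y = lay$xyz[, 2], z = lay$xyz[, 3],
        occupancy = 1.0, bfactor = 0.0, element = lay$element,
        is_hetero = FALSE, stringsAsFactors = FALSE)
      serial <- serial + n
    }
    s <- new_structure(sprintf("random_screen_seed%d", seed),
                       do.call(rbind, rows),
                       source = sprintf("synthetic: random screen, seed %d",
                                        seed))
    list(structure = s, anchor_point = rep(box / 2, 3L))
  })
}

#' Specification of synthetic per-group alignments
#'
#' Emulates the contrast structure of cross-group consensus comparison:
#' background columns i.i.d. from a background residue distribution, with
#' designated columns planted at a controlled consensus probability in
#' designated groups. The default emulates four phylogenetic groups with
#' 50 sequences each, 200 columns, and 20 columns exclusively conserved in
#' group D at consensus probability 0.95.
#'
#' @param groups data.frame with columns `label`, `n_seqs`.
#' @param ncol alignment length.
#' @param planted data.frame with columns `column`, `group`, `residue`,
#'   `p_cons`.
#' @param background named probability vector over the 20 amino acids
#'   (default uniform).
#' @param ref_id id of the gapless reference sequence.
#' @param ref_group group whose alignment carries the reference.
#' @param seed RNG seed.
#' @return list of class `ptp_msa_spec`.
#' @export
group_msa_spec <- function(
    groups = data.frame(label = c("A", "B", "C", "D"),
                        n_seqs = 50L, stringsAsFactors = FALSE),
    ncol = 200L,
    planted = data.frame(column = seq(10L, 200L, by = 10L), group = "D",
                         residue = rep(c("E", "D", "S"), length.out = 20L),
                         p_cons = 0.95, stringsAsFactors = FALSE),
    background = NULL, ref_id = "REFSEQ", ref_group = "D", seed = 13L) {
  if (is.null(background)) {
    background <- rep(1 / 20, 20L)
    names(background) <- AA20
  }
  stopifnot(all(groups$n_seqs >= 2L), ncol >= 1L,
            all(planted$column >= 1L & planted$column <= ncol),
            all(planted$p_cons > 0 & planted$p_cons <= 1),
            all(planted$group %in% groups$label),
            all(planted$residue %in% AA20),
            ref_group %in% groups$label,
            abs(sum(background) - 1) < 1e-9)
  structure(list(groups = groups, ncol = as.integer(ncol),
                 planted = planted, background = background,
                 ref_id = ref_id, ref_group = ref_group,
                 seed = as.integer(seed)),
            class = "ptp_msa_spec")
}

#' Generate synthetic per-group alignments with planted conservation
#'
#' @param spec a [group_msa_spec()].
#' @return list with `msas` (named list of `ptp_msa`), and `ground_truth`
#'   (the planted table plus `exclusive_positions`: columns planted in
#'   exactly one group; alignments are gapless so reference positions
#'   equal column indices).
#' @export
generate_group_msas <- function(spec = group_msa_spec()) {
  stopifnot(inherits(spec, "ptp_msa_spec"))
  with_seed(spec$seed, {
    bg <- spec$background
    msas <- list()
    for (gi in seq_len(nrow(spec$groups))) {
      g <- spec$groups$label[gi]
      n <- spec$groups$n_seqs[gi]
      mat <- matrix(sample(AA20, n * spec$ncol, replace = TRUE, prob = bg),
                    nrow = n, ncol = spec$ncol)
      pl <- spec$planted[spec$planted$group == g, , drop = FALSE]
      # several planted residues on one column partition the probability
      # space jointly (p_1 for the first residue, p_2 for the second, ...)
      for (cl in unique(pl$column)) {
        rows <- pl[pl$column == cl, , drop = FALSE]
        if (sum(rows$p_cons) > 1 + 1e-9)
          stop("planted probabilities at column ", cl, " exceed 1")
        u <- stats::runif(n)
        edges <- cumsum(rows$p_cons)
        lower <- c(0, edges[-length(edges)])
        for (k in seq_len(nrow(rows))) {
          hit <- u >= lower[k] & u < edges[k]
          mat[hit, cl] <- rows$residue[k]
        }
      }
      ids <- sprintf("%s_seq%03d", g, seq_len(n))
      if (g == spec$ref_group) {
        # the reference is one of the group's n_seqs sequences: the first
        # generated sequence, forced to carry the planted residues so all
        # planted columns are addressable in reference numbering
        refpl <- spec$planted[spec$planted$group == g, , drop = FALSE]
        mat[1L, refpl$column] <- refpl$residue
        ids[1L] <- spec$ref_id
      }
      msas[[g]] <- new_msa(ids = ids,
                           seqs = apply(mat, 1L, paste, collapse = ""),
                           group_label = g)
    }
    tab <- table(spec$planted$column)
    excl_cols <- as.integer(names(tab)[tab == 1L])
    list(msas = msas,
         ground_truth = list(
           planted = spec$planted,
           exclusive_positions = sort(excl_cols),
           ref_id = spec$ref_id, ref_group = spec$ref_group,
           seed = spec$seed))
  })
}
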