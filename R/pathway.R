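# Anchored distance-cutoff relay search: from a buried anchor point,
# repeatedly take the nearest unvisited eligible relay site within the
# cutoff (extending it adaptively up to dmax when nothing lies within the
# base cutoff), until the current site is solvent-exposed.

#' Search parameters for pathway tracing
#'
#' @param d0 base heavy-atom distance cutoff, Angstrom. The screen asks for
#'   relay partners within roughly hydrogen-bonding-network range; 5.0 by
#'   default.
#' @param dmax maximum extended cutoff, Angstrom (default 5.3).
#' @param step cutoff extension increment, Angstrom (default 0.1). The
#'   cutoff is re-set to `d0` after every accepted relay.
#' @param eligible_classes relay classes admitted as chain members.
#' @param include_waters admit water oxygens as relays.
#' @param sasa_threshold relative side-chain accessibility at which a
#'   residue counts as surface-exposed (default 0.20).
#' @param max_steps maximum chain length guard.
#' @param probe,n_points,vdw,reference_sasa SASA settings, see
#'   [shrake_rupley_sasa()] and [relative_sasa()].
#' @return list of class `ptp_params`.
#' @export
search_params <- function(d0 = 5.0, dmax = 5.3, step = 0.1,
                          eligible_classes = c("protonatable", "hydroxyl_polar"),
                          include_waters = FALSE,
                          sasa_threshold = 0.20, max_steps = 20L,
                          probe = 1.4, n_points = 960L,
                          vdw = vdw_radii(),
                          reference_sasa = max_sidechain_sasa()) {
  stopifnot(d0 > 0, d0 <= dmax, step > 0,
            sasa_threshold > 0, sasa_threshold < 1, max_steps >= 1)
  structure(list(d0 = d0, dmax = dmax, step = step,
                 eligible_classes = eligible_classes,
                 include_waters = include_waters,
                 sasa_threshold = sasa_threshold,
                 max_steps = as.integer(max_steps),
                 probe = probe, n_points = as.integer(n_points),
                 vdw = vdw, reference_sasa = reference_sasa),
            class = "ptp_params")
}

site_coords <- function(x) {
  if (inherits(x, "ptp_relay_site"))
    return(list(xyz = as.matrix(x$atoms[, c("x", "y", "z")]),
                names = x$atoms$name))
  stopifnot(is.numeric(x), length(x) == 3L, all(is.finite(x)))
  list(xyz = matrix(x, nrow = 1L), names = "anchor")
}

#' Minimum heavy-atom distance between two relay sites
#'
#' The distance convention of the search: the minimum Euclidean distance
#' over all pairs of relay atoms (the anchor contributes a single point),
#' together with the atom pair realising it.
#'
#' @param a a `ptp_relay_site` or a numeric xyz point.
#' @param b a `ptp_relay_site`.
#' @return list with `distance` (Angstrom) and `pair` (two atom names).
#' @export
min_site_distance <- function(a, b) {
  ca <- site_coords(a)
  cb <- site_coords(b)
  if (nrow(cb$xyz) == 0L) stop("relay site has no relay atoms")
  best <- Inf; bi <- 1L; bj <- 1L
  for (i in seq_len(nrow(ca$xyz))) {
    d2 <- (cb$xyz[, 1] - ca$xyz[i, 1])^2 + (cb$xyz[, 2] - ca$xyz[i, 2])^2 +
      (cb$xyz[, 3] - ca$xyz[i, 3])^2
    j <- which.min(d2)
    if (d2[j] < best) { best <- d2[j]; bi <- i; bj <- j }
  }
  list(distance = unname(sqrt(best)),
       pair = c(ca$names[bi], cb$names[bj]))
}

# cutoff levels d0, d0+step, ..., capped at dmax
cutoff_levels <- function(params) {
  k <- 0:ceiling((params$dmax - params$d0) / params$step + 1e-9)
  lv <- pmin(params$d0 + k * params$step, params$dmax)
  unique(round(lv, 9))
}

# first level at which a distance qualifies
level_for <- function(d, levels) {
  i <- which(levels >= d - 1e-9)
  if (!length(i)) NA_real_ else levels[i[1L]]
}

#' Find candidate next relays around a point or site
#'
#' All unvisited eligible sites within the base cutoff `d0`, sorted by
#' distance; when none qualifies the cutoff grows by `step` until a
#' candidate appears or `dmax` is reached. Each candidate carries
#' `cutoff_used`, the first cutoff level at which it qualified.
#'
#' @param current a `ptp_relay_site` or xyz point.
#' @param sites list of `ptp_relay_site`.
#' @param visited character vector of visited site keys (`chain|resnum|icode`).
#' @param params a `ptp_params`.
#' @return data.frame with columns `index`, `distance`, `cutoff_used`,
#'   `atom_a`, `atom_b` (possibly 0 rows).
#' @export
find_candidates <- function(current, sites, visited, params) {
  idx <- seq_along(sites)
  if (length(visited))
    idx <- idx[!vapply(sites, site_key, character(1)) %in% visited]
  empty <- data.frame(index = integer(0), distance = numeric(0),
                      cutoff_used = numeric(0), atom_a = character(0),
                      atom_b = character(0), stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  md <- lapply(sites[idx], function(b) min_site_distance(current, b))
  d <- vapply(md, `[[`, numeric(1), "distance")
  levels <- cutoff_levels(params)
  lvl <- levels[which(vapply(levels, function(L) any(d <= L + 1e-9),
                             logical(1)))[1L]]
  if (is.na(lvl) || !length(lvl)) return(empty)
  keep <- which(d <= lvl + 1e-9)
  out <- data.frame(
    index = idx[keep],
    distance = d[keep],
    cutoff_used = vapply(d[keep], level_for, numeric(1), levels = levels),
    atom_a = vapply(md[keep], function(m) m$pair[1L], character(1)),
    atom_b = vapply(md[keep], function(m) m$pair[2L], character(1)),
    stringsAsFactors = FALSE
  )
  resnum <- vapply(sites[out$index], `[[`, integer(1), "resnum")
  chain <- vapply(sites[out$index], `[[`, character(1), "chain")
  out[order(out$distance, resnum, chain), , drop = FALSE]
}

resolve_anchor <- function(s, anchor) {
  if (inherits(anchor, "ptp_selector")) {
    at <- select_atom(s, anchor)
    list(point = c(at$x, at$y, at$z),
         exclude = paste(at$chain, at$resnum, at$icode, sep = "|"),
         label = sprintf("%s/%s%d%s/%s", at$resname, at$chain, at$resnum,
                         at$icode, at$name))
  } else {
    stopifnot(is.numeric(anchor), length(anchor) == 3L,
              all(is.finite(anchor)))
    list(point = as.numeric(anchor), exclude = NULL,
         label = sprintf("point(%.3f, %.3f, %.3f)", anchor[1], anchor[2],
                         anchor[3]))
  }
}

prepare_sites <- function(s, anchor_info, params,
                          table = default_relay_table()) {
  sites <- relay_sites(s, table = table,
                       eligible_classes = params$eligible_classes,
                       include_waters = params$include_waters)
  if (!is.null(anchor_info$exclude))
    sites <- sites[vapply(sites, site_key, character(1)) !=
                     anchor_info$exclude]
  sites
}

#' Trace a proton transfer pathway from anchor to surface
#'
#' Greedy nearest-first traversal: starting at the anchor, repeatedly take
#' the closest unvisited eligible relay site within the (adaptively
#' extended) cutoff, stopping as soon as the current site is
#' surface-exposed (`reached_surface`), no candidate lies within `dmax`
#' (`exhausted_cutoff`), or `max_steps` relays have been accepted
#' (`max_steps`). Distance ties (within 1e-6 Angstrom) break to the lower
#' residue number, then chain id.
#'
#' @param s a `ptp_structure`.
#' @param anchor a `ptp_selector` naming the anchor atom (its residue is
#'   excluded from the search) or a numeric xyz point — useful when the
#'   cofactor's atom naming is unknown.
#' @param params a `ptp_params`.
#' @param table relay-atom table.
#' @return object of class `ptp_pathway`: list with `anchor` (xyz),
#'   `anchor_label`, `steps` (data.frame: `step`, `chain`, `resnum`,
#'   `icode`, `resname`, `class`, `distance`, `cutoff_used`, `atom_a`,
#'   `atom_b`, `rel_sasa`), `status`, `terminal_rel_sasa`, `params`.
#' @export
trace_pathway <- function(s, anchor, params = search_params(),
                          table = default_relay_table()) {
  info <- resolve_anchor(s, anchor)
  sites <- prepare_sites(s, info, params, table)
  empty_steps <- data.frame(
    step = integer(0), chain = character(0), resnum = integer(0),
    icode = character(0), resname = character(0), class = character(0),
    distance = numeric(0), cutoff_used = numeric(0),
    atom_a = character(0), atom_b = character(0), rel_sasa = numeric(0),
    stringsAsFactors = FALSE)
  result <- function(steps, status, term) {
    structure(list(anchor = info$point, anchor_label = info$label,
                   steps = steps, status = status,
                   terminal_rel_sasa = term, params = params),
              class = "ptp_pathway")
  }
  if (!length(sites))
    return(result(empty_steps, "exhausted_cutoff", NA_real_))
  rsasa <- site_relative_sasa(s, sites, params)

  current <- info$point
  visited <- character(0)
  steps <- empty_steps
  status <- "max_steps"
  term <- NA_real_
  for (k in seq_len(params$max_steps)) {
    cand <- find_candidates(current, sites, visited, params)
    if (nrow(cand) == 0L) { status <- "exhausted_cutoff"; break }
    pick <- cand[1L, ]
    site <- sites[[pick$index]]
    visited <- c(visited, site_key(site))
    steps <- rbind(steps, data.frame(
      step = k, chain = site$chain, resnum = site$resnum,
      icode = site$icode, resname = site$resname, class = site$class,
      distance = pick$distance, cutoff_used = pick$cutoff_used,
      atom_a = pick$atom_a, atom_b = pick$atom_b,
      rel_sasa = rsasa[pick$index], stringsAsFactors = FALSE))
    term <- rsasa[pick$index]
    if (term >= params$sasa_threshold) { status <- "reached_surface"; break }
    current <- site
  }
  result(steps, status, term)
}

#' @export
print.ptp_pathway <- function(x, ...) {
  cat(sprintf("ptp_pathway from %s: %d step(s), status %s\n",
              x$anchor_label, nrow(x$steps), x$status))
  if (nrow(x$steps)) {
    lab <- sprintf("%s%s%d%s", x$steps$resname, x$steps$chain,
                   x$steps$resnum, x$steps$icode)
    cat("  ", paste(lab, collapse = " -> "), "\n", sep = "")
    cat("  distances (A): ",
        paste(formatC(x$steps$distance, format = "f", digits = 1),
              collapse = " / "), "\n", sep = "")
  }
  if (is.finite(x$terminal_rel_sasa))
    cat(sprintf("  terminal relative SASA: %.2f\n", x$terminal_rel_sasa))
  invisible(x)
}

#' Enumerate all surface-reaching relay chains (exhaustive oracle)
#'
#' Depth-first enumeration of every simple chain from the anchor whose
#' steps all lie within `dmax` and whose terminus is surface-exposed, up to
#' `max_len` steps. Exists to audit the greedy [trace_pathway()] choice;
#' guarded to small structures.
#'
#' @inheritParams trace_pathway
#' @param max_len maximum chain length.
#' @param max_sites guard on the number of eligible sites (default 40).
#' @return list of `ptp_pathway` objects sorted by (number of steps,
#'   maximum step distance).
#' @export
enumerate_pathways <- function(s, anchor, params = search_params(),
                               max_len = params$max_steps,
                               table = default_relay_table(),
                               max_sites = 40L) {
  info <- resolve_anchor(s, anchor)
  sites <- prepare_sites(s, info, params, table)
  if (length(sites) > max_sites)
    stop("too many eligible sites for exhaustive enumeration (",
         length(sites), " > ", max_sites, ")")
  if (!length(sites)) return(list())
  rsasa <- site_relative_sasa(s, sites, params)
  levels <- cutoff_levels(params)
  n <- length(sites)
  # pairwise site distances + anchor distances
  dmat <- matrix(Inf, n, n)
  pairs <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    m <- min_site_distance(sites[[i]], sites[[j]])
    dmat[i, j] <- m$distance
    pairs[[(i - 1L) * n + j]] <- m$pair
  }
  a0 <- lapply(sites, function(b) min_site_distance(info$point, b))
  d0v <- vapply(a0, `[[`, numeric(1), "distance")

  out <- list()
  path <- integer(0)
  emit <- function(path) {
    prev <- c(NA_integer_, path[-length(path)])
    dist <- c(d0v[path[1L]],
              if (length(path) > 1L)
                dmat[cbind(path[-length(path)], path[-1L])])
    pr <- lapply(seq_along(path), function(k) {
      if (k == 1L) a0[[path[1L]]]$pair
      else pairs[[(path[k - 1L] - 1L) * n + path[k]]]
    })
    steps <- data.frame(
      step = seq_along(path),
      chain = vapply(sites[path], `[[`, character(1), "chain"),
      resnum = vapply(sites[path], `[[`, integer(1), "resnum"),
      icode = vapply(sites[path], `[[`, character(1), "icode"),
      resname = vapply(sites[path], `[[`, character(1), "resname"),
      class = vapply(sites[path], `[[`, character(1), "class"),
      distance = dist,
      cutoff_used = vapply(dist, level_for, numeric(1), levels = levels),
      atom_a = vapply(pr, `[[`, character(1), 1L),
      atom_b = vapply(pr, `[[`, character(1), 2L),
      rel_sasa = rsasa[path], stringsAsFactors = FALSE)
    structure(list(anchor = info$point, anchor_label = info$label,
                   steps = steps, status = "reached_surface",
                   terminal_rel_sasa = rsasa[path[length(path)]],
                   params = params),
              class = "ptp_pathway")
  }
  recurse <- function(path) {
    last <- path[length(path)]
    if (rsasa[last] >= params$sasa_threshold)
      out[[length(out) + 1L]] <<- emit(path)
    if (length(path) >= max_len) return()
    nxt <- setdiff(which(dmat[last, ] <= params$dmax + 1e-9), path)
    for (j in nxt) recurse(c(path, j))
  }
  for (i in which(d0v <= params$dmax + 1e-9)) recurse(i)
  if (!length(out)) return(list())
  nsteps <- vapply(out, function(p) nrow(p$steps), integer(1))
  maxd <- vapply(out, function(p) max(p$steps$distance), numeric(1))
  out[order(nsteps, maxd)]
}
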