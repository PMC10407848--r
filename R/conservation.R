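# Per-group multiple sequence alignment conservation: reference-numbering
# maps, column frequencies, consensus-logo information content, and
# group-exclusive conservation calls.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a multiple sequence alignment
#'
#' FASTA or Clustal, parsed via Biostrings. Sequences are upper-cased and
#' '.' gap characters normalised to '-'.
#'
#' @param file path to the alignment; alternatively pass `text`.
#' @param text character scalar of alignment text.
#' @param format `"fasta"` or `"clustal"`.
#' @param group_label label for the sequence group (phylogenetic group)
#'   this alignment represents.
#' @return object of class `ptp_msa`: list with `group_label`, `ids`,
#'   `seqs` (character vector of aligned rows), `ncol`, and `mat`
#'   (character matrix, sequences x columns).
#' @export
read_msa <- function(file = NULL, text = NULL,
                     format = c("fasta", "clustal"), group_label = "group") {
  format <- match.arg(format)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'file' or 'text'")
  if (!is.null(text)) {
    file <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(file))
    writeLines(text, file)
  }
  aln <- Biostrings::readAAMultipleAlignment(file, format = format)
  seqs <- toupper(as.character(aln))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  new_msa(ids = names(seqs), seqs = unname(seqs), group_label = group_label)
}

new_msa <- function(ids, seqs, group_label) {
  if (length(seqs) < 2L)
    stop("alignment must contain at least 2 sequences")
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L)
    stop("ragged alignment: sequences have differing lengths")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  structure(list(group_label = group_label, ids = ids, seqs = seqs,
                 ncol = nc, mat = mat),
            class = "ptp_msa")
}

#' @export
print.ptp_msa <- function(x, ...) {
  cat(sprintf("ptp_msa '%s': %d sequences x %d columns\n",
              x$group_label, length(x$seqs), x$ncol))
  invisible(x)
}

#' Write an alignment as FASTA
#'
#' @param m a `ptp_msa`.
#' @param file output path.
#' @export
write_msa_fasta <- function(m, file) {
  ss <- Biostrings::AAStringSet(m$seqs)
  names(ss) <- m$ids
  Biostrings::writeXStringSet(ss, file, width = 80L)
  invisible(file)
}

#' Map alignment columns to reference residue numbering
#'
#' The k-th non-gap column of the reference sequence maps to reference
#' position k (1-based author numbering of the reference protein, e.g.
#' the numbering in which pathway positions are reported).
#'
#' @param m a `ptp_msa`.
#' @param ref_id sequence id of the reference within `m`.
#' @return object of class `ptp_refmap`: list with `ref_id`, `col`
#'   (alignment column indices) and `refpos` (reference positions), both
#'   strictly increasing.
#' @export
map_columns_to_reference <- function(m, ref_id) {
  i <- match(ref_id, m$ids)
  if (is.na(i)) stop("reference id '", ref_id, "' not present in alignment")
  refrow <- m$mat[i, ]
  col <- which(refrow != "-")
  structure(list(ref_id = ref_id, col = col,
                 refpos = seq_along(col)),
            class = "ptp_refmap")
}

refmap_col <- function(rm, pos) {
  i <- match(pos, rm$refpos)
  if (is.na(i)) NA_integer_ else rm$col[i]
}

#' Column residue frequencies
#'
#' Frequencies over the 20 standard amino acids among non-gap, non-X
#' symbols; gaps and 'X'/nonstandard symbols count into `gap_fraction`.
#'
#' @param m a `ptp_msa`.
#' @param col column index.
#' @return list with `freq` (named numeric over the 20 amino acids,
#'   summing to 1 unless the column is fully gapped) and `gap_fraction`.
#' @export
column_frequencies <- function(m, col) {
  if (col < 1L || col > m$ncol) stop("column index out of range: ", col)
  x <- m$mat[, col]
  ok <- x %in% AA20
  counts <- table(factor(x[ok], levels = AA20))
  n <- sum(ok)
  freq <- if (n > 0) as.numeric(counts) / n else numeric(20)
  names(freq) <- AA20
  list(freq = freq, gap_fraction = 1 - n / length(x))
}

#' Information content of a column frequency vector
#'
#' Small-sample-uncorrected Schneider-Stephens form:
#' IC = log2(20) - H with H = -sum f log2 f. An all-zero vector (fully
#' gapped column) gives 0 bits.
#'
#' @param freq numeric frequency vector summing to 1 (tolerance 1e-9) or
#'   all zero.
#' @return bits, in \[0, log2(20)\].
#' @export
information_content <- function(freq) {
  if (any(freq < 0)) stop("negative frequency")
  s <- sum(freq)
  if (s == 0) return(0)
  if (abs(s - 1) > 1e-9) stop("frequencies must sum to 1 (got ", s, ")")
  f <- freq[freq > 0]
  h <- -sum(f * log2(f))
  log2(20) - h
}

#' Per-column conservation profile of one group alignment
#'
#' For every column: residue frequencies, gap fraction, consensus residue
#' (ties to the lexicographically first, flagged), consensus fraction,
#' information content, and the occupancy-normalised logo letter height of
#' the consensus (`f * IC * (1 - gap_fraction)`).
#'
#' @param m a `ptp_msa`.
#' @return object of class `ptp_profile`: list with `group_label`, `freq`
#'   (20 x ncol matrix), and data.frame `columns` (`col`, `gap_fraction`,
#'   `consensus`, `consensus_fraction`, `consensus_tie`, `info_content`,
#'   `consensus_height`).
#' @export
conservation_profile <- function(m) {
  fr <- matrix(0, nrow = 20L, ncol = m$ncol, dimnames = list(AA20, NULL))
  gapf <- numeric(m$ncol)
  for (j in seq_len(m$ncol)) {
    cf <- column_frequencies(m, j)
    fr[, j] <- cf$freq
    gapf[j] <- cf$gap_fraction
  }
  cons_i <- apply(fr, 2L, which.max)
  cons <- AA20[cons_i]
  consf <- fr[cbind(cons_i, seq_len(m$ncol))]
  tie <- vapply(seq_len(m$ncol), function(j)
    sum(abs(fr[, j] - consf[j]) < 1e-12) > 1L & consf[j] > 0, logical(1))
  ic <- apply(fr, 2L, information_content)
  structure(list(
    group_label = m$group_label, freq = fr,
    columns = data.frame(
      col = seq_len(m$ncol), gap_fraction = gapf, consensus = cons,
      consensus_fraction = consf, consensus_tie = tie,
      info_content = ic,
      consensus_height = consf * ic * (1 - gapf),
      stringsAsFactors = FALSE)
  ), class = "ptp_profile")
}

#' Hydroxyl preference at a position
#'
#' Combined serine + threonine frequency of a column, used to describe
#' positions conserved as hydroxyl-bearing residues rather than as one
#' specific amino acid.
#'
#' @param profile a `ptp_profile`.
#' @param col alignment column index.
#' @return fraction in \[0, 1\].
#' @export
hydroxyl_preference <- function(profile, col) {
  unname(profile$freq["S", col] + profile$freq["T", col])
}

#' Group-exclusive conservation at one reference position
#'
#' A position is called exclusive to `target_group` when the target
#' group's consensus fraction reaches `c_high` and every other group
#' either falls below `c_high` or holds a different consensus residue.
#' The score is the target consensus fraction minus the maximum frequency
#' of that same residue in any other group.
#'
#' @param profiles named list of `ptp_profile`, one per group. The group
#'   alignments must share one column coordinate system (e.g. per-group
#'   slices of a master alignment, or equal-length synthetic alignments).
#' @param refmap a `ptp_refmap` built from the reference sequence (which
#'   lives in the target group's alignment); its column indices are
#'   applied to every group.
#' @param pos reference position (must be mapped).
#' @param target_group name of the group tested for exclusivity.
#' @param c_high consensus-fraction threshold for "highly conserved"
#'   (default 0.9).
#' @return list: `pos`, `comparable` (FALSE when the mapped column is
#'   absent from some group's alignment), `exclusive` (NA when not
#'   comparable), `score`, `target_consensus`, `target_fraction`,
#'   `others` (data.frame).
#' @export
group_exclusive_conservation <- function(profiles, refmap, pos,
                                         target_group, c_high = 0.9) {
  stopifnot(target_group %in% names(profiles), length(profiles) >= 2L)
  tcol <- refmap_col(refmap, pos)
  if (is.na(tcol))
    stop("position ", pos, " is not mapped by the reference map")
  tp <- profiles[[target_group]]
  trow <- tp$columns[tcol, ]
  other <- setdiff(names(profiles), target_group)
  in_range <- vapply(other, function(g)
    tcol <= nrow(profiles[[g]]$columns), logical(1))
  if (!all(in_range)) {
    return(list(pos = pos, comparable = FALSE, exclusive = NA,
                score = NA_real_, target_consensus = trow$consensus,
                target_fraction = trow$consensus_fraction, others = NULL))
  }
  odf <- data.frame(
    group = other,
    consensus = vapply(other, function(g)
      profiles[[g]]$columns$consensus[tcol], character(1)),
    consensus_fraction = vapply(other, function(g)
      profiles[[g]]$columns$consensus_fraction[tcol], numeric(1)),
    same_residue_fraction = vapply(other, function(g)
      profiles[[g]]$freq[trow$consensus, tcol], numeric(1)),
    stringsAsFactors = FALSE)
  excl <- trow$consensus_fraction >= c_high &&
    all(odf$consensus_fraction < c_high | odf$consensus != trow$consensus)
  list(pos = pos, comparable = TRUE, exclusive = excl,
       score = trow$consensus_fraction - max(odf$same_residue_fraction),
       target_consensus = trow$consensus,
       target_fraction = trow$consensus_fraction, others = odf)
}

#' Cross-group conservation report over reference positions
#'
#' Per reference position and group: consensus statistics, information
#' content, hydroxyl (S+T) fraction, plus the exclusivity call for the
#' target group.
#'
#' @param msas named list of `ptp_msa` per group, sharing one column
#'   coordinate system (per-group slices of a master alignment, or
#'   equal-length alignments).
#' @param ref_id reference sequence id, present in the target group's
#'   alignment; its non-gap columns define the reference numbering applied
#'   to every group.
#' @param positions integer vector of reference positions (default: all
#'   mapped positions of the target group).
#' @param target_group group tested for exclusive conservation.
#' @param c_high "highly conserved" threshold (default 0.9).
#' @param c_moderate "moderately conserved" threshold (default 0.5).
#' @return object of class `ptp_group_report`: list with `per_position`
#'   data.frame (`refpos`, `group`, `consensus`, `consensus_fraction`,
#'   `conservation_level`, `info_content`, `gap_fraction`,
#'   `hydroxyl_fraction`), `exclusivity` data.frame (`refpos`,
#'   `comparable`, `exclusive`, `score`, `target_consensus`,
#'   `target_fraction`), and the thresholds.
#' @export
group_conservation_report <- function(msas, ref_id, positions = NULL,
                                      target_group, c_high = 0.9,
                                      c_moderate = 0.5) {
  stopifnot(target_group %in% names(msas))
  if (!ref_id %in% msas[[target_group]]$ids)
    stop("reference id '", ref_id, "' absent from target group alignment")
  profiles <- lapply(msas, conservation_profile)
  refmap <- map_columns_to_reference(msas[[target_group]], ref_id)
  if (is.null(positions)) positions <- refmap$refpos

  rows <- list(); exrows <- list()
  for (pos in positions) {
    ex <- group_exclusive_conservation(profiles, refmap, pos,
                                       target_group, c_high)
    exrows[[length(exrows) + 1L]] <- data.frame(
      refpos = pos, comparable = ex$comparable, exclusive = ex$exclusive,
      score = ex$score, target_consensus = ex$target_consensus,
      target_fraction = ex$target_fraction, stringsAsFactors = FALSE)
    cl <- refmap_col(refmap, pos)
    for (g in names(msas)) {
      if (cl > nrow(profiles[[g]]$columns)) next
      row <- profiles[[g]]$columns[cl, ]
      lvl <- if (row$consensus_fraction >= c_high) "high"
             else if (row$consensus_fraction >= c_moderate) "moderate"
             else "low"
      rows[[length(rows) + 1L]] <- data.frame(
        refpos = pos, group = g, consensus = row$consensus,
        consensus_fraction = row$consensus_fraction,
        conservation_level = lvl, info_content = row$info_content,
        gap_fraction = row$gap_fraction,
        hydroxyl_fraction = hydroxyl_preference(profiles[[g]], cl),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(per_position = do.call(rbind, rows),
                 exclusivity = do.call(rbind, exrows),
                 target_group = target_group, ref_id = ref_id,
                 c_high = c_high, c_moderate = c_moderate),
            class = "ptp_group_report")
}

#' @export
print.ptp_group_report <- function(x, ...) {
  ne <- sum(x$exclusivity$exclusive %in% TRUE)
  cat(sprintf("ptp_group_report: %d position(s), target group '%s', %d exclusive call(s)\n",
              nrow(x$exclusivity), x$target_group, ne))
  invisible(x)
}
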