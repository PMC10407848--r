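# End-to-end orchestration: structure -> pathway -> distance table ->
# conservation of pathway positions, with machine-readable reports.

#' Build a pipeline run configuration
#'
#' @param structure_path PDB file of the structure to search.
#' @param anchor either a `ptp_selector` or a numeric xyz point (the
#'   explicit-point form covers models whose cofactor atom naming is
#'   unknown).
#' @param params a [search_params()].
#' @param msa_inputs optional data.frame with columns `group`, `path`,
#'   `format` (`fasta`/`clustal`); when given, conservation is evaluated
#'   at every pathway residue's reference position.
#' @param ref_id reference sequence id for residue numbering (required
#'   with `msa_inputs`).
#' @param target_group group tested for exclusive conservation (required
#'   with `msa_inputs`).
#' @param c_high,c_moderate conservation thresholds.
#' @param output_dir directory for `report.json`, `pathway.tsv` and
#'   `conservation.tsv` (created if missing); `NULL` writes no files.
#' @return list of class `ptp_run_config`.
#' @export
run_config <- function(structure_path, anchor, params = search_params(),
                       msa_inputs = NULL, ref_id = NULL,
                       target_group = NULL, c_high = 0.9, c_moderate = 0.5,
                       output_dir = NULL) {
  if (!file.exists(structure_path))
    stop("structure file not found: ", structure_path)
  if (!is.null(msa_inputs)) {
    stopifnot(all(c("group", "path", "format") %in% names(msa_inputs)),
              !is.null(ref_id), !is.null(target_group))
    missing <- msa_inputs$path[!file.exists(msa_inputs$path)]
    if (length(missing))
      stop("alignment file not found: ", paste(missing, collapse = ", "))
  }
  structure(list(structure_path = structure_path, anchor = anchor,
                 params = params, msa_inputs = msa_inputs,
                 ref_id = ref_id, target_group = target_group,
                 c_high = c_high, c_moderate = c_moderate,
                 output_dir = output_dir),
            class = "ptp_run_config")
}

config_echo <- function(config) {
  p <- config$params
  list(structure_path = config$structure_path,
       anchor = if (inherits(config$anchor, "ptp_selector"))
         unclass(config$anchor) else as.numeric(config$anchor),
       params = list(d0 = p$d0, dmax = p$dmax, step = p$step,
                     eligible_classes = p$eligible_classes,
                     include_waters = p$include_waters,
                     sasa_threshold = p$sasa_threshold,
                     max_steps = p$max_steps, probe = p$probe,
                     n_points = p$n_points),
       msa_inputs = config$msa_inputs, ref_id = config$ref_id,
       target_group = config$target_group,
       c_high = config$c_high, c_moderate = config$c_moderate)
}

#' Run the full pathway + conservation pipeline
#'
#' Reads the structure, traces the relay pathway from the anchor, builds
#' the distance table, and — when alignments are configured — evaluates
#' cross-group conservation at each pathway residue's reference position.
#' Reports embed the effective configuration and md5 checksums of all
#' inputs, so identical inputs give identical reports.
#'
#' @param config a [run_config()].
#' @return object of class `ptp_run_report`: list with `pathway`
#'   (`ptp_pathway`), `distance_table`, `conservation`
#'   (`ptp_group_report` or `NULL`), `status` (`"reached_surface"` etc.),
#'   `exit_status` (0 = complete pathway, 2 = incomplete), `provenance`.
#'   Written files (if `output_dir` set): `report.json`, `pathway.tsv`,
#'   `conservation.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ptp_run_config"))
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    s <- read_pdb(file = config$structure_path)
    pathway <- trace_pathway(s, config$anchor, config$params)
    dtable <- pathway_distance_table(pathway)

    conservation <- NULL
    if (!is.null(config$msa_inputs) && nrow(pathway$steps) > 0L) {
      msas <- list()
      for (i in seq_len(nrow(config$msa_inputs))) {
        m <- config$msa_inputs[i, ]
        msas[[m$group]] <- read_msa(file = m$path, format = m$format,
                                    group_label = m$group)
      }
      conservation <- group_conservation_report(
        msas, ref_id = config$ref_id,
        positions = pathway$steps$resnum,
        target_group = config$target_group,
        c_high = config$c_high, c_moderate = config$c_moderate)
    }

    input_files <- c(config$structure_path,
                     if (!is.null(config$msa_inputs)) config$msa_inputs$path)
    provenance <- list(
      package = "protonpath",
      version = as.character(utils::packageVersion("protonpath")),
      config = config_echo(config),
      input_checksums = as.list(tools::md5sum(input_files)))

    report <- structure(list(
      pathway = pathway, distance_table = dtable,
      conservation = conservation, status = pathway$status,
      exit_status = if (pathway$status == "reached_surface") 0L else 2L,
      provenance = provenance), class = "ptp_run_report")

    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      jf <- file.path(config$output_dir, "report.json")
      written <- c(written, jf)
      jsonlite::write_json(report_as_list(report), jf, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
      pf <- file.path(config$output_dir, "pathway.tsv")
      written <- c(written, pf)
      utils::write.table(dtable, pf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if (!is.null(conservation)) {
        cf <- file.path(config$output_dir, "conservation.tsv")
        written <- c(written, cf)
        utils::write.table(conservation$per_position, cf, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    report
  }, error = on_fail)
}

report_as_list <- function(report) {
  p <- report$pathway
  list(
    status = report$status,
    exit_status = report$exit_status,
    anchor = as.numeric(p$anchor),
    anchor_label = p$anchor_label,
    terminal_rel_sasa = p$terminal_rel_sasa,
    steps = p$steps,
    distance_table = report$distance_table,
    conservation = if (!is.null(report$conservation)) list(
      target_group = report$conservation$target_group,
      ref_id = report$conservation$ref_id,
      c_high = report$conservation$c_high,
      c_moderate = report$conservation$c_moderate,
      per_position = report$conservation$per_position,
      exclusivity = report$conservation$exclusivity),
    provenance = report$provenance)
}

#' @export
print.ptp_run_report <- function(x, ...) {
  print(x$pathway)
  if (!is.null(x$conservation)) print(x$conservation)
  cat(sprintf("exit status: %d\n", x$exit_status))
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File schema mirrors [run_config()]: `structure_path`, `anchor` (either
#' `{chain, resnum, atom}` or `[x, y, z]`), optional `params` overrides,
#' optional `msa_inputs` (list of `{group, path, format}`), `ref_id`,
#' `target_group`, `c_high`, `c_moderate`, `output_dir`. Relative paths
#' are resolved against the config file's directory.
#'
#' @param path config file.
#' @return a `ptp_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  anchor <- raw$anchor
  if (is.list(anchor) && !is.null(anchor$resnum))
    anchor <- atom_selector(anchor$chain %||% "*", anchor$resnum,
                            anchor$atom, anchor$icode %||% "")
  else anchor <- as.numeric(unlist(anchor))
  params <- do.call(search_params, raw$params %||% list())
  msa <- raw$msa_inputs
  if (!is.null(msa)) {
    if (!is.data.frame(msa))
      msa <- do.call(rbind, lapply(msa, function(m)
        as.data.frame(m, stringsAsFactors = FALSE)))
    msa$path <- rel(msa$path)
  }
  run_config(structure_path = rel(raw$structure_path), anchor = anchor,
             params = params, msa_inputs = msa, ref_id = raw$ref_id,
             target_group = raw$target_group,
             c_high = raw$c_high %||% 0.9,
             c_moderate = raw$c_moderate %||% 0.5,
             output_dir = raw$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
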