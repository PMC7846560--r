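# End-to-end orchestration: parse -> pairwise align -> subset filter ->
# star MSA -> anchor profile -> PVR table -> sigma_abs -> geometry reports.

#' Pipeline configuration
#'
#' Defaults reproduce the standard thresholds of the analysis: anchor RMSD
#' cut-off 2.0 Angstrom, PVR length-range cut 10 residues, and the
#' comparability rule "more than 220 aligned residues or RMSD below 3".
#'
#' @param inputs Character vector of structure file paths, or a list of
#'   `pvr_structure` objects.
#' @param reference Id of the reference structure (for paths: file base
#'   name).
#' @param chains Optional named vector mapping structure id to chain.
#' @param rmsd_cut,range_cut,min_run Anchor/PVR thresholds
#'   (see [call_anchors()], [delineate_pvrs()]).
#' @param min_aligned,max_rmsd Subset-filter thresholds
#'   (see [select_subset()]); set `filter = FALSE` to disable filtering.
#' @param filter Apply the subset filter? Default `TRUE`.
#' @param norm TM-score normalisation (see [align_pair()]).
#' @param metal_cutoff Metal coordination cutoff in Angstrom.
#' @param hbond_dmax Hydrogen-bond heavy-atom distance cutoff.
#' @param probe SASA probe radius.
#' @param assembly Optional assembly id of the reference; when set, interface
#'   area and hydrogen bonds are reported for every chain pair of that
#'   assembly.
#' @param out_dir Optional output directory for TSV/JSON result files.
#' @param seed Optional integer seed recorded in the provenance (the analysis
#'   itself is deterministic).
#' @return A `pvr_config` list.
#' @export
pvr_config <- function(inputs, reference, chains = NULL,
                       rmsd_cut = 2.0, range_cut = 10, min_run = 1L,
                       min_aligned = 220, max_rmsd = 3.0, filter = TRUE,
                       norm = "reference", metal_cutoff = 3.0,
                       hbond_dmax = 3.5, probe = 1.4, assembly = NULL,
                       out_dir = NULL, seed = NULL) {
  structure(list(inputs = inputs, reference = reference, chains = chains,
                 rmsd_cut = rmsd_cut, range_cut = range_cut,
                 min_run = min_run, min_aligned = min_aligned,
                 max_rmsd = max_rmsd, filter = filter, norm = norm,
                 metal_cutoff = metal_cutoff, hbond_dmax = hbond_dmax,
                 probe = probe, assembly = assembly, out_dir = out_dir,
                 seed = seed),
            class = "pvr_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields of [pvr_config()].
#' @return A `pvr_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pvr_config, y)
}

#' Run the full PVR analysis pipeline
#'
#' Deterministic given its configuration. Per-structure failures (parse or
#' alignment) are reported as warnings and the structure is dropped; a
#' reference failure is fatal, as is an empty post-filter set.
#'
#' @param config A `pvr_config`, or a path to a YAML file of its fields.
#' @return A result bundle: `pairwise` (summary table), `alignments`, `msa`,
#'   `profile`, `anchors`, `pvr_table`, `report`, `sites` (metal sites per
#'   structure), `interfaces`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  checksums <- NULL
  if (is.character(cfg$inputs)) {
    checksums <- tryCatch(tools::md5sum(cfg$inputs), error = function(e) NULL)
    structures <- list()
    for (p in cfg$inputs) {
      s <- tryCatch(read_structure(p), error = function(e) {
        warning("skipping ", p, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(s)) structures[[s$id]] <- s
    }
  } else {
    structures <- cfg$inputs
    names(structures) <- vapply(structures, `[[`, character(1), "id")
  }
  if (!cfg$reference %in% names(structures))
    stop("reference ", sQuote(cfg$reference), " unavailable (parse failure?)")
  ref <- structures[[cfg$reference]]
  ref_trace <- ca_trace(ref, cfg$chains[cfg$reference])
  others <- setdiff(names(structures), cfg$reference)
  alignments <- list()
  for (id in others) {
    al <- tryCatch(
      align_pair(ref_trace, ca_trace(structures[[id]], cfg$chains[id]),
                 norm = cfg$norm),
      error = function(e) {
        warning("alignment vs ", id, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(al)) alignments[[id]] <- al
  }
  pairwise <- data.frame(
    structure_id = names(alignments),
    n_aligned = vapply(alignments, `[[`, numeric(1), "n_aligned"),
    rmsd = vapply(alignments, `[[`, numeric(1), "rmsd"),
    tm_score = vapply(alignments, `[[`, numeric(1), "tm_score"),
    seq_identity = vapply(alignments, `[[`, numeric(1), "seq_identity"),
    row.names = NULL, stringsAsFactors = FALSE)
  kept <- if (cfg$filter)
    select_subset(alignments, cfg$min_aligned, cfg$max_rmsd)
  else alignments
  pairwise$kept <- pairwise$structure_id %in% names(kept)
  if (!length(kept))
    stop("no structure passes the subset filter (>", cfg$min_aligned,
         " aligned residues or RMSD < ", cfg$max_rmsd, ")")
  members <- c(cfg$reference, names(kept))
  msa <- star_align(structures[members], cfg$reference, chains = cfg$chains,
                    alignments = kept, norm = cfg$norm)
  profile <- column_profile(msa)
  anchors <- call_anchors(profile, rmsd_cut = cfg$rmsd_cut,
                          min_run = cfg$min_run)
  pvr_table <- delineate_pvrs(msa, anchors, range_cut = cfg$range_cut)
  report <- pvr_report(pvr_table, msa)
  sites <- lapply(structures[members], find_metal_sites,
                  cutoff = cfg$metal_cutoff)
  interfaces <- list()
  if (!is.null(cfg$assembly)) {
    asm <- build_assembly(ref, cfg$assembly)
    chs <- chain_ids(asm)
    if (length(chs) > 1) {
      combos <- utils::combn(chs, 2, simplify = FALSE)
      interfaces <- lapply(combos, function(pr) {
        hb <- count_interface_hbonds(asm, pr, d_max = cfg$hbond_dmax,
                                     metal_cutoff = cfg$metal_cutoff)
        list(chains = pr,
             buried_area = interface_area(asm, pr, probe = cfg$probe),
             hbond_count = hb$hbond_count, hbonds = hb$hbonds)
      })
    }
  }
  provenance <- list(
    package = "pvrscan",
    version = as.character(utils::packageVersion("pvrscan")),
    reference = cfg$reference,
    thresholds = cfg[c("rmsd_cut", "range_cut", "min_run", "min_aligned",
                       "max_rmsd", "metal_cutoff", "hbond_dmax", "probe")],
    norm = cfg$norm, seed = cfg$seed,
    inputs = names(structures),
    input_md5 = as.list(checksums))
  bundle <- list(pairwise = pairwise, alignments = alignments, msa = msa,
                 profile = profile, anchors = anchors, pvr_table = pvr_table,
                 report = report, sites = sites, interfaces = interfaces,
                 provenance = provenance)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wtsv(bundle$pairwise, "pairwise.tsv")
  prof <- bundle$profile
  prof$is_anchor <- prof$column %in% bundle$anchors
  wtsv(prof, "anchors.tsv")
  wtsv(bundle$report$segments, "pvrs.tsv")
  wtsv(data.frame(structure_id = names(bundle$report$sigma_abs),
                  sigma_abs = as.numeric(bundle$report$sigma_abs)),
       "sigma_abs.tsv")
  jsonlite::write_json(bundle$sites, file.path(out_dir, "sites.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(bundle$interfaces,
                       file.path(out_dir, "interfaces.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
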