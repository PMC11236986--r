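# Orchestration of the two workflows: library triage (activity filter ->
# fingerprints -> clustering -> representatives -> similarity search ->
# PAINS/Ro5 -> scaffold mining -> overlap) and structure profiling
# (contacts -> aromatic interactions -> cavity occupancy -> summary ->
# residue deviations). Stage products are flat TSV files plus a JSON
# manifest recording every parameter and the record counts surviving each
# stage, so runs are inspectable and diffable.

#' Default run configuration
#'
#' Every parameter with an established value in the source workflow keeps it
#' as the default: fingerprint radius 3 over 2048 bits, similarity threshold
#' 0.3, activity cutoff IC50 < 500 nM, scaffold frequency thresholds 5
#' (reference set) and 20 (candidate library), group-outlier tolerances
#' 1.0 kcal/mol (dG) and 0.5 (ligand efficiency), docking-vs-experiment
#' tolerance 2.0 kcal/mol. The Butina distance cutoff (0.4) and the
#' geometric cutoffs follow common practice and are recorded in every
#' manifest.
#'
#' @param ... overrides for any configuration entry.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    fp_radius = 3L, fp_nbits = 2048L,
    similarity_threshold = 0.3,
    butina_cutoff = 0.4,
    ic50_threshold_nM = 500,
    min_count_reference = 5L, min_count_candidates = 20L,
    apply_pains = TRUE, apply_ro5 = TRUE,
    temperature_K = 298.15,
    dg_tol = 1.0, le_tol = 0.5, score_exp_tol = 2.0,
    hbond_max = 3.5, contact_max = 4.0,
    d_stack_max = 5.5, angle_parallel_max = 30,
    offset_parallel_max = 1.5, angle_t_min = 60,
    cavity_capture = 4.0,
    salt_strip = TRUE,
    seed = 1L)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(cfg)))
  utils::modifyList(cfg, ov)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the library-triage workflow
#'
#' Stage order: activity filtering of the reference set, fingerprinting,
#' Butina clustering, representative selection, similarity search of the
#' candidate library against the representatives, PAINS and rule-of-five
#' filtering of the hits, scaffold frequency mining of both sets, and
#' scaffold overlap. Optionally, per-scaffold docking statistics when a
#' score table is supplied. Every stage's parameters and input/output counts
#' go into the manifest; rejected records are warned about, never silently
#' dropped.
#'
#' @param reference list with \code{molecules} and \code{activities} (as
#'   from \code{\link{read_smiles_table}} or \code{\link{gen_library}}).
#' @param candidates list of candidate \code{molecule}s (may be empty).
#' @param config from \code{\link{default_config}}.
#' @param out_dir output directory for TSV reports and the manifest; created
#'   if needed. \code{NULL} skips writing.
#' @param top_k number of cluster representatives (default: all clusters).
#' @param scores optional docking score table (\code{id}, \code{score},
#'   \code{scaffold}, \code{heavy_atoms}) for the statistics stage.
#' @return list with \code{actives}, \code{assignment},
#'   \code{representatives}, \code{hits}, \code{clean_hits} (ids surviving
#'   PAINS/Ro5), \code{scaffolds_reference}, \code{scaffolds_candidates},
#'   \code{overlap}, optional \code{docking_stats}, and \code{manifest}.
#' @export
run_triage <- function(reference, candidates, config = default_config(),
                       out_dir = NULL, top_k = NULL, scores = NULL) {
  manifest <- list(workflow = "triage", config = config,
                   temperature_note = paste0(
                     "dG from IC50 at T = ", config$temperature_K,
                     " K, R = 1.987e-3 kcal/(mol K), Kd taken equal to IC50"),
                   stages = list())
  note <- function(stage, n_in, n_out, extra = NULL) {
    manifest$stages[[stage]] <<- c(list(n_in = n_in, n_out = n_out), extra)
  }

  stage <- "filter_actives"
  actives <- tryCatch(
    filter_actives(reference$activities, config$ic50_threshold_nM),
    error = function(e) stop("stage ", stage, " failed: ",
                             conditionMessage(e)))
  note(stage, nrow(reference$activities), nrow(actives))

  ref_ids <- vapply(reference$molecules, function(m) m$id, "")
  ref_mols <- reference$molecules[ref_ids %in% actives$compound_id]

  stage <- "fingerprint"
  fps <- lapply(ref_mols, circular_fingerprint,
                radius = config$fp_radius, nbits = config$fp_nbits)
  note(stage, length(ref_mols), length(fps),
       list(salt_stripped = sum(vapply(ref_mols, function(m)
         m$n_fragments_stripped, integer(1)) > 0)))

  stage <- "butina_cluster"
  assignment <- butina_cluster(fps, cutoff = config$butina_cutoff,
                               ids = vapply(ref_mols, function(m) m$id, ""))
  note(stage, length(fps), length(assignment$clusters))

  stage <- "select_representatives"
  if (is.null(top_k)) top_k <- length(assignment$clusters)
  representatives <- select_representatives(assignment, top_k)
  note(stage, length(assignment$clusters), length(representatives))

  stage <- "similarity_search"
  rep_mols <- ref_mols[match(representatives,
                             vapply(ref_mols, function(m) m$id, ""))]
  hits <- if (length(candidates)) {
    similarity_search(rep_mols, candidates,
                      threshold = config$similarity_threshold,
                      radius = config$fp_radius, nbits = config$fp_nbits)
  } else {
    data.frame(candidate_id = character(0), reference_id = character(0),
               similarity = numeric(0), stringsAsFactors = FALSE)
  }
  note(stage, length(candidates), nrow(hits))

  stage <- "pains_ro5"
  cand_ids <- vapply(candidates, function(m) m$id, "")
  hit_mols <- candidates[cand_ids %in% hits$candidate_id]
  clean_hits <- character(0)
  pains <- if (config$apply_pains) load_pains_patterns() else NULL
  for (m in hit_mols) {
    if (config$apply_pains && length(pains_match(m, pains))) next
    if (config$apply_ro5 && !ro5_pass(descriptors(m))) next
    clean_hits <- c(clean_hits, m$id)
  }
  note(stage, length(hit_mols), length(clean_hits))

  stage <- "scaffold_frequency"
  scaffolds_reference <- scaffold_frequency(ref_mols,
                                            config$min_count_reference)
  clean_mols <- hit_mols[vapply(hit_mols, function(m) m$id, "") %in%
                         clean_hits]
  scaffolds_candidates <- scaffold_frequency(clean_mols,
                                             config$min_count_candidates)
  note(stage, length(ref_mols) + length(clean_mols),
       nrow(scaffolds_reference) + nrow(scaffolds_candidates),
       list(n_acyclic_reference = attr(scaffolds_reference, "n_acyclic"),
            n_acyclic_candidates = attr(scaffolds_candidates, "n_acyclic")))

  stage <- "scaffold_overlap"
  overlap <- scaffold_overlap(scaffolds_reference, scaffolds_candidates)
  note(stage, nrow(scaffolds_reference) + nrow(scaffolds_candidates),
       nrow(overlap))

  docking_stats <- NULL
  if (!is.null(scores)) {
    stage <- "docking_stats"
    docking_stats <- scaffold_group_stats(scores, dg_tol = config$dg_tol,
                                          le_tol = config$le_tol)
    note(stage, nrow(scores), nrow(docking_stats$stats))
  }

  res <- list(actives = actives, assignment = assignment,
              representatives = representatives, hits = hits,
              clean_hits = clean_hits,
              scaffolds_reference = scaffolds_reference,
              scaffolds_candidates = scaffolds_candidates,
              overlap = overlap, docking_stats = docking_stats,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cl <- data.frame(
      compound_id = unlist(assignment$clusters),
      cluster_id = rep(seq_along(assignment$clusters),
                       lengths(assignment$clusters)),
      stringsAsFactors = FALSE)
    cl$is_centroid <- cl$compound_id %in% assignment$centroids
    write_tsv(cl, file.path(out_dir, "clusters.tsv"))
    write_tsv(hits, file.path(out_dir, "hits.tsv"))
    write_scaffold_table(scaffolds_reference,
                         file.path(out_dir, "scaffolds_reference.tsv"))
    write_scaffold_table(scaffolds_candidates,
                         file.path(out_dir, "scaffolds_candidates.tsv"))
    write_tsv(overlap, file.path(out_dir, "scaffold_overlap.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Run the structure-profiling workflow
#'
#' For each complex: close contacts, aromatic interactions, cavity occupancy
#' and the per-ligand interaction summary; with two or more structures, the
#' catalytic-residue deviation table after C-alpha superposition on the
#' first structure.
#'
#' @param complexes list of \code{structure_complex} objects, or a character
#'   vector of PDB paths (then \code{ligand_selector} is required).
#' @param config from \code{\link{default_config}}.
#' @param ligand_selector HET code / chain passed to
#'   \code{\link{read_complex}} when paths are given.
#' @param cavities cavity definitions (default
#'   \code{\link{default_cavities}()}).
#' @param out_dir optional output directory for TSV reports + manifest.
#' @return list with \code{summary} (one row per complex: counts and cavity
#'   criterion), \code{contacts}, \code{aromatics} (per-complex lists),
#'   \code{deviations} (or \code{NULL}), and \code{manifest}.
#' @export
run_profile <- function(complexes, config = default_config(),
                        ligand_selector = NULL,
                        cavities = default_cavities(), out_dir = NULL) {
  if (is.character(complexes)) {
    stopifnot(!is.null(ligand_selector))
    complexes <- lapply(complexes, read_complex,
                        ligand_selector = ligand_selector)
  }
  stopifnot(length(complexes) >= 1L)
  manifest <- list(workflow = "profile", config = config, stages = list())

  contacts <- list(); aromatics <- list(); rows <- list()
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]
    label <- basename(cx$metadata$source %||% paste0("complex", i))
    cc <- close_contacts(cx, config$hbond_max, config$contact_max)
    ar <- aromatic_interactions(cx, config$d_stack_max,
                                config$angle_parallel_max,
                                config$offset_parallel_max,
                                config$angle_t_min)
    occ <- tryCatch(cavity_occupancy(cx, cavities, config$cavity_capture),
                    error = function(e) NULL)
    contacts[[label]] <- cc
    aromatics[[label]] <- ar
    rows[[i]] <- data.frame(
      complex = label,
      n_close_contacts = nrow(cc),
      n_hbonds = sum(cc$class == "hydrogen_bond"),
      n_aromatic = sum(ar$class != "unclassified"),
      cavities_occupied = if (is.null(occ)) NA_integer_
                          else length(occ$occupied),
      two_of_three = if (is.null(occ)) NA else occ$two_of_three,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  manifest$stages$profile <- list(n_in = length(complexes),
                                  n_out = nrow(summary))

  deviations <- NULL
  if (length(complexes) >= 2L) {
    deviations <- residue_deviations(complexes)
    manifest$stages$residue_deviations <- list(
      n_in = length(complexes), n_out = nrow(deviations),
      n_missing = length(attr(deviations, "missing")))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(summary, file.path(out_dir, "interaction_summary.tsv"))
    for (label in names(contacts)) {
      write_tsv(contacts[[label]],
                file.path(out_dir, paste0("contacts_", label, ".tsv")))
    }
    if (!is.null(deviations)) {
      dv <- cbind(residue = rownames(deviations), deviations)
      write_tsv(dv, file.path(out_dir, "residue_deviations.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(summary = summary, contacts = contacts, aromatics = aromatics,
       deviations = deviations, manifest = manifest)
}
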