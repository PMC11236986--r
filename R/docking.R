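# Ingestion and statistics of externally produced docking results: poses
# with score tags, pose-vs-crystal RMSD, score-vs-experiment comparison, and
# per-scaffold boxplot statistics.

#' Read docking results from an SDF with score tags
#'
#' One result per pose; poses are ranked by score ascending (more negative =
#' better). The score lives in a named SDF data field
#' (default \code{"minimizedAffinity"}, the Gnina/Vina convention).
#'
#' @param file SDF file path.
#' @param score_tag name of the score data field.
#' @param scaffold_tag optional data field holding a scaffold label.
#' @return list of \code{docking_result}: each a list with \code{ligand_id},
#'   \code{coords} (heavy-atom matrix, rownames element+index),
#'   \code{score} (kcal/mol), \code{rank}, \code{scaffold}.
#' @export
read_results <- function(file, score_tag = "minimizedAffinity",
                         scaffold_tag = NULL) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(file))
  n <- length(sdfs)
  if (!n) stop("no molecules in ", file)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    sdf <- sdfs[[i]]
    db <- ChemmineR::datablock(sdf)
    if (!score_tag %in% names(db)) {
      stop("score tag ", sQuote(score_tag), " absent; available tags: ",
           if (length(db)) paste(names(db), collapse = ", ") else "(none)")
    }
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    keep <- el != "H"
    coords <- ab[keep, 1:3, drop = FALSE]
    rownames(coords) <- paste0(el[keep], seq_len(sum(keep)))
    res[[i]] <- structure(list(
      ligand_id = ChemmineR::sdfid(sdf),
      coords = coords,
      score = as.numeric(db[[score_tag]]),
      rank = NA_integer_,
      scaffold = if (!is.null(scaffold_tag) && scaffold_tag %in% names(db))
        db[[scaffold_tag]] else NA_character_
    ), class = "docking_result")
  }
  scores <- vapply(res, `[[`, numeric(1), "score")
  ord <- order(scores)   # stable: ties keep file order
  res <- res[ord]
  for (i in seq_along(res)) res[[i]]$rank <- i
  res
}

#' Read a docking score table (TSV)
#'
#' @param file TSV with columns \code{id}, \code{score} and optionally
#'   \code{scaffold}, \code{heavy_atoms}.
#' @return data frame, ranked by score ascending, stable for ties.
#' @export
read_score_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "score") %in% names(df)))
  df[order(df$score), , drop = FALSE]
}

#' Heavy-atom RMSD of a docked pose against a reference position
#'
#' Direct (non-superposed) RMSD: docked and crystal poses share the receptor
#' frame, so no fitting is applied. Atoms are paired by name (rownames).
#' Symmetry-equivalent atom renumbering is not corrected for; reference and
#' pose are expected to come from the same topology.
#'
#' @param pose a \code{docking_result} or a coordinate matrix with rownames.
#' @param reference coordinate matrix with rownames matching the pose.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose, reference) {
  coords <- if (inherits(pose, "docking_result")) pose$coords else pose
  stopifnot(is.matrix(coords), is.matrix(reference))
  if (is.null(rownames(coords)) || is.null(rownames(reference))) {
    stop("pose_rmsd pairs atoms by name: both matrices need rownames")
  }
  if (!setequal(rownames(coords), rownames(reference)) ||
      nrow(coords) != nrow(reference)) {
    stop("atom name mismatch between pose and reference")
  }
  ref <- reference[rownames(coords), , drop = FALSE]
  sqrt(mean(rowSums((coords - ref)^2)))
}

#' Compare docking scores with experiment-derived binding free energies
#'
#' Docking scores are treated as binding free energies in kcal/mol. Each
#' shared compound gets its difference (dock - experiment); compounds whose
#' absolute difference exceeds \code{tol} are flagged.
#'
#' @param dock data frame (\code{id}, \code{score}).
#' @param exp data frame (\code{id}, \code{dg}).
#' @param tol agreement tolerance, kcal/mol (default 2.0).
#' @return data frame \code{id}, \code{score}, \code{dg}, \code{diff},
#'   \code{flagged}; attribute \code{max_abs_diff}.
#' @export
score_vs_experiment <- function(dock, exp, tol = 2.0) {
  shared <- intersect(dock$id, exp$id)
  if (!length(shared)) stop("no compound ids shared between dock and exp")
  d <- dock$score[match(shared, dock$id)]
  e <- exp$dg[match(shared, exp$id)]
  out <- data.frame(id = shared, score = d, dg = e, diff = d - e,
                    flagged = abs(d - e) > tol, stringsAsFactors = FALSE)
  attr(out, "max_abs_diff") <- max(abs(out$diff))
  attr(out, "tol") <- tol
  out
}

#' Per-scaffold docking statistics with outlier detection
#'
#' For every scaffold group, Tukey boxplot statistics (median, hinges,
#' whiskers at 1.5 IQR) of the binding free energy and of the ligand
#' efficiency; points beyond the whiskers are outliers ("dots outside
#' boxplot whiskers"). The leave-one-out median rule
#' (\code{\link{flag_group_outliers}}, 1.0 kcal/mol on dG and 0.5 on LE) is
#' applied alongside and both outlier sets are reported.
#'
#' @param results data frame with columns \code{id}, \code{score} (kcal/mol),
#'   \code{scaffold}, \code{heavy_atoms}.
#' @param dg_tol,le_tol tolerances for the leave-one-out rule.
#' @return list with \code{stats} (one row per scaffold and metric:
#'   \code{scaffold}, \code{metric}, \code{n}, \code{median}, \code{q1},
#'   \code{q3}, \code{whisker_lo}, \code{whisker_hi}),
#'   \code{whisker_outliers} (data frame \code{scaffold}, \code{id},
#'   \code{metric}) and \code{loo_outliers} (from
#'   \code{\link{flag_group_outliers}}).
#' @export
scaffold_group_stats <- function(results, dg_tol = 1.0, le_tol = 0.5) {
  stopifnot(all(c("id", "score", "scaffold", "heavy_atoms") %in%
                names(results)))
  results$le <- ligand_efficiency(results$score, results$heavy_atoms)
  stats_rows <- list(); out_rows <- list(); groups <- list()
  for (sc in unique(results$scaffold)) {
    sub <- results[results$scaffold == sc, , drop = FALSE]
    groups[[sc]] <- data.frame(compound_id = sub$id, dg = sub$score,
                               le = sub$le, stringsAsFactors = FALSE)
    for (metric in c("dg", "le")) {
      v <- if (metric == "dg") sub$score else sub$le
      bs <- grDevices::boxplot.stats(v, coef = 1.5)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        scaffold = sc, metric = metric, n = length(v),
        median = bs$stats[3], q1 = bs$stats[2], q3 = bs$stats[4],
        whisker_lo = bs$stats[1], whisker_hi = bs$stats[5],
        stringsAsFactors = FALSE)
      if (length(v) >= 2L && length(bs$out)) {
        out_rows[[length(out_rows) + 1L]] <- data.frame(
          scaffold = sc, id = sub$id[v %in% bs$out], metric = metric,
          stringsAsFactors = FALSE)
      }
    }
  }
  wout <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(scaffold = character(0), id = character(0),
               metric = character(0), stringsAsFactors = FALSE)
  singletons <- vapply(groups, nrow, integer(1)) < 2L
  loo <- suppressWarnings(
    flag_group_outliers(groups[!singletons], dg_tol = dg_tol,
                        le_tol = le_tol))
  list(stats = do.call(rbind, stats_rows), whisker_outliers = wout,
       loo_outliers = loo)
}
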