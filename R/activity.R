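# Potency filtering, thermodynamic conversion of IC50/Kd to binding free
# energy, ligand efficiency, and the group-outlier rules used to spot
# compounds deviating from their scaffold series.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.987e-3

#' Filter activity records by potency
#'
#' Keeps records with IC50 strictly below the threshold (the convention for
#' "IC50 < 500 nM" extracts). Records with non-positive IC50 are rejected
#' with a warning, never silently dropped.
#'
#' @param records data frame with columns \code{compound_id}, \code{ic50}
#'   (nM) and optionally \code{source}.
#' @param threshold potency cutoff in nM (default 500).
#' @return the kept rows, input order preserved.
#' @export
filter_actives <- function(records, threshold = 500) {
  stopifnot(is.data.frame(records), threshold > 0)
  if (!nrow(records)) return(records)
  bad <- !is.finite(records$ic50) | records$ic50 <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive IC50 rejected: ",
            paste(records$compound_id[bad], collapse = ", "), call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  records[records$ic50 < threshold, , drop = FALSE]
}

#' Binding free energy from a dissociation constant
#'
#' \deqn{\Delta G = R T \ln(K_d / c), \quad c = 1\,\mathrm{M}}
#' with R = 1.987e-3 kcal/(mol K). IC50 values are used directly as Kd when
#' comparing assay potency with docking energies (no Cheng-Prusoff
#' correction by default).
#'
#' @param kd dissociation constant in mol/L; vectorized.
#' @param temperature absolute temperature in K (default 298.15).
#' @return binding free energy in kcal/mol; negative whenever Kd < 1 M.
#' @examples
#' dg_from_kd(1)        # 0
#' dg_from_kd(500e-9)   # about -8.60 kcal/mol
#' @export
dg_from_kd <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd) | kd <= 0)) stop("kd must be positive and finite")
  if (temperature <= 0) stop("temperature must be positive")
  R_KCAL * temperature * log(kd)
}

#' Dissociation constant back from a binding free energy
#' @param dg binding free energy in kcal/mol.
#' @param temperature absolute temperature in K.
#' @return Kd in mol/L.
#' @export
kd_from_dg <- function(dg, temperature = 298.15) {
  exp(dg / (R_KCAL * temperature))
}

#' Ligand efficiency
#'
#' Binding free energy per heavy atom, the size-normalized potency measure
#' used to compare compound series of different molecular size.
#'
#' @param dg binding free energy, kcal/mol.
#' @param heavy_atoms heavy-atom count (>= 1).
#' @return kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(dg, heavy_atoms) {
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1")
  dg / heavy_atoms
}

#' Build an energy report from activities and molecules
#'
#' @param activities data frame (\code{compound_id}, \code{ic50} nM).
#' @param molecules list of \code{molecule} objects whose ids cover the
#'   activity table.
#' @param temperature K.
#' @return data frame \code{compound_id}, \code{ic50_nM}, \code{dg_kcal_mol},
#'   \code{heavy_atoms}, \code{le}.
#' @export
energy_report <- function(activities, molecules, temperature = 298.15) {
  ids <- vapply(molecules, function(m) m$id, "")
  heavy <- vapply(molecules, n_heavy, integer(1))
  idx <- match(activities$compound_id, ids)
  if (anyNA(idx)) {
    stop("no molecule for compound id(s): ",
         paste(activities$compound_id[is.na(idx)], collapse = ", "))
  }
  dg <- dg_from_kd(activities$ic50 * 1e-9, temperature)
  data.frame(compound_id = activities$compound_id,
             ic50_nM = activities$ic50,
             dg_kcal_mol = dg,
             heavy_atoms = heavy[idx],
             le = ligand_efficiency(dg, heavy[idx]),
             stringsAsFactors = FALSE)
}

#' Flag group outliers by leave-one-out median deviation
#'
#' Within each group (typically a scaffold series), a member is flagged when
#' its binding free energy deviates from the median of the \emph{other}
#' members by more than \code{dg_tol}, and analogously for ligand efficiency
#' with \code{le_tol}. Each flag records which criterion fired. Singleton
#' groups are skipped with a warning.
#'
#' @param groups named list of data frames, each with columns
#'   \code{compound_id}, \code{dg} and optionally \code{le}.
#' @param dg_tol binding-energy tolerance, kcal/mol (default 1.0).
#' @param le_tol ligand-efficiency tolerance, kcal/mol per heavy atom
#'   (default 0.5).
#' @return data frame \code{group}, \code{compound_id}, \code{criterion}
#'   (\code{"dg"} or \code{"le"}), \code{deviation}.
#' @export
flag_group_outliers <- function(groups, dg_tol = 1.0, le_tol = 0.5) {
  stopifnot(is.list(groups))
  out <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    if (nrow(df) < 2L) {
      warning("group ", sQuote(g), " has fewer than 2 members; skipped",
              call. = FALSE)
      next
    }
    for (crit in c("dg", "le")) {
      if (!crit %in% names(df)) next
      tol <- if (crit == "dg") dg_tol else le_tol
      v <- df[[crit]]
      for (i in seq_along(v)) {
        dev <- abs(v[i] - stats::median(v[-i]))
        if (dev > tol) {
          out[[length(out) + 1L]] <- data.frame(
            group = g, compound_id = df$compound_id[i],
            criterion = crit, deviation = dev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(group = character(0), compound_id = character(0),
                      criterion = character(0), deviation = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Flag group outliers by Tukey boxplot whiskers
#'
#' The boxplot convention: points beyond 1.5 IQR past the hinges
#' ("dots outside boxplot whiskers") are outliers.
#'
#' @param values numeric vector.
#' @param ids identifiers parallel to \code{values}.
#' @return ids of points beyond the whiskers.
#' @export
whisker_outliers <- function(values, ids = seq_along(values)) {
  stopifnot(length(values) == length(ids))
  if (length(values) < 2L) return(ids[0])
  st <- grDevices::boxplot.stats(values, coef = 1.5)
  ids[values %in% st$out]
}
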