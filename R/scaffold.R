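# Bemis-Murcko scaffold decomposition and scaffold frequency mining.

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively deletes terminal heavy atoms that are not in any ring (and, by
#' construction, not on a path between rings) until a fixed point: what
#' remains is the molecule's ring systems plus the linkers connecting them.
#' Acyclic molecules have no scaffold and return \code{NULL}.
#'
#' @param mol a \code{molecule}.
#' @param generic when \code{TRUE}, return the generic (all-carbon,
#'   all-single-bond) framework instead of the atom-typed scaffold.
#' @return a \code{molecule} holding the canonicalized scaffold, or
#'   \code{NULL} with no rings present (the acyclic case).
#' @examples
#' murcko_scaffold(parse_smiles("Cc1ccccc1"))$smiles  # benzene
#' murcko_scaffold(parse_smiles("CCCCCC"))            # NULL (acyclic)
#' @export
murcko_scaffold <- function(mol, generic = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (!any(mol$ring_atom)) return(NULL)

  n <- n_heavy(mol)
  keep <- rep(TRUE, n)
  b <- mol$bonds
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(b))) {
      if (keep[b$a1[k]] && keep[b$a2[k]]) {
        deg[b$a1[k]] <- deg[b$a1[k]] + 1L
        deg[b$a2[k]] <- deg[b$a2[k]] + 1L
      }
    }
    prune <- keep & deg <= 1L & !mol$ring_atom
    if (!any(prune)) break
    keep[prune] <- FALSE
  }

  scaffold_smiles <- subgraph_canonical_smiles(mol, which(keep),
                                               generic = generic)
  parse_smiles(scaffold_smiles, id = paste0(mol$id, "_scaffold"),
               strip_salts = FALSE)
}

# canonical SMILES of an induced heavy-atom subgraph, via a rebuilt molfile
# handed back to the substrate for canonicalization
subgraph_canonical_smiles <- function(mol, keep_idx, generic = FALSE) {
  idx_map <- match(seq_len(n_heavy(mol)), keep_idx)
  el <- mol$elements[keep_idx]
  chg <- mol$charges[keep_idx]
  xyz <- mol$coords[keep_idx, , drop = FALSE]
  b <- mol$bonds
  bk <- b[!is.na(idx_map[b$a1]) & !is.na(idx_map[b$a2]), , drop = FALSE]
  if (generic) {
    el[] <- "C"
    chg[] <- 0L
    bk$order <- 1L
  }
  na <- length(el); nb <- nrow(bk)

  atom_lines <- vapply(seq_len(na), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[i, 1], xyz[i, 2], xyz[i, 3], el[i])
  }, "")
  bond_lines <- if (nb) vapply(seq_len(nb), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0",
            idx_map[bk$a1[k]], idx_map[bk$a2[k]], bk$order[k])
  }, "") else character(0)
  chg_lines <- character(0)
  charged <- which(chg != 0L)
  if (length(charged)) {
    chg_lines <- paste0("M  CHG", sprintf("%3d", length(charged)),
                        paste0(sprintf("%4d%4d", charged, chg[charged]),
                               collapse = ""))
  }
  molfile <- paste(c("scaffold", "  chemtriage", "",
                     sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
                     atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
                   collapse = "\n")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", molfile)),
    error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) stop("substrate failed to canonicalize scaffold subgraph")
  out
}

#' Scaffold frequency table of a molecule set
#'
#' Groups molecules by canonical Bemis-Murcko scaffold SMILES and keeps
#' scaffolds whose member count reaches \code{min_count} (inclusive).
#' Acyclic molecules carry no scaffold; they are excluded from the table and
#' counted separately in the \code{n_acyclic} attribute.
#'
#' @param mols list of \code{molecule} objects.
#' @param min_count minimum member count for a scaffold to be reported
#'   (inclusive; default 1).
#' @param generic use generic frameworks (see \code{\link{murcko_scaffold}}).
#' @return object of class \code{scaffold_table}: data frame
#'   \code{scaffold_smiles}, \code{frequency}, \code{member_ids}
#'   (list column), sorted by frequency descending (ties by first
#'   appearance), with attributes \code{n_acyclic} and \code{min_count}.
#' @export
scaffold_frequency <- function(mols, min_count = 1L, generic = FALSE) {
  stopifnot(min_count >= 1L)
  scaff <- character(length(mols))
  ids <- character(length(mols))
  for (i in seq_along(mols)) {
    ids[i] <- mols[[i]]$id
    s <- murcko_scaffold(mols[[i]], generic = generic)
    scaff[i] <- if (is.null(s)) NA_character_ else s$smiles
  }
  acyclic <- is.na(scaff)
  tab <- split(ids[!acyclic], scaff[!acyclic])
  freq <- lengths(tab)
  first_seen <- vapply(names(tab), function(s) match(s, scaff), integer(1))
  ord <- order(-freq, first_seen)
  df <- data.frame(scaffold_smiles = names(tab)[ord],
                   frequency = as.integer(freq[ord]),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$member_ids <- unname(tab[ord])
  df <- df[df$frequency >= min_count, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_acyclic = sum(acyclic), min_count = as.integer(min_count),
            class = c("scaffold_table", "data.frame"))
}

#' Scaffolds shared between two scaffold tables
#'
#' Exact canonical-SMILES intersection; the matched row indices in both
#' tables are reported so shared scaffolds can be cross-referenced by rank.
#'
#' @param a,b \code{scaffold_table} objects.
#' @return data frame \code{scaffold_smiles}, \code{row_a}, \code{row_b}.
#' @export
scaffold_overlap <- function(a, b) {
  stopifnot(inherits(a, "scaffold_table"), inherits(b, "scaffold_table"))
  shared <- intersect(a$scaffold_smiles, b$scaffold_smiles)
  data.frame(scaffold_smiles = shared,
             row_a = match(shared, a$scaffold_smiles),
             row_b = match(shared, b$scaffold_smiles),
             stringsAsFactors = FALSE)
}

#' Write a scaffold table as TSV
#' @param tab a \code{scaffold_table}.
#' @param file output path.
#' @export
write_scaffold_table <- function(tab, file) {
  out <- data.frame(scaffold_smiles = tab$scaffold_smiles,
                    frequency = tab$frequency,
                    member_ids = vapply(tab$member_ids, paste, "",
                                        collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
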