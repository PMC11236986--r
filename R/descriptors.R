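# Per-molecule descriptors and the PAINS / rule-of-five triage filters.

#' Physicochemical descriptors of a molecule
#'
#' Molecular weight is summed from standard atomic weights including implicit
#' hydrogens. H-bond donors and acceptors follow the Lipinski convention
#' (donors: N or O carrying at least one hydrogen; acceptors: any N or O).
#' Rotatable bonds are acyclic single bonds between two non-terminal heavy
#' atoms, excluding amide C-N bonds. clogP is delegated to the substrate's
#' Crippen-type atomic-contribution model.
#'
#' @param mol a \code{molecule}.
#' @return data frame with one row: \code{mw}, \code{clogp}, \code{hbd},
#'   \code{hba}, \code{rotb}, \code{heavy}.
#' @examples
#' descriptors(parse_smiles("CCO"))  # hbd 1, hba 1, rotb 0
#' @export
descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  el <- mol$elements
  mass <- ATOMIC_MASS[el]
  if (anyNA(mass)) {
    warning("unknown atomic mass for element(s): ",
            paste(unique(el[is.na(mass)]), collapse = ", "))
    mass[is.na(mass)] <- 0
  }
  mw <- sum(mass) + sum(mol$n_h) * ATOMIC_MASS[["H"]]

  is_no <- el %in% c("N", "O")
  hbd <- sum(is_no & mol$n_h >= 1L)
  hba <- sum(is_no)

  rotb <- count_rotatable(mol)
  clogp <- ob_logp(mol$smiles)

  data.frame(mw = mw, clogp = clogp, hbd = hbd, hba = hba,
             rotb = rotb, heavy = n_heavy(mol))
}

ob_logp <- function(smiles) {
  p <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
  if (is.null(p)) return(NA_real_)
  as.numeric(p$logP)
}

count_rotatable <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  deg <- integer(n_heavy(mol))
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  ring_bond <- bond_in_ring(mol)
  # amide carbon: C double-bonded to O and single-bonded to N
  amide_c <- rep(FALSE, n_heavy(mol))
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L) {
      pr <- c(b$a1[k], b$a2[k])
      elp <- mol$elements[pr]
      if (setequal(elp, c("C", "O"))) amide_c[pr[elp == "C"]] <- TRUE
    }
  }
  n_rot <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || ring_bond[k]) next
    i <- b$a1[k]; j <- b$a2[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    eli <- mol$elements[i]; elj <- mol$elements[j]
    is_amide <- (eli == "C" && elj == "N" && amide_c[i]) ||
                (elj == "C" && eli == "N" && amide_c[j])
    if (is_amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

bond_in_ring <- function(mol) {
  b <- mol$bonds
  flags <- logical(nrow(b))
  if (!nrow(b)) return(flags)
  g <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
  n <- n_heavy(mol)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bc <- igraph::biconnected_components(g)
  ring_pairs <- character(0)
  for (ce in bc$component_edges) {
    ends <- igraph::ends(g, ce)
    if (nrow(ends) >= 3L) {   # biconnected component with a cycle
      ring_pairs <- c(ring_pairs,
                      paste(pmin(ends[, 1], ends[, 2]),
                            pmax(ends[, 1], ends[, 2])))
    }
  }
  key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  key %in% ring_pairs
}

#' Lipinski rule-of-five check
#'
#' @param desc one-row data frame from \code{\link{descriptors}}.
#' @return \code{TRUE} when MW <= 500, clogP <= 5, donors <= 5 and
#'   acceptors <= 10.
#' @export
ro5_pass <- function(desc) {
  isTRUE(desc$mw <= 500 && desc$clogp <= 5 && desc$hbd <= 5 && desc$hba <= 10)
}

#' Load a PAINS substructure pattern file
#'
#' Reads a tab-separated SMARTS pattern file (pattern id, SMARTS per line;
#' \code{#} comments allowed). The packaged default is a curated subset of the
#' published pan-assay interference (PAINS) families; every pattern is
#' validated against the substrate's SMARTS engine at load time.
#'
#' @param file pattern file; default: the packaged subset.
#' @return data frame with columns \code{id} and \code{smarts}.
#' @export
load_pains_patterns <- function(file = system.file("extdata",
                                                   "pains_subset.smarts",
                                                   package = "chemtriage")) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed PAINS pattern line(s): ",
                     paste(lines[bad], collapse = "; "))
  pat <- data.frame(id = vapply(parts, `[[`, "", 1L),
                    smarts = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pat))) {
    ok <- tryCatch({
      smarts_count("C", pat$smarts[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS for PAINS pattern ", sQuote(pat$id[i]))
  }
  pat
}

smarts_count <- function(smiles, smarts) {
  suppressWarnings(ChemmineOB::smartsSearch_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity), smarts,
    uniqueMatches = TRUE))
}

#' Match a molecule against PAINS patterns
#'
#' @param mol a \code{molecule}.
#' @param patterns pattern data frame from \code{\link{load_pains_patterns}}.
#' @return character vector of matched pattern ids; empty when clean.
#' @export
pains_match <- function(mol, patterns = load_pains_patterns()) {
  stopifnot(inherits(mol, "molecule"))
  hits <- vapply(seq_len(nrow(patterns)), function(i) {
    as.numeric(smarts_count(mol$smiles, patterns$smarts[i])) > 0
  }, logical(1))
  patterns$id[hits]
}
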