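# Molecular data model on top of the OpenBabel substrate (ChemmineR/ChemmineOB).
# Parsing and canonicalization are delegated; the graph bookkeeping used by
# fingerprints, descriptors and scaffold pruning lives here.

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
                     Cl = 1, Br = 1, I = 1)

# Monoisotopic-free standard atomic weights, CIAAW 2021 abridged
ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
                 Br = 79.904, I = 126.904)

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, Br = 35, I = 53)

#' Parse a SMILES string into a molecule
#'
#' Canonicalizes the input through the OpenBabel substrate, keeps the largest
#' covalent fragment when the SMILES encodes a salt or mixture, and builds the
#' heavy-atom graph (elements, bonds with orders, formal charges, implicit
#' hydrogen counts, ring membership and aromaticity) used by every downstream
#' operation.
#'
#' @param smiles a single SMILES string.
#' @param id identifier attached to the molecule; defaults to the canonical
#'   SMILES itself.
#' @param strip_salts keep only the largest covalent fragment (by heavy-atom
#'   count) before canonicalization. Default \code{TRUE}: library SMILES
#'   frequently carry counterions.
#' @return an object of class \code{molecule}: a list with elements
#'   \code{id}, \code{smiles} (canonical), \code{elements}, \code{charges},
#'   \code{bonds} (data frame \code{a1}, \code{a2}, \code{order}),
#'   \code{n_h} (implicit hydrogens per heavy atom), \code{ring_atom},
#'   \code{aromatic}, \code{coords} (2D substrate coordinates, Angstrom-scaled
#'   drawing coordinates, not a conformer), \code{n_fragments_stripped}.
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' n_heavy(m)  # 6
#' @export
parse_smiles <- function(smiles, id = NULL, strip_salts = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")

  n_stripped <- 0L
  if (strip_salts && grepl(".", smiles, fixed = TRUE)) {
    frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    sizes <- vapply(frags, smiles_heavy_count, numeric(1))
    keep <- which.max(sizes)
    n_stripped <- length(frags) - 1L
    smiles <- frags[[keep]]
  }

  can <- ob_canonical_smiles(smiles)
  if (is.na(can)) stop("unparseable SMILES: ", sQuote(smiles))

  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  mol <- if (ncol(ab) < 3L || !any(grepl("_", rownames(ab)))) {
    # ChemmineR returns a placeholder block for single-atom molecules
    single_atom_molecule(can, id = if (is.null(id)) can else id)
  } else {
    molecule_from_sdf(sdf, id = if (is.null(id)) can else id, smiles = can)
  }
  mol$n_fragments_stripped <- n_stripped
  mol
}

single_atom_molecule <- function(can, id) {
  m <- regmatches(can, regexec("^\\[?([A-Z][a-z]?)H?[0-9]*([+-][0-9]*)?\\]?$",
                               can))[[1]]
  if (length(m) < 2L || !nzchar(m[2])) {
    stop("unparseable single-atom SMILES: ", sQuote(can))
  }
  element <- m[2]
  charge <- 0L
  if (length(m) >= 3L && nzchar(m[3])) {
    sign <- if (startsWith(m[3], "-")) -1L else 1L
    mag <- sub("^[+-]", "", m[3])
    charge <- sign * if (nzchar(mag)) as.integer(mag) else 1L
  }
  defval <- DEFAULT_VALENCE[element]
  defval[is.na(defval)] <- 0
  chg_adj <- if (element %in% c("N", "P", "O", "S")) charge
             else if (element == "C") -abs(charge) else 0L
  structure(list(
    id = id, smiles = can, elements = element, charges = charge,
    bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)),
    n_h = max(0L, as.integer(defval + chg_adj)),
    ring_atom = FALSE, aromatic = FALSE,
    coords = matrix(0, 1, 3), sdf = NULL, n_fragments_stripped = 0L
  ), class = "molecule")
}

# canonical SMILES via the substrate; NA on parse failure
ob_canonical_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) return(NA_character_)
  out
}

# crude heavy-atom count straight off a SMILES fragment (used only to pick the
# largest salt component; full parsing happens afterwards)
smiles_heavy_count <- function(smi) {
  toks <- gregexpr("Cl|Br|Si|[BCNOPSFIbcnops]|\\[[^]]+\\]", smi)[[1]]
  if (toks[1] == -1) 0 else length(toks)
}

molecule_from_sdf <- function(sdf, id, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  stopifnot(n >= 1L)

  # single-atom molecules come back with a placeholder zero bond block
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    bonds[bonds$a1 >= 1L & bonds$a2 >= 1L, , drop = FALSE]
  }

  charges <- integer(n)
  binfo <- tryCatch(ChemmineR::bonds(sdf, type = "bonds"),
                    error = function(e) NULL)
  if (is.data.frame(binfo) && nrow(binfo) == n && "charge" %in% names(binfo)) {
    charges <- as.integer(binfo$charge)   # per-atom, in atom-block order
  }

  bosum <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bosum[bonds$a1[k]] <- bosum[bonds$a1[k]] + bonds$order[k]
      bosum[bonds$a2[k]] <- bosum[bonds$a2[k]] + bonds$order[k]
    }
  }

  defval <- DEFAULT_VALENCE[elements]
  defval[is.na(defval)] <- 0   # metals etc.: no implicit H
  chg_adj <- ifelse(elements %in% c("N", "P", "O", "S"), charges,
                    ifelse(elements == "C", -abs(charges), 0L))
  n_h <- pmax(0L, as.integer(defval + chg_adj - bosum))

  ring_atom <- ring_atom_flags(n, bonds)
  aromatic <- aromatic_flags(sdf, n, rownames(ab))

  structure(list(
    id = id, smiles = smiles, elements = elements, charges = charges,
    bonds = bonds, n_h = n_h, ring_atom = ring_atom, aromatic = aromatic,
    coords = ab[, 1:3, drop = FALSE], sdf = sdf,
    n_fragments_stripped = 0L
  ), class = "molecule")
}

# atoms lying on any cycle: members of a biconnected component with >= 3 atoms
ring_atom_flags <- function(n, bonds) {
  flags <- logical(n)
  if (nrow(bonds) == 0L) return(flags)
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bc <- igraph::biconnected_components(g)
  for (comp in bc$components) {
    if (length(comp) >= 3L) flags[as.integer(comp)] <- TRUE
  }
  flags
}

aromatic_flags <- function(sdf, n, atom_names) {
  flags <- logical(n)
  rr <- tryCatch(suppressWarnings(
    ChemmineR::rings(sdf, upper = 10, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (is.null(rr) || !length(rr$RINGS)) return(flags)
  for (i in seq_along(rr$RINGS)) {
    if (isTRUE(rr$AROMATIC[[i]])) {
      flags[match(rr$RINGS[[i]], atom_names)] <- TRUE
    }
  }
  flags
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, "\n  SMILES: ", x$smiles,
      "\n  heavy atoms: ", n_heavy(x),
      ", bonds: ", nrow(x$bonds),
      ", rings atoms: ", sum(x$ring_atom), "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol a \code{molecule}.
#' @return integer count of non-hydrogen atoms.
#' @export
n_heavy <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  length(mol$elements)
}

#' Read molecules from a delimited table
#'
#' Ingests the conventional (id, smiles, activity) layout used for activity
#' extracts and candidate libraries. Unparseable SMILES are dropped with a
#' warning naming the offending row, never silently.
#'
#' @param file path to a CSV or TSV file with columns \code{id},
#'   \code{smiles} and optionally \code{ic50} (nM).
#' @param sep field separator; guessed from the extension when \code{NULL}.
#' @param strip_salts passed to \code{\link{parse_smiles}}.
#' @return list with \code{molecules} (list of \code{molecule}) and
#'   \code{activities} (data frame \code{compound_id}, \code{ic50},
#'   \code{source}, or \code{NULL} when no activity column is present).
#' @export
read_smiles_table <- function(file, sep = NULL, strip_salts = TRUE) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", file, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  names(df) <- tolower(names(df))
  stopifnot(all(c("id", "smiles") %in% names(df)))
  mols <- vector("list", nrow(df))
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- tryCatch(parse_smiles(df$smiles[i], id = as.character(df$id[i]),
                               strip_salts = strip_salts),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("dropping unparseable SMILES for id ", df$id[i], ": ",
              sQuote(df$smiles[i]), call. = FALSE)
    } else {
      mols[[i]] <- m
      ok[i] <- TRUE
    }
  }
  acts <- NULL
  if ("ic50" %in% names(df)) {
    acts <- data.frame(compound_id = as.character(df$id[ok]),
                       ic50 = as.numeric(df$ic50[ok]),
                       source = file, stringsAsFactors = FALSE)
  }
  list(molecules = mols[ok], activities = acts)
}
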