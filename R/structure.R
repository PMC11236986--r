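# Geometric profiling of protein-ligand complexes: ingest, close contacts,
# aromatic-interaction classification, and cavity occupancy.

POLAR_ELEMENTS <- c("N", "O", "S")

# side-chain ring atom names of the aromatic residues
PROTEIN_RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

#' Read a protein-ligand complex from a PDB file
#'
#' Protein atoms are the ATOM records; the ligand is selected by HET code
#' (residue name of HETATM records) or by chain. Waters are dropped and only
#' altloc A (or blank) is kept. Hydrogens are discarded: all profiling here
#' is heavy-atom based.
#'
#' @param pdb path to a PDB file.
#' @param ligand_selector HET code (e.g. \code{"LIG"}) or chain id selecting
#'   exactly one ligand residue group.
#' @param drop_bridging_sulfur remove a ligand sulfur atom within covalent
#'   range (2.3 A) of the catalytic cysteine C277 SG before profiling; the
#'   thioester bridge of covalently bound peptidomimetics otherwise distorts
#'   contact counts. Default \code{FALSE}.
#' @return object of class \code{structure_complex}: list with \code{protein}
#'   and \code{ligand} atom data frames (\code{element}, \code{name},
#'   \code{resid}, \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z})
#'   and \code{metadata}.
#' @export
read_complex <- function(pdb, ligand_selector, drop_bridging_sulfur = FALSE) {
  pdbobj <- bio3d::read.pdb(pdb)
  at <- pdbobj$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at <- at[at$alt %in% c("", " ", NA, "A"), , drop = FALSE]
  el <- infer_element(at)
  at <- at[el != "H", , drop = FALSE]
  el <- el[el != "H"]

  is_het <- at$type == "HETATM"
  lig_mask <- if (toupper(ligand_selector) %in% unique(at$resid[is_het])) {
    is_het & at$resid == toupper(ligand_selector)
  } else if (ligand_selector %in% unique(at$chain[is_het])) {
    is_het & at$chain == ligand_selector
  } else {
    stop("ligand selector ", sQuote(ligand_selector),
         " matches nothing; available het codes: ",
         paste(unique(at$resid[is_het]), collapse = ", "))
  }
  if (!any(lig_mask)) {
    stop("ligand selector ", sQuote(ligand_selector), " selects no atoms")
  }

  mkdf <- function(mask) {
    data.frame(element = el[mask], name = at$elety[mask],
               resid = at$resid[mask], resno = at$resno[mask],
               chain = at$chain[mask],
               x = at$x[mask], y = at$y[mask], z = at$z[mask],
               stringsAsFactors = FALSE)
  }
  protein <- mkdf(!is_het)
  ligand <- mkdf(lig_mask)
  if (any(!stats::complete.cases(protein[c("x", "y", "z")])) ||
      any(!stats::complete.cases(ligand[c("x", "y", "z")]))) {
    stop("non-finite coordinates in ", pdb)
  }

  cx <- structure(list(protein = protein, ligand = ligand,
                       metadata = list(source = pdb,
                                       ligand_selector = ligand_selector)),
                  class = "structure_complex")
  if (drop_bridging_sulfur) cx <- remove_bridging_sulfur(cx)
  cx
}

infer_element <- function(at) {
  el <- trimws(at$elesy)
  miss <- !nzchar(el) | is.na(el)
  if (any(miss)) {
    # fall back to the atom name: strip digits, take leading letters
    nm <- gsub("[0-9'\\*]", "", trimws(at$elety[miss]))
    two <- toupper(substr(nm, 1, 2))
    el[miss] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "SE"),
                       paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
                       substr(nm, 1, 1))
  }
  paste0(toupper(substr(el, 1, 1)),
         tolower(substr(el, 2, nchar(el))))
}

#' Remove a covalent sulfur bridging the ligand to the catalytic cysteine
#'
#' Covalently bound peptidomimetic inhibitors carry a thioester sulfur
#' bridging to C277; dropping it yields the non-covalent interaction profile.
#'
#' @param cx a \code{structure_complex}.
#' @param cys_resno residue number of the catalytic cysteine (default 277).
#' @param covalent_max maximum S-S distance counted as covalent (default
#'   2.3 A).
#' @return the complex with any bridging ligand sulfur removed; the number
#'   removed is recorded in \code{metadata$n_bridging_sulfur_removed}.
#' @export
remove_bridging_sulfur <- function(cx, cys_resno = 277, covalent_max = 2.3) {
  stopifnot(inherits(cx, "structure_complex"))
  sg <- cx$protein[cx$protein$resno == cys_resno &
                   cx$protein$name == "SG", , drop = FALSE]
  removed <- 0L
  if (nrow(sg)) {
    lig_s <- which(cx$ligand$element == "S")
    for (i in lig_s) {
      d <- sqrt((cx$ligand$x[i] - sg$x[1])^2 + (cx$ligand$y[i] - sg$y[1])^2 +
                (cx$ligand$z[i] - sg$z[1])^2)
      if (d <= covalent_max) {
        cx$ligand <- cx$ligand[-i, , drop = FALSE]
        removed <- removed + 1L
        break
      }
    }
  }
  cx$metadata$n_bridging_sulfur_removed <- removed
  cx
}

#' @export
print.structure_complex <- function(x, ...) {
  cat("<structure_complex> ", x$metadata$source %||% "", "\n  protein atoms: ",
      nrow(x$protein), " (", length(unique(paste(x$protein$chain,
                                                 x$protein$resno))),
      " residues), ligand atoms: ", nrow(x$ligand), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

xyz_mat <- function(df) as.matrix(df[, c("x", "y", "z")])

#' Close contacts between protein and ligand
#'
#' Every protein/ligand heavy-atom pair within \code{contact_max} produces
#' one record. Pairs of two polar atoms (N, O or S on both sides, the
#' donor/acceptor elements) within \code{hbond_max} are classed
#' \code{hydrogen_bond}; all other pairs within \code{contact_max} are
#' \code{close_contact}. Geometry-only criteria: no explicit-hydrogen angle
#' term, in line with heavy-atom-only complex profiling.
#'
#' @param cx a \code{structure_complex}.
#' @param hbond_max hydrogen-bond distance cutoff, A (default 3.5).
#' @param contact_max generic close-contact cutoff, A (default 4.0).
#' @return data frame \code{protein_atom}, \code{protein_resid},
#'   \code{protein_resno}, \code{ligand_atom}, \code{distance},
#'   \code{class}; attribute \code{cutoffs} records the criteria used.
#' @export
close_contacts <- function(cx, hbond_max = 3.5, contact_max = 4.0) {
  stopifnot(inherits(cx, "structure_complex"))
  if (!nrow(cx$ligand)) stop("complex has an empty ligand")
  stopifnot(hbond_max > 0, contact_max > 0, hbond_max <= contact_max)

  pm <- xyz_mat(cx$protein); lm <- xyz_mat(cx$ligand)
  rows <- list()
  for (j in seq_len(nrow(lm))) {
    d2 <- (pm[, 1] - lm[j, 1])^2 + (pm[, 2] - lm[j, 2])^2 +
          (pm[, 3] - lm[j, 3])^2
    hits <- which(d2 <= contact_max^2)
    for (i in hits) {
      d <- sqrt(d2[i])
      polar <- cx$protein$element[i] %in% POLAR_ELEMENTS &&
               cx$ligand$element[j] %in% POLAR_ELEMENTS
      cls <- if (polar && d <= hbond_max) "hydrogen_bond" else "close_contact"
      rows[[length(rows) + 1L]] <- data.frame(
        protein_atom = cx$protein$name[i], protein_resid = cx$protein$resid[i],
        protein_resno = cx$protein$resno[i], ligand_atom = cx$ligand$name[j],
        distance = d, class = cls, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_atom = character(0), protein_resid = character(0),
               protein_resno = integer(0), ligand_atom = character(0),
               distance = numeric(0), class = character(0),
               stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- c(hbond_max = hbond_max, contact_max = contact_max)
  out
}

# rings: list of coordinate matrices (>= 3 atoms each) with residue labels
protein_rings <- function(cx) {
  rings <- list()
  reskey <- paste(cx$protein$chain, cx$protein$resno)
  for (key in unique(reskey)) {
    sel <- reskey == key
    resid <- cx$protein$resid[sel][1]
    defs <- PROTEIN_RING_ATOMS[[resid]]
    if (is.null(defs)) next
    for (atoms in defs) {
      idx <- which(sel & cx$protein$name %in% atoms)
      if (length(idx) == length(atoms)) {
        rings[[length(rings) + 1L]] <- list(
          label = paste0(resid, cx$protein$resno[idx[1]]),
          coords = xyz_mat(cx$protein[idx, , drop = FALSE]))
      }
    }
  }
  rings
}

# ligand rings from a distance-based bond graph: simple 5/6-cycles that are
# nearly planar (RMS out-of-plane < 0.15 A)
ligand_rings <- function(cx, bond_max = 1.75, planarity_max = 0.15) {
  n <- nrow(cx$ligand)
  if (n < 5L) return(list())
  xyz <- xyz_mat(cx$ligand)
  d <- as.matrix(stats::dist(xyz))
  edges <- which(upper.tri(d) & d <= bond_max & d > 0.5, arr.ind = TRUE)
  if (nrow(edges) < 5L) return(list())
  cyc <- find_small_cycles(edges, n, min_len = 5L, max_len = 6L)
  rings <- list()
  for (cy in cyc) {
    coords <- xyz[cy, , drop = FALSE]
    centered <- sweep(coords, 2, colMeans(coords))
    sv <- svd(centered)
    if (sqrt(mean((centered %*% sv$v[, 3])^2)) <= planarity_max) {
      rings[[length(rings) + 1L]] <- list(
        label = paste0("LIGring", length(rings) + 1L), coords = coords)
    }
  }
  rings
}

# enumerate unique simple cycles of bounded length by DFS from each vertex
# (ligand graphs are small; this is exhaustive and order-independent)
find_small_cycles <- function(edges, n, min_len = 5L, max_len = 6L) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  found <- list(); seen <- character(0)
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1] && length(path) >= min_len) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!w %in% path && length(path) < max_len && w > path[1]) {
        dfs(c(path, w))
      }
    }
  }
  for (v in seq_len(n)) if (length(adj[[v]]) >= 2L) dfs(v)
  found
}

ring_plane <- function(coords) {
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  normal <- svd(centered)$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Aromatic interactions between protein and ligand rings
#'
#' Protein rings are the named side-chain rings of Phe, Tyr, His and Trp;
#' ligand rings are planar 5/6-cycles of the distance-based bond graph. For
#' every ring pair with centroid distance at most \code{d_stack_max} the
#' interplanar angle and the lateral offset (displacement of the ligand ring
#' centroid within the protein ring plane) decide the class: parallel
#' (face-to-face), parallel-displaced, or T-shaped (edge-to-face).
#' Intermediate angles are reported as \code{unclassified}.
#'
#' @param cx a \code{structure_complex}.
#' @param d_stack_max centroid-centroid cutoff, A (default 5.5).
#' @param angle_parallel_max maximum interplanar angle for the parallel
#'   classes, degrees (default 30).
#' @param offset_parallel_max maximum lateral offset separating parallel
#'   from parallel-displaced, A (default 1.5).
#' @param angle_t_min minimum interplanar angle for T-shaped, degrees
#'   (default 60).
#' @return data frame \code{protein_ring}, \code{ligand_ring},
#'   \code{distance}, \code{angle}, \code{offset}, \code{class}.
#' @export
aromatic_interactions <- function(cx, d_stack_max = 5.5,
                                  angle_parallel_max = 30,
                                  offset_parallel_max = 1.5,
                                  angle_t_min = 60) {
  stopifnot(inherits(cx, "structure_complex"))
  prings <- protein_rings(cx)
  lrings <- ligand_rings(cx)
  rows <- list()
  for (pr in prings) {
    pp <- ring_plane(pr$coords)
    for (lr in lrings) {
      lp <- ring_plane(lr$coords)
      dvec <- lp$centroid - pp$centroid
      dist <- sqrt(sum(dvec^2))
      if (dist > d_stack_max) next
      cosang <- abs(sum(pp$normal * lp$normal))
      angle <- acos(pmin(1, cosang)) * 180 / pi
      offset <- sqrt(max(0, dist^2 - sum(dvec * pp$normal)^2))
      cls <- if (angle <= angle_parallel_max && offset <= offset_parallel_max) {
        "parallel"
      } else if (angle <= angle_parallel_max) {
        "parallel_displaced"
      } else if (angle >= angle_t_min) {
        "t_shaped"
      } else "unclassified"
      rows[[length(rows) + 1L]] <- data.frame(
        protein_ring = pr$label, ligand_ring = lr$label,
        distance = dist, angle = angle, offset = offset, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_ring = character(0), ligand_ring = character(0),
                      distance = numeric(0), angle = numeric(0),
                      offset = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Interaction summary of a complex
#'
#' Totals of \code{\link{close_contacts}} and
#' \code{\link{aromatic_interactions}} (classified ring pairs only), the
#' per-ligand quantities tabulated across complexes.
#'
#' @param cx a \code{structure_complex}.
#' @param ... cutoffs passed through to the two profiling operations.
#' @return one-row data frame \code{n_close_contacts}, \code{n_hbonds},
#'   \code{n_aromatic}.
#' @export
interaction_summary <- function(cx, ...) {
  args <- list(...)
  cc_args <- args[names(args) %in% c("hbond_max", "contact_max")]
  ar_args <- args[names(args) %in% c("d_stack_max", "angle_parallel_max",
                                     "offset_parallel_max", "angle_t_min")]
  cc <- do.call(close_contacts, c(list(cx), cc_args))
  ar <- do.call(aromatic_interactions, c(list(cx), ar_args))
  data.frame(n_close_contacts = nrow(cc),
             n_hbonds = sum(cc$class == "hydrogen_bond"),
             n_aromatic = sum(ar$class != "unclassified"))
}

#' Default active-site cavity definitions
#'
#' The active site is modeled as three cavities: the catalytic pocket around
#' the nucleophilic cysteine (C277, with W241/W332/H335 lining it), the
#' surface pocket at Q169, and a user-supplied wide pocket. Residues are
#' given in UniProt P21980 numbering.
#'
#' @param wide_residues residue ids for the wide pocket (default none, i.e.
#'   the wide cavity is skipped unless supplied).
#' @return list of cavity definitions (\code{label}, \code{residues},
#'   character ids like \code{"C277"}).
#' @export
default_cavities <- function(wide_residues = character(0)) {
  cavs <- list(
    list(label = "catalytic", residues = c("C277", "W241", "W332", "H335")),
    list(label = "surface", residues = "Q169"))
  if (length(wide_residues)) {
    cavs <- c(cavs, list(list(label = "wide", residues = wide_residues)))
  }
  cavs
}

parse_residue_id <- function(rid) {
  as.integer(sub("^[A-Za-z]+", "", rid))
}

#' Cavity occupancy of a ligand
#'
#' A cavity is occupied when any ligand heavy atom lies within
#' \code{capture} of any heavy atom of the cavity's defining residues. Also
#' reports whether the binding-mode criterion -- occupancy of at least two
#' of the three cavities -- holds.
#'
#' @param cx a \code{structure_complex}.
#' @param cavities list of cavity definitions (see
#'   \code{\link{default_cavities}}).
#' @param capture capture radius, A (default 4.0).
#' @return list with \code{occupied} (labels), \code{per_cavity} (named
#'   logical) and \code{two_of_three} (criterion over the first three
#'   cavities defined).
#' @export
cavity_occupancy <- function(cx, cavities = default_cavities(),
                             capture = 4.0) {
  stopifnot(inherits(cx, "structure_complex"))
  lm <- xyz_mat(cx$ligand)
  occ <- logical(length(cavities))
  names(occ) <- vapply(cavities, `[[`, "", "label")
  for (k in seq_along(cavities)) {
    resnos <- parse_residue_id(cavities[[k]]$residues)
    sel <- cx$protein$resno %in% resnos
    if (!any(sel)) {
      stop("cavity ", sQuote(cavities[[k]]$label),
           " has no defining residues in the structure: ",
           paste(cavities[[k]]$residues, collapse = ", "))
    }
    pm <- xyz_mat(cx$protein[sel, , drop = FALSE])
    mind <- min(vapply(seq_len(nrow(lm)), function(j) {
      min(sqrt((pm[, 1] - lm[j, 1])^2 + (pm[, 2] - lm[j, 2])^2 +
               (pm[, 3] - lm[j, 3])^2))
    }, numeric(1)))
    occ[k] <- mind <= capture
  }
  list(occupied = names(occ)[occ], per_cavity = occ,
       two_of_three = sum(occ[seq_len(min(3L, length(occ)))]) >= 2L)
}
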