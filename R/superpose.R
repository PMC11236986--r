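# Rigid-body superposition (Kabsch) and cross-structure residue deviations.

#' Least-squares rigid-body superposition
#'
#' Kabsch algorithm: atoms are paired between mobile and reference by
#' (chain, residue number, atom name); the optimal rotation is obtained from
#' the SVD of the covariance of the centered paired coordinates, with the
#' usual determinant correction to exclude reflections.
#'
#' @param mobile,reference \code{structure_complex} objects (their protein
#'   atoms are paired), or plain coordinate matrices with matching rownames.
#' @param atom_names restrict pairing to these atom names (e.g. \code{"CA"});
#'   \code{NULL} pairs every shared atom.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3,
#'   applied as \code{x \%*\% rotation + translation}), \code{rmsd} over the
#'   paired atoms, and \code{n_atoms}.
#' @export
superpose <- function(mobile, reference, atom_names = NULL) {
  pm <- pair_atoms(mobile, reference, atom_names)
  if (nrow(pm$mobile) < 3L) {
    stop("superposition needs at least 3 paired atoms, got ", nrow(pm$mobile))
  }
  fit <- kabsch(pm$mobile, pm$reference)
  moved <- sweep(pm$mobile %*% fit$rotation, 2, fit$translation, `+`)
  fit$rmsd <- sqrt(mean(rowSums((moved - pm$reference)^2)))
  fit$n_atoms <- nrow(pm$mobile)
  fit
}

kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, translation = as.numeric(cy - cx %*% rot))
}

#' Apply a superposition transform to a complex
#' @param cx a \code{structure_complex}.
#' @param fit result of \code{\link{superpose}}.
#' @return the transformed complex.
#' @export
apply_transform <- function(cx, fit) {
  stopifnot(inherits(cx, "structure_complex"))
  for (part in c("protein", "ligand")) {
    xyz <- xyz_mat(cx[[part]])
    moved <- sweep(xyz %*% fit$rotation, 2, fit$translation, `+`)
    cx[[part]]$x <- moved[, 1]; cx[[part]]$y <- moved[, 2]
    cx[[part]]$z <- moved[, 3]
  }
  cx
}

pair_atoms <- function(mobile, reference, atom_names = NULL) {
  getdf <- function(obj) {
    if (inherits(obj, "structure_complex")) obj$protein
    else if (is.matrix(obj)) {
      data.frame(element = "X", name = rownames(obj), resid = "XXX",
                 resno = seq_len(nrow(obj)), chain = "A",
                 x = obj[, 1], y = obj[, 2], z = obj[, 3],
                 stringsAsFactors = FALSE)
    } else stop("expected structure_complex or coordinate matrix")
  }
  dm <- getdf(mobile); dr <- getdf(reference)
  if (is.matrix(mobile) && is.matrix(reference) &&
      (is.null(rownames(mobile)) || is.null(rownames(reference)))) {
    stopifnot(nrow(mobile) == nrow(reference))
    return(list(mobile = mobile, reference = reference))
  }
  if (!is.null(atom_names)) {
    dm <- dm[dm$name %in% atom_names, , drop = FALSE]
    dr <- dr[dr$name %in% atom_names, , drop = FALSE]
  }
  km <- paste(dm$chain, dm$resno, dm$name)
  kr <- paste(dr$chain, dr$resno, dr$name)
  shared <- intersect(km, kr)
  list(mobile = xyz_mat(dm[match(shared, km), , drop = FALSE]),
       reference = xyz_mat(dr[match(shared, kr), , drop = FALSE]))
}

#' Per-residue deviations of catalytic residues across structures
#'
#' Each structure is superposed on the reference (the first in the list)
#' over shared C-alpha atoms; the deviation of each named residue is the
#' heavy-atom RMSD over its atoms shared with the reference. Residues absent
#' from a structure are reported as \code{NA} rather than failing -- partial
#' models with unresolved loops are the norm for this target.
#'
#' @param structures list of \code{structure_complex} (>= 2).
#' @param residues residue ids in UniProt numbering; the default covers the
#'   catalytic machinery (nucleophile C277, charge-relay H335/D358,
#'   intermediate-stabilizing W241, amine-attack H305/E363) plus the
#'   binding-site residues N333, W332 and Q169.
#' @return data frame: one row per residue, one column per non-reference
#'   structure, values in Angstrom; attribute \code{missing} lists
#'   (structure, residue) pairs not present.
#' @export
residue_deviations <- function(structures,
                               residues = c("C277", "H335", "D358", "W241",
                                            "H305", "E363", "N333", "W332",
                                            "Q169")) {
  stopifnot(length(structures) >= 2L)
  ref <- structures[[1]]
  resnos <- parse_residue_id(residues)
  labels <- vapply(structures, function(s) {
    s$metadata$source %||% "structure"
  }, "")
  labels <- make.unique(basename(labels))

  out <- matrix(NA_real_, nrow = length(residues),
                ncol = length(structures) - 1L,
                dimnames = list(residues, labels[-1]))
  missing <- list()
  for (si in seq_along(structures)[-1]) {
    fit <- superpose(structures[[si]], ref, atom_names = "CA")
    moved <- apply_transform(structures[[si]], fit)
    for (ri in seq_along(resnos)) {
      mref <- ref$protein[ref$protein$resno == resnos[ri], , drop = FALSE]
      mmov <- moved$protein[moved$protein$resno == resnos[ri], , drop = FALSE]
      if (!nrow(mref) || !nrow(mmov)) {
        missing[[length(missing) + 1L]] <- c(labels[si], residues[ri])
        next
      }
      shared <- intersect(mref$name, mmov$name)
      if (!length(shared)) {
        missing[[length(missing) + 1L]] <- c(labels[si], residues[ri])
        next
      }
      a <- xyz_mat(mref[match(shared, mref$name), , drop = FALSE])
      b <- xyz_mat(mmov[match(shared, mmov$name), , drop = FALSE])
      out[ri, si - 1L] <- sqrt(mean(rowSums((b - a)^2)))
    }
  }
  df <- as.data.frame(out)
  attr(df, "missing") <- missing
  df
}
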