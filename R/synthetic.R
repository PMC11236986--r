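# Seeded synthetic-data generators. Each one is a pure function of its
# specification and seed, and emits the planted ground truth alongside the
# dataset so every downstream stage can be scored without external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# decoration fragments: prefixes end, and suffixes begin, at the attachment
# atom so plain string concatenation onto an aromatic CH yields valid SMILES.
# Sulfonamide and carboxamide are included deliberately: sulfonamide-bearing
# scaffolds dominate realistic transglutaminase-targeted libraries.
DECOR_PREFIXES <- c("", "C", "CC", "CO", "CCO", "F", "Cl", "Br",
                    "FC(F)(F)", "NC(=O)", "NS(=O)(=O)")
DECOR_SUFFIXES <- c("", "C", "CC", "CCC", "OC", "F", "Cl", "Br",
                    "S(N)(=O)=O", "C(N)=O")

# lead-series-sized ring systems (15-18 heavy atoms), the scale of scaffolds
# that frequency mining actually operates on in target-focused libraries;
# all are bare ring systems + linkers, so each reduces to itself
DEFAULT_SCAFFOLDS <- c(
  "c1ccc(Nc2ncnc3ccccc23)cc1",       # 4-anilinoquinazoline
  "c1ccc(-c2nc3ccccc3o2)cc1",        # 2-phenylbenzoxazole
  "c1ccc(CN2CCN(c3ccccc3)CC2)cc1")   # 1-benzyl-4-phenylpiperazine

#' Generate a scaffold-structured synthetic compound library
#'
#' Every compound is a planted cyclic scaffold decorated with small acyclic
#' substituents (halogens, alkyl, methoxy, sulfonamide, carboxamide), so
#' each compound is guaranteed to Murcko-reduce to its scaffold; the
#' guarantee is asserted at generation time. IC50 values are drawn
#' log-normally per scaffold -- potency data are log-scale by convention.
#'
#' @param scaffolds cyclic scaffold SMILES (default: three chemically
#'   distinct ring systems). Acyclic scaffolds are rejected.
#' @param per_scaffold compounds per scaffold (default 25).
#' @param ic50_median_nM median (geometric mean) IC50 per scaffold in nM;
#'   recycled (default 150, an active-range potency).
#' @param ic50_gsd geometric standard deviation of IC50 (default 2.0).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return list with \code{molecules}, \code{activities} (data frame
#'   \code{compound_id}, \code{ic50}, \code{source}), and \code{truth}:
#'   \code{compound_scaffold} (named character: compound id ->
#'   canonical scaffold SMILES) and \code{scaffold_smiles} (the planted
#'   canonical scaffolds).
#' @export
gen_library <- function(scaffolds = DEFAULT_SCAFFOLDS, per_scaffold = 25L,
                        ic50_median_nM = 150, ic50_gsd = 2.0, seed = 1L) {
  stopifnot(per_scaffold >= 1L, all(ic50_median_nM > 0), ic50_gsd >= 1)
  ic50_median_nM <- rep_len(ic50_median_nM, length(scaffolds))

  canon <- character(length(scaffolds))
  for (k in seq_along(scaffolds)) {
    base <- parse_smiles(scaffolds[k])
    if (!any(base$ring_atom)) {
      stop("scaffold ", sQuote(scaffolds[k]),
           " is acyclic: its Murcko scaffold would be empty")
    }
    sc <- murcko_scaffold(base)
    if (is.null(sc) || sc$smiles != base$smiles) {
      stop("scaffold ", sQuote(scaffolds[k]),
           " does not Murcko-reduce to itself; use a bare ring system")
    }
    canon[k] <- base$smiles
  }

  combos <- expand.grid(prefix = DECOR_PREFIXES, suffix = DECOR_SUFFIXES,
                        stringsAsFactors = FALSE)
  if (per_scaffold > nrow(combos)) {
    stop("per_scaffold exceeds the ", nrow(combos),
         " distinct decoration combinations available")
  }

  with_seed(seed, {
    mols <- list(); acts <- list(); truth_map <- character(0)
    for (k in seq_along(scaffolds)) {
      pick <- combos[sample.int(nrow(combos), per_scaffold), , drop = FALSE]
      ic50 <- stats::rlnorm(per_scaffold, meanlog = log(ic50_median_nM[k]),
                            sdlog = log(ic50_gsd))
      for (j in seq_len(per_scaffold)) {
        cid <- sprintf("S%02dC%03d", k, j)
        smi <- paste0(pick$prefix[j], scaffolds[k], pick$suffix[j])
        m <- parse_smiles(smi, id = cid)
        sc <- murcko_scaffold(m)
        if (is.null(sc) || sc$smiles != canon[k]) {
          stop("generated compound ", cid,
               " does not reduce to its planted scaffold (internal error)")
        }
        mols[[length(mols) + 1L]] <- m
        acts[[length(acts) + 1L]] <- data.frame(
          compound_id = cid, ic50 = ic50[j], source = "synthetic",
          stringsAsFactors = FALSE)
        truth_map[cid] <- canon[k]
      }
    }
    list(molecules = mols, activities = do.call(rbind, acts),
         truth = list(compound_scaffold = truth_map,
                      scaffold_smiles = canon))
  })
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# residue templates in local coordinates: the interaction-bearing side-chain
# atom sits at the origin and the planted ligand atom is placed on -z;
# backbone atoms point away (+z) so they stay outside the contact cutoffs.
RES_TEMPLATES <- list(
  SER = list(atoms = c("OG", "CB", "CA", "N", "C", "O"),
             elements = c("O", "C", "C", "N", "C", "O"),
             xyz = rbind(c(0, 0, 0), c(0, 0, 1.43), c(0, 1.25, 2.35),
                         c(0, 1.05, 3.75), c(1.40, 2.05, 2.45),
                         c(1.35, 3.25, 2.65))),
  ALA = list(atoms = c("CB", "CA", "N", "C", "O"),
             elements = c("C", "C", "N", "C", "O"),
             xyz = rbind(c(0, 0, 0), c(0, 0, 1.54), c(0, 1.20, 2.25),
                         c(1.30, 0.00, 2.40), c(2.40, 0.60, 2.70))))

hexagon <- function(radius = 1.39) {
  ang <- (0:5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

#' Generate a synthetic protein-ligand complex with planted interactions
#'
#' Builds a PDB-format complex in which every requested interaction is
#' realized analytically in its own spatial pocket (pockets are 30 A apart,
#' so pockets never interfere): hydrogen bonds as Ser OG vs a polar ligand
#' atom, apolar contacts as Ala CB vs a ligand carbon, aromatic interactions
#' as a Phe side-chain ring vs a ligand benzene ring at the requested
#' centroid distance, interplanar angle and lateral offset, and cavity
#' residues with or without a ligand atom in capture range. Each pocket gets
#' a random rigid rotation (seeded), which changes nothing about the planted
#' geometry.
#'
#' @param n_hbonds number of planted hydrogen bonds (default 2).
#' @param n_apolar number of planted apolar close contacts (default 1).
#' @param stacks data frame with columns \code{distance}, \code{angle}
#'   (deg), \code{offset} describing planted ring-ring geometries; may have
#'   zero rows. Default: one face-to-face stack at 3.5 A.
#' @param hbond_distance,apolar_distance planted pair distances, A.
#' @param cavity_residues named list: cavity residue id (e.g. \code{"C277"})
#'   -> logical, whether a ligand atom is planted within capture range.
#' @param seed RNG seed (pocket orientations only).
#' @param file optional path; when given, the complex is also written as a
#'   PDB file.
#' @return list with \code{complex} (a \code{structure_complex}) and
#'   \code{truth}: planted counts and per-stack expected classes
#'   (\code{parallel}, \code{parallel_displaced}, \code{t_shaped} or
#'   \code{unclassified} by the default classification cutoffs).
#' @export
gen_complex <- function(n_hbonds = 2L, n_apolar = 1L,
                        stacks = data.frame(distance = 3.5, angle = 0,
                                            offset = 0),
                        hbond_distance = 3.0, apolar_distance = 3.6,
                        cavity_residues = list(), seed = 1L, file = NULL) {
  stopifnot(n_hbonds >= 0L, n_apolar >= 0L)
  if (hbond_distance > 3.5) stop("infeasible: hbond_distance beyond cutoff")
  if (apolar_distance > 4.0) stop("infeasible: apolar_distance beyond cutoff")
  if (nrow(stacks)) {
    stopifnot(all(c("distance", "angle", "offset") %in% names(stacks)))
    if (any(stacks$offset > stacks$distance)) {
      stop("infeasible stack: lateral offset exceeds centroid distance")
    }
    if (any(stacks$angle < 0 | stacks$angle > 90)) {
      stop("infeasible stack: angle must be in [0, 90] degrees")
    }
  }

  with_seed(seed, {
    prot <- list(); lig <- list()
    resno <- 0L; pocket <- 0L
    add_protein <- function(resname, names, elements, xyz, rno = NULL) {
      resno <<- if (is.null(rno)) resno + 1L else rno
      prot[[length(prot) + 1L]] <<- data.frame(
        element = elements, name = names, resid = resname,
        resno = resno, chain = "A",
        x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    add_ligand <- function(elements, xyz) {
      k <- length(lig)
      lig[[k + 1L]] <<- data.frame(
        element = elements,
        name = paste0(elements, seq_along(elements) + 100L * k),
        resid = "LIG", resno = 900L, chain = "L",
        x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    place <- function(xyz) {   # rotate pocket-local coords, then translate
      pocket <<- pocket + 1L
      rot <- random_rotation()
      sweep(xyz %*% t(rot), 2, c(30 * pocket, 0, 0), `+`)
    }

    for (i in seq_len(n_hbonds)) {
      tmpl <- RES_TEMPLATES$SER
      lig_el <- if (i %% 2 == 0) "O" else "N"
      all_xyz <- place(rbind(tmpl$xyz, c(0, 0, -hbond_distance)))
      add_protein("SER", tmpl$atoms, tmpl$elements,
                  all_xyz[seq_along(tmpl$atoms), , drop = FALSE])
      add_ligand(lig_el, all_xyz[nrow(all_xyz), , drop = FALSE])
    }
    for (i in seq_len(n_apolar)) {
      tmpl <- RES_TEMPLATES$ALA
      all_xyz <- place(rbind(tmpl$xyz, c(0, 0, -apolar_distance)))
      add_protein("ALA", tmpl$atoms, tmpl$elements,
                  all_xyz[seq_along(tmpl$atoms), , drop = FALSE])
      add_ligand("C", all_xyz[nrow(all_xyz), , drop = FALSE])
    }

    stack_class <- character(nrow(stacks))
    if (nrow(stacks)) {
      for (i in seq_len(nrow(stacks))) {
        d <- stacks$distance[i]; ang <- stacks$angle[i]; off <- stacks$offset[i]
        ring_p <- hexagon()                       # protein ring, normal +z
        cb <- c(2.90, 0, 0); ca <- c(3.75, 1.20, 0)
        bbN <- c(3.80, 1.40, 1.40); bbC <- c(5.10, 1.80, -0.40)
        bbO <- c(6.10, 2.20, 0.20)
        h <- sqrt(d^2 - off^2)
        theta <- ang * pi / 180
        rot_y <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
                       c(-sin(theta), 0, cos(theta)))
        ring_l <- sweep(hexagon() %*% t(rot_y), 2, c(-off, 0, h), `+`)
        all_xyz <- place(rbind(ring_p, cb, ca, bbN, bbC, bbO, ring_l))
        add_protein("PHE",
                    c("CG", "CD1", "CE1", "CZ", "CE2", "CD2",
                      "CB", "CA", "N", "C", "O"),
                    c(rep("C", 7), "C", "N", "C", "O"),
                    all_xyz[1:11, , drop = FALSE])
        add_ligand(rep("C", 6), all_xyz[12:17, , drop = FALSE])
        stack_class[i] <- if (ang <= 30 && off <= 1.5) "parallel"
          else if (ang <= 30) "parallel_displaced"
          else if (ang >= 60) "t_shaped" else "unclassified"
      }
    }

    cavity_occupied <- logical(0)
    for (rid in names(cavity_residues)) {
      rno <- parse_residue_id(rid)
      tmpl <- RES_TEMPLATES$ALA
      resname <- c(C = "CYS", Q = "GLN", W = "TRP", H = "HIS", D = "ASP",
                   E = "GLU", N = "ASN")[substr(rid, 1, 1)]
      if (is.na(resname)) resname <- "ALA"
      occupied <- isTRUE(cavity_residues[[rid]])
      pts <- if (occupied) rbind(tmpl$xyz, c(0, 0, -3.0)) else tmpl$xyz
      all_xyz <- place(pts)
      add_protein(resname, tmpl$atoms, tmpl$elements,
                  all_xyz[seq_along(tmpl$atoms), , drop = FALSE], rno = rno)
      if (occupied) add_ligand("C", all_xyz[nrow(all_xyz), , drop = FALSE])
      cavity_occupied[rid] <- occupied
    }

    if (!length(prot)) {
      # an empty interaction spec still needs a protein to profile against
      tmpl <- RES_TEMPLATES$ALA
      add_protein("ALA", tmpl$atoms, tmpl$elements,
                  sweep(tmpl$xyz, 2, c(0, 0, 50), `+`))
    }
    if (!length(lig)) {
      # profiling requires a ligand; park a lone carbon far from everything
      add_ligand("C", matrix(c(-50, -50, -50), 1))
    }
    cx <- structure(list(
      protein = do.call(rbind, prot), ligand = do.call(rbind, lig),
      metadata = list(source = "gen_complex", seed = seed)),
      class = "structure_complex")

    truth <- list(
      n_hbonds = n_hbonds, n_apolar = n_apolar,
      n_contacts_planted = n_hbonds + n_apolar + sum(cavity_occupied),
      stack_classes = stack_class,
      cavity_occupied = cavity_occupied)

    if (!is.null(file)) write_complex_pdb(cx, file)
    list(complex = cx, truth = truth)
  })
}

#' Write a structure complex as a PDB file
#' @param cx a \code{structure_complex}.
#' @param file output path.
#' @export
write_complex_pdb <- function(cx, file) {
  stopifnot(inherits(cx, "structure_complex"))
  fmt <- function(df, rectype, offset) {
    vapply(seq_len(nrow(df)), function(i) {
      sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              rectype, i + offset, substr(df$name[i], 1, 4), "", df$resid[i],
              df$chain[i], df$resno[i], "", df$x[i], df$y[i], df$z[i],
              1.0, 0.0, toupper(df$element[i]))
    }, "")
  }
  lines <- c(fmt(cx$protein, "ATOM", 0L), "TER",
             fmt(cx$ligand, "HETATM", nrow(cx$protein)), "END")
  writeLines(lines, file)
  invisible(file)
}

#' Generate a per-scaffold docking score table with planted outliers
#'
#' Scores are drawn around per-group means with bounded noise; one outlier
#' per designated group is displaced far beyond both the Tukey whisker of
#' its group and the leave-one-out median tolerance. The generator verifies
#' its own planted truth (re-drawing a group's inliers, deterministically
#' under the seeded stream, in the rare event that noise alone trips an
#' outlier rule), so downstream outlier recovery is exact by construction.
#'
#' @param groups number of scaffold groups (default 12).
#' @param per_group compounds per group (default 5, the "five compounds per
#'   scaffold" series design).
#' @param base_dg mean binding free energy per group, kcal/mol; recycled
#'   (default evenly spaced in [-9.5, -6.5]).
#' @param noise_sd half-width of the bounded score noise, kcal/mol
#'   (default 0.3).
#' @param outlier_groups indices of groups receiving one planted outlier
#'   (default: group 1).
#' @param seed RNG seed.
#' @return list with \code{table} (data frame \code{id}, \code{score},
#'   \code{scaffold}, \code{heavy_atoms}) and \code{truth}: planted outlier
#'   ids and the expected flag sets per rule
#'   (\code{whisker_dg}, \code{whisker_le}, \code{loo_dg}, \code{loo_le}).
#' @export
gen_docking_table <- function(groups = 12L, per_group = 5L,
                              base_dg = NULL, noise_sd = 0.3,
                              outlier_groups = 1L, seed = 1L) {
  stopifnot(per_group >= 2L, groups >= 1L, noise_sd >= 0)
  if (is.null(base_dg)) base_dg <- seq(-9.5, -6.5, length.out = groups)
  base_dg <- rep_len(base_dg, groups)
  stopifnot(all(outlier_groups >= 1L), all(outlier_groups <= groups))
  displacement <- 8 * noise_sd + 2.0   # clears whiskers and the 1 kcal rule

  with_seed(seed, {
    rows <- list(); outlier_ids <- character(0)
    loo_le_ids <- character(0)
    for (g in seq_len(groups)) {
      heavy <- sample(20:32, 1)
      sc <- sprintf("scaffold_%02d", g)
      ids <- sprintf("%s_c%d", sc, seq_len(per_group))
      has_out <- g %in% outlier_groups
      for (try in 1:200) {
        dg <- base_dg[g] + stats::runif(per_group, -noise_sd, noise_sd)
        if (has_out) dg[per_group] <- base_dg[g] - displacement
        le <- dg / heavy
        w_dg <- whisker_outliers(dg, ids)
        w_le <- whisker_outliers(le, ids)
        loo <- flag_group_outliers(list(g = data.frame(
          compound_id = ids, dg = dg, le = le, stringsAsFactors = FALSE)))
        loo_dg <- loo$compound_id[loo$criterion == "dg"]
        loo_le <- loo$compound_id[loo$criterion == "le"]
        want <- if (has_out) ids[per_group] else character(0)
        want_loo_le <- if (has_out && displacement / heavy > 0.5)
          ids[per_group] else character(0)
        ok <- setequal(w_dg, want) && setequal(w_le, want) &&
              setequal(loo_dg, want) && setequal(loo_le, want_loo_le)
        if (ok) break
        if (try == 200L) stop("could not realize planted truth for group ", g)
      }
      if (has_out) {
        outlier_ids <- c(outlier_ids, ids[per_group])
        loo_le_ids <- c(loo_le_ids, want_loo_le)
      }
      rows[[g]] <- data.frame(id = ids, score = dg, scaffold = sc,
                              heavy_atoms = heavy, stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows),
         truth = list(outlier_ids = outlier_ids,
                      whisker_dg = outlier_ids, whisker_le = outlier_ids,
                      loo_dg = outlier_ids, loo_le = loo_le_ids))
  })
}
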