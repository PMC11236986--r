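# Hashed circular (Morgan-type) fingerprints and Tanimoto similarity.
# The iterative neighborhood-hashing scheme is order-independent by
# construction (neighbor contributions are sorted before hashing), and the
# molecule graph itself comes from the canonicalized SMILES, so the bitset is
# invariant to how the input SMILES was written.

HASH_P <- 2147483647  # 2^31 - 1; keeps exact double arithmetic well under 2^53

hash_mix <- function(h, v) ((h * 31) %% HASH_P + v) %% HASH_P

hash_vec <- function(vals) {
  h <- 17
  for (v in vals) h <- hash_mix(h, v)
  h
}

#' Circular fingerprint of a molecule
#'
#' Morgan-style extended-connectivity fingerprint: every heavy atom starts
#' from an invariant built from its element, degree, bond-order sum, implicit
#' hydrogen count, formal charge, ring membership and aromaticity; the
#' invariant is then iteratively re-hashed with the sorted (bond order,
#' neighbor invariant) list out to the requested radius. All environment
#' identifiers from radius 0 up to \code{radius} are folded onto a fixed-width
#' bitset by modular hashing; bit collisions are accepted as-is, the standard
#' behavior for hashed fingerprints.
#'
#' @param mol a \code{molecule}.
#' @param radius neighborhood radius in bonds (default 3, i.e. ECFP6-class).
#' @param nbits bitset width (default 2048).
#' @return object of class \code{chemfp}: a logical vector of length
#'   \code{nbits} with attributes \code{nbits} and \code{radius}.
#' @examples
#' fp <- circular_fingerprint(parse_smiles("CCO"))
#' sum(fp)  # popcount
#' @export
circular_fingerprint <- function(mol, radius = 3L, nbits = 2048L) {
  stopifnot(inherits(mol, "molecule"))
  if (length(nbits) != 1L || nbits <= 0) stop("nbits must be a positive integer")
  if (length(radius) != 1L || radius < 0) stop("radius must be >= 0")
  n <- n_heavy(mol)

  nbr <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }

  degree <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bosum <- vapply(nbr, function(x) if (is.null(x)) 0L else sum(x[, 2]), integer(1))
  z <- ATOMIC_NUMBER[mol$elements]
  z[is.na(z)] <- 0

  inv <- vapply(seq_len(n), function(i) hash_vec(c(
    z[i], degree[i], bosum[i], mol$n_h[i], mol$charges[i] + 8,
    as.integer(mol$ring_atom[i]), as.integer(mol$aromatic[i])
  )), numeric(1))

  ids <- inv
  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    for (i in seq_len(n)) {
      if (is.null(nbr[[i]])) {
        new_inv[i] <- hash_mix(inv[i], r)
        next
      }
      contrib <- nbr[[i]][, 2] * HASH_P + inv[nbr[[i]][, 1]]
      contrib <- sort(contrib)
      h <- hash_mix(17, inv[i])
      for (cv in contrib) {
        h <- hash_mix(hash_mix(h, cv %/% HASH_P), cv %% HASH_P)
      }
      new_inv[i] <- h
    }
    inv <- new_inv
    ids <- c(ids, inv)
  }

  bits <- logical(nbits)
  bits[(unique(ids) %% nbits) + 1] <- TRUE
  structure(bits, nbits = as.integer(nbits), radius = as.integer(radius),
            class = "chemfp")
}

#' @export
print.chemfp <- function(x, ...) {
  cat("<chemfp> nbits=", attr(x, "nbits"), " radius=", attr(x, "radius"),
      " popcount=", sum(x), "\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over set bits. Two all-zero fingerprints are
#' defined as identical (similarity 1).
#'
#' @param a,b \code{chemfp} objects of equal width.
#' @return similarity in \eqn{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "chemfp"), inherits(b, "chemfp"))
  if (attr(a, "nbits") != attr(b, "nbits")) {
    stop("fingerprint length mismatch: ", attr(a, "nbits"), " vs ",
         attr(b, "nbits"))
  }
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

# pairwise Tanimoto similarity matrix for a fingerprint list
tanimoto_matrix <- function(fps) {
  n <- length(fps)
  m <- matrix(1, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
    }
  }
  m
}
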