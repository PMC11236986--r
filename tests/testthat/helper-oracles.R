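# Independent oracles and small fixture builders shared across test files.

# brute-force sphere-exclusion clustering, written directly from the rule:
# neighbor lists at distance <= cutoff, repeatedly seed at the unassigned
# item with most unassigned neighbors (ties by input order). Independent of
# butina_cluster(): similarity is recomputed here from the raw bit vectors.
butina_oracle <- function(fps, cutoff) {
  n <- length(fps)
  sim <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- as.logical(fps[[i]]); b <- as.logical(fps[[j]])
      u <- sum(a | b)
      sim[i, j] <- if (u == 0) 1 else sum(a & b) / u
    }
  }
  neighbors <- lapply(seq_len(n), function(i)
    setdiff(which((1 - sim[i, ]) <= cutoff), i))
  unassigned <- rep(TRUE, n)
  clusters <- list(); centroids <- integer(0)
  while (any(unassigned)) {
    counts <- vapply(seq_len(n), function(i) {
      if (!unassigned[i]) -1L
      else length(intersect(neighbors[[i]], which(unassigned)))
    }, integer(1))
    c0 <- which(counts == max(counts))[1]
    members <- union(c0, intersect(neighbors[[c0]], which(unassigned)))
    unassigned[members] <- FALSE
    clusters[[length(clusters) + 1L]] <- sort(members)
    centroids <- c(centroids, c0)
  }
  list(clusters = clusters, centroids = centroids)
}

# canonical string form of a partition (set of member sets), order-free
partition_key <- function(member_sets) {
  paste(sort(vapply(member_sets, function(m) paste(sort(m), collapse = ","),
                    "")), collapse = "|")
}

# random sparse fingerprints (no chemistry needed to exercise clustering)
random_fps <- function(n, nbits = 64L, density = 0.25) {
  lapply(seq_len(n), function(i) {
    bits <- logical(nbits)
    k <- max(1L, stats::rbinom(1, nbits, density))
    bits[sample.int(nbits, k)] <- TRUE
    structure(bits, nbits = nbits, radius = 3L, class = "chemfp")
  })
}

rand_index <- function(a, b) {
  n <- length(a); agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1L
      agree <- agree + as.integer((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / total
}

cluster_membership <- function(assignment, ids) {
  memb <- rep(NA_character_, length(ids))
  names(memb) <- ids
  for (k in seq_along(assignment$clusters)) {
    memb[assignment$clusters[[k]]] <- as.character(k)
  }
  memb[ids]
}

# synthetic full-length target with the transglutaminase guard letters
# planted (Q at 276, C at 336) for numbering-sensitive masking tests
make_guarded_target <- function(len = 400L, seed = 42L) {
  set.seed(seed)
  aa <- sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), len,
               replace = TRUE)
  aa[276] <- "Q"; aa[336] <- "C"
  paste(aa, collapse = "")
}

# a small rigid rotation matrix from an axis-angle
rotation_about_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

transform_complex <- function(cx, rot, shift) {
  for (part in c("protein", "ligand")) {
    xyz <- as.matrix(cx[[part]][, c("x", "y", "z")]) %*% t(rot)
    cx[[part]]$x <- xyz[, 1] + shift[1]
    cx[[part]]$y <- xyz[, 2] + shift[2]
    cx[[part]]$z <- xyz[, 3] + shift[3]
  }
  cx
}

# off-boundary stack geometry sampler for classification-recovery tests:
# every draw sits >= 5 degrees / >= 0.3 A away from the decision boundaries
sample_stack_geometry <- function() {
  class <- sample(c("parallel", "parallel_displaced", "t_shaped",
                    "unclassified"), 1)
  if (class == "parallel") {
    ang <- stats::runif(1, 0, 25); off <- stats::runif(1, 0, 1.2)
    d <- stats::runif(1, max(3.2, off + 0.3), 5.0)
  } else if (class == "parallel_displaced") {
    ang <- stats::runif(1, 0, 25); off <- stats::runif(1, 1.8, 3.0)
    d <- stats::runif(1, off + 0.3, 5.2)
  } else if (class == "t_shaped") {
    ang <- stats::runif(1, 65, 90); off <- stats::runif(1, 0, 1.0)
    d <- stats::runif(1, 4.2, 5.2)
  } else {
    ang <- stats::runif(1, 35, 55); off <- stats::runif(1, 0, 1.0)
    d <- stats::runif(1, 3.8, 5.0)
  }
  list(distance = d, angle = ang, offset = off, class = class)
}
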