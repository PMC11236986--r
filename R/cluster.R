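# Butina sphere-exclusion clustering, representative selection, and
# similarity search against a reference panel.

#' Butina sphere-exclusion clustering of fingerprints
#'
#' Neighbor lists are built at Tanimoto distance (1 - similarity) at or below
#' \code{cutoff}; the unassigned item with the most unassigned neighbors
#' becomes the next cluster centroid and captures its unassigned neighbors,
#' until everything is assigned. Ties are broken by input order; items with
#' no neighbors end up as singleton clusters.
#'
#' @param fps list of \code{chemfp} fingerprints.
#' @param cutoff Tanimoto-distance cutoff in (0, 1). Default 0.4, common
#'   practice for 2048-bit circular fingerprints.
#' @param ids optional identifiers parallel to \code{fps}.
#' @return object of class \code{cluster_assignment}: list with
#'   \code{clusters} (list of member-id vectors, ordered by size descending,
#'   ties by first appearance), \code{centroids} (one id per cluster),
#'   \code{cutoff}.
#' @export
butina_cluster <- function(fps, cutoff = 0.4, ids = NULL) {
  if (!length(fps)) stop("butina_cluster: empty fingerprint list")
  stopifnot(cutoff > 0, cutoff < 1)
  n <- length(fps)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))

  sim <- tanimoto_matrix(fps)
  adj <- (1 - sim) <= cutoff
  diag(adj) <- FALSE

  assigned <- logical(n)
  clusters <- list()
  centroids <- integer(0)
  while (!all(assigned)) {
    counts <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else sum(adj[i, ] & !assigned)
    }, integer(1))
    centroid <- which.max(counts)      # ties: first by input order
    members <- c(centroid, which(adj[centroid, ] & !assigned))
    members <- unique(members)
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- members
    centroids <- c(centroids, centroid)
  }

  sizes <- lengths(clusters)
  ord <- order(-sizes, seq_along(clusters))
  structure(list(
    clusters = lapply(clusters[ord], function(m) ids[m]),
    centroids = ids[centroids[ord]],
    cutoff = cutoff
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$clusters), " clusters (cutoff ",
      x$cutoff, "), sizes: ",
      paste(utils::head(lengths(x$clusters), 10), collapse = " "),
      if (length(x$clusters) > 10) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Representative compounds of the largest clusters
#'
#' Returns the sphere centroids of the \code{top_k} largest clusters (the
#' "one representative compound from each cluster" step of library triage).
#'
#' @param assignment a \code{cluster_assignment}.
#' @param top_k number of clusters to draw representatives from.
#' @return character vector of \code{top_k} compound ids.
#' @export
select_representatives <- function(assignment, top_k) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (top_k < 1) stop("top_k must be >= 1")
  if (top_k > length(assignment$clusters)) {
    stop("top_k (", top_k, ") exceeds number of clusters (",
         length(assignment$clusters), ")")
  }
  assignment$centroids[seq_len(top_k)]
}

#' Similarity search of a candidate set against reference molecules
#'
#' A candidate is a hit when its best Tanimoto similarity over all references
#' reaches \code{threshold}; the best-matching reference is reported.
#'
#' @param references,candidates lists of \code{molecule} objects.
#' @param threshold minimum Tanimoto similarity (default 0.3).
#' @param radius,nbits fingerprint parameters.
#' @return data frame \code{candidate_id}, \code{reference_id},
#'   \code{similarity}, hits only, candidate input order preserved.
#' @export
similarity_search <- function(references, candidates, threshold = 0.3,
                              radius = 3L, nbits = 2048L) {
  if (!length(references) || !length(candidates)) {
    stop("similarity_search: reference and candidate lists must be non-empty")
  }
  rfp <- lapply(references, circular_fingerprint, radius = radius, nbits = nbits)
  rid <- vapply(references, function(m) m$id, "")
  rows <- list()
  for (cand in candidates) {
    cfp <- circular_fingerprint(cand, radius = radius, nbits = nbits)
    sims <- vapply(rfp, tanimoto, numeric(1), b = cfp)
    best <- which.max(sims)
    if (sims[best] >= threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = cand$id, reference_id = rid[best],
        similarity = sims[best], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(candidate_id = character(0), reference_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
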