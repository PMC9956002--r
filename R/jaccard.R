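#' Jaccard distance between two finite sets
#'
#' `1 - |A intersect B| / |A union B|`, the metric used throughout the
#' two-stage clustering: on frame supports within a replica, and on residue
#' membership sets across replicas and substrates.
#'
#' @param a,b Vectors interpreted as sets (duplicates ignored).
#' @return A number in `[0, 1]`. If both sets are empty the distance is
#'   defined as 0 with a warning; empty-support items are filtered out
#'   before clustering, so this case is not reached in the pipeline.
#' @examples
#' jaccard_distance(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    warn("jaccard_distance of two empty sets; returning 0")
    return(0)
  }
  inter <- length(intersect(a, b))
  1 - inter / (length(a) + length(b) - inter)
}

# Pairwise Jaccard distance matrix for a list of integer sets, via sparse
# cross-products (fast for many residues x many frames).
jaccard_dist_matrix <- function(sets) {
  n <- length(sets)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  sets <- lapply(sets, unique)
  elems <- sort(unique(unlist(sets)))
  sizes <- lengths(sets)
  if (length(elems) == 0) {
    warn("all sets empty in jaccard_dist_matrix")
    return(matrix(0, n, n))
  }
  i <- rep.int(seq_len(n), sizes)
  j <- match(unlist(sets), elems)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n, length(elems)))
  inter <- as.matrix(Matrix::tcrossprod(M))
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  d
}

#' Deterministic agglomerative clustering under a distance cutoff
#'
#' Bottom-up agglomeration (single, complete, or average/UPGMA linkage)
#' that stops when the smallest inter-cluster distance exceeds `cutoff`,
#' which for these monotone linkages is the same as cutting the dendrogram
#' at that height. Equal-height merges are resolved deterministically: the
#' candidate pair whose clusters contain the smallest original item indices
#' (lexicographically) merges first, so output never depends on internal
#' ordering quirks.
#'
#' @param d A symmetric numeric distance matrix.
#' @param cutoff Merge while the linkage distance is `<= cutoff`.
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`.
#' @return An integer membership vector: items sharing a label were merged.
#'   Labels are renumbered 1..k in order of each cluster's smallest item.
#' @export
agglomerate <- function(d, cutoff, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  # active clusters as lists of member indices; representative = min member
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  D <- d
  diag(D) <- Inf
  repeat {
    act <- which(active)
    if (length(act) < 2) break
    sub <- D[act, act, drop = FALSE]
    mn <- min(sub)
    if (!is.finite(mn) || mn > cutoff + 1e-9) break
    # all tied candidate pairs at the minimum (1e-9 slack so float noise in
    # linkage updates cannot reorder genuinely tied merges); pick by
    # smallest min-members
    idx <- which(sub <= mn + 1e-9, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    reps <- vapply(members[act], min, integer(1))
    pair_key <- cbind(pmin(reps[idx[, 1]], reps[idx[, 2]]),
                      pmax(reps[idx[, 1]], reps[idx[, 2]]))
    best <- order(pair_key[, 1], pair_key[, 2])[1]
    a <- act[idx[best, 1]]
    b <- act[idx[best, 2]]
    # merge b into a, update distances to every other active cluster
    others <- setdiff(act, c(a, b))
    if (length(others) > 0) {
      new_d <- switch(linkage,
        single = pmin(D[a, others], D[b, others]),
        complete = pmax(D[a, others], D[b, others]),
        average = (sizes[a] * D[a, others] + sizes[b] * D[b, others]) /
          (sizes[a] + sizes[b])
      )
      D[a, others] <- new_d
      D[others, a] <- new_d
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
  }
  labels <- integer(n)
  act <- which(active)
  mins <- vapply(members[act], min, integer(1))
  for (k in seq_along(act)) {
    labels[members[[act[order(mins)[k]]]]] <- k
  }
  labels
}
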