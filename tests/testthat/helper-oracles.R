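# Independent oracles and small generators used across the suite.

# Jaccard distance by plain set enumeration (no arithmetic shortcuts).
naive_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) return(0)
  inter <- sum(vapply(u, function(x) x %in% a && x %in% b, logical(1)))
  1 - inter / length(u)
}

# Brute-force agglomerative clustering: at every step recompute every
# cluster-pair distance from the ORIGINAL distance matrix (mean over cross
# pairs for average linkage), pick the closest pair (ties by the
# lexicographically smallest pair of minimum member indices), merge while
# the distance stays within the cutoff. Independent of the package's
# incremental-update implementation.
naive_agglomerate <- function(d, cutoff, linkage = "average") {
  n <- nrow(d)
  if (n == 0) return(integer(0))
  clusters <- as.list(seq_len(n))
  link <- function(ci, cj) {
    vals <- as.vector(d[ci, cj, drop = FALSE])
    switch(linkage,
           single = min(vals), complete = max(vals), average = mean(vals))
  }
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- link(clusters[[i]], clusters[[j]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (dij < best_d - 1e-9 ||
            (dij <= best_d + 1e-9 &&
             (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best <- c(i, j)
          best_d <- min(best_d, dij)
          best_key <- key
        }
      }
    }
    if (best_d > cutoff + 1e-9) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  labels <- integer(n)
  mins <- vapply(clusters, min, integer(1))
  for (k in seq_along(clusters)) {
    labels[clusters[[order(mins)[k]]]] <- k
  }
  labels
}

# Canonical form of a partition label vector, for comparing partitions
# irrespective of label values.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# All-pairs distance contact oracle: loops over every (protein atom,
# ligand atom) pair with explicit sqrt-Euclidean distances.
brute_force_contacts <- function(traj, ligand_resname, cutoff = 2.7) {
  atoms <- traj$atoms
  is_lig <- atoms$resid %in% ligand_resname
  prot <- atoms[!is_lig, , drop = FALSE]
  res_keys <- paste(prot$chain, prot$resno, sep = ":")
  res_index <- match(res_keys, unique(res_keys))
  lig_rows <- which(is_lig)
  entries <- list()
  for (f in seq_along(traj$coords)) {
    xyz <- traj$coords[[f]]
    for (ri in unique(res_index)) {
      pa <- prot$atom[res_index == ri]
      hit <- FALSE
      for (p in pa) {
        for (l in lig_rows) {
          dd <- sqrt(sum((xyz[p, ] - xyz[l, ])^2))
          if (dd <= cutoff + 1e-9) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) entries[[length(entries) + 1L]] <- c(ri, f - 1L)
    }
  }
  if (length(entries) == 0) {
    return(tibble::tibble(residue = integer(), frame = integer()))
  }
  m <- do.call(rbind, entries)
  tibble::tibble(residue = as.integer(m[, 1]), frame = as.integer(m[, 2]))
}

# Random toy trajectory: n_res single-atom residues plus extra atoms, one
# multi-atom ligand, coordinates uniform in a box.
random_toy_trajectory <- function(n_res = 4, atoms_per_res = 2,
                                  lig_atoms = 3, n_frames = 10,
                                  box = 8) {
  n_prot <- n_res * atoms_per_res
  atoms <- tibble::tibble(
    atom = seq_len(n_prot + lig_atoms),
    resno = c(rep(seq_len(n_res), each = atoms_per_res), rep(900L, lig_atoms)),
    resid = c(rep("ALA", n_prot), rep("LIG", lig_atoms)),
    elety = "C1",
    chain = c(rep("A", n_prot), rep("L", lig_atoms))
  )
  coords <- lapply(seq_len(n_frames), function(f) {
    matrix(stats::runif((n_prot + lig_atoms) * 3, 0, box), ncol = 3)
  })
  structure(list(atoms = atoms, coords = coords), class = "tbs_trajectory")
}

# Random frame-support sets for clustering tests.
random_supports <- function(n_items, universe = 30, min_size = 1,
                            max_size = 12) {
  lapply(seq_len(n_items), function(i) {
    sort(sample.int(universe, sample(min_size:max_size, 1)))
  })
}

# Minimal binding_sites tibble built by hand, for selection tests.
make_sites <- function(site_residues, member_tbls) {
  out <- tibble::tibble(
    site_id = seq_along(site_residues),
    residues = site_residues,
    n_residues = lengths(site_residues),
    time_table = lapply(seq_along(site_residues), function(i) {
      tt <- vapply(split(member_tbls[[i]]$cluster_time_ns,
                         member_tbls[[i]]$substrate), stats::median,
                   numeric(1))
      tt
    }),
    members = member_tbls
  )
  class(out) <- c("binding_sites", class(tibble::tibble()))
  out
}

# One member local-cluster row.
member_row <- function(substrate, replica, residues, per_res_times,
                       cluster_time) {
  res <- as.integer(residues)
  prt <- stats::setNames(as.numeric(per_res_times), res)
  tibble::tibble(substrate = substrate, replica = replica,
                 residues = list(res),
                 per_residue_time_ns = list(prt),
                 cluster_time_ns = cluster_time,
                 n_residues = length(res))
}

# Bare (residue, frame) data frame of a contact matrix or entry tibble,
# stripped of metadata attributes, for comparisons against oracles.
entries_df <- function(x) {
  data.frame(residue = as.integer(x$residue), frame = as.integer(x$frame))
}
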