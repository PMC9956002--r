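#' Stage-1 clustering: local clusters within one replica
#'
#' Residues with non-empty contact vectors are clustered hierarchically on
#' the Jaccard distance between their frame supports; the dendrogram is cut
#' at `jaccard_cutoff` and clusters smaller than `min_cluster_size` are
#' discarded. Surviving groups are the local clusters: residues that tend
#' to be touched by the ligand in the same frames, i.e. one transient
#' binding patch seen within one replica.
#'
#' Times are attached from the matrix: per-residue interaction time, and a
#' cluster time equal to the union of member frame supports times the frame
#' spacing (co-contacted frames are not double-counted).
#'
#' @param m A [contact_matrix()].
#' @param jaccard_cutoff Dendrogram cut height on Jaccard distance
#'   (default 0.65; members of a surviving pair share at least 35% of
#'   their combined support).
#' @param min_cluster_size Minimum residues per reported cluster (default 3).
#' @param linkage Linkage passed to [agglomerate()].
#' @return A tibble of class `local_clusters` with one row per cluster:
#'   `substrate`, `replica`, `cluster_id`, `residues` (list of int),
#'   `per_residue_time_ns` (list of named numeric), `cluster_time_ns`,
#'   `n_residues`. Empty input gives zero rows.
#' @export
local_cluster <- function(m, jaccard_cutoff = 0.65, min_cluster_size = 3,
                          linkage = "average") {
  stopifnot(inherits(m, "contact_matrix"))
  meta <- cm_meta(m)
  empty <- tibble(substrate = character(), replica = character(),
                  cluster_id = integer(), residues = list(),
                  per_residue_time_ns = list(), cluster_time_ns = numeric(),
                  n_residues = integer())
  class(empty) <- c("local_clusters", class(empty))
  if (nrow(m) == 0) return(empty)

  supports <- frame_supports(m)
  res_ids <- as.integer(names(supports))
  d <- jaccard_dist_matrix(supports)
  labels <- agglomerate(d, cutoff = jaccard_cutoff, linkage = linkage)

  out <- lapply(sort(unique(labels)), function(k) {
    mem <- res_ids[labels == k]
    if (length(mem) < min_cluster_size) return(NULL)
    mem <- sort(mem)
    sup <- supports[as.character(mem)]
    per_res <- vapply(sup, length, integer(1)) * meta$dt_ps / 1000
    names(per_res) <- as.character(mem)
    union_frames <- length(unique(unlist(sup)))
    tibble(substrate = meta$substrate, replica = meta$replica,
           residues = list(mem), per_residue_time_ns = list(per_res),
           cluster_time_ns = union_frames * meta$dt_ps / 1000,
           n_residues = length(mem))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty)
  out <- out %>%
    mutate(cluster_id = row_number()) %>%
    select("substrate", "replica", "cluster_id", "residues",
           "per_residue_time_ns", "cluster_time_ns", "n_residues")
  class(out) <- c("local_clusters", class(tibble()))
  out
}

#' Stage-2 clustering: global binding sites for one substrate
#'
#' Local clusters collected across all replicas of one substrate are
#' represented by their residue-membership sets and clustered under the
#' same Jaccard distance and cutoff. Each resulting group is a binding
#' site: its residue set is the union of its members and its time is an
#' aggregate of the member local-cluster times (default the median, with
#' `"sum"` available for cumulative reporting).
#'
#' @param locals A `local_clusters` tibble (rows from one substrate,
#'   typically several replicas, via [dplyr::bind_rows()]).
#' @param jaccard_cutoff,min_cluster_size,linkage As in [local_cluster()];
#'   `min_cluster_size` applies to the merged residue set.
#' @param aggregator `"median"` (default) or `"sum"` over member
#'   local-cluster times.
#' @return A tibble of class `binding_sites`: `site_id`, `residues` (list),
#'   `n_residues`, `time_table` (list of named numeric, one entry per
#'   substrate), `members` (list of member local-cluster tibbles).
#' @export
global_cluster <- function(locals, jaccard_cutoff = 0.65,
                           min_cluster_size = 3, linkage = "average",
                           aggregator = c("median", "sum")) {
  aggregator <- match.arg(aggregator)
  if (nrow(locals) == 0) abort("no local clusters to group")
  d <- jaccard_dist_matrix(locals$residues)
  labels <- agglomerate(d, cutoff = jaccard_cutoff, linkage = linkage)
  agg_fun <- if (aggregator == "median") median else sum

  out <- lapply(sort(unique(labels)), function(k) {
    mem <- locals[labels == k, , drop = FALSE]
    residues <- sort(unique(unlist(mem$residues)))
    if (length(residues) < min_cluster_size) return(NULL)
    tt <- vapply(split(mem$cluster_time_ns, mem$substrate), agg_fun,
                 numeric(1))
    n_res <- length(residues)
    tibble(residues = list(residues), n_residues = n_res,
           time_table = list(tt), members = list(mem))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(residues = list(), n_residues = integer(),
                  time_table = list(), members = list())
  }
  out <- number_sites(out)
  class(out) <- c("binding_sites", class(tibble()))
  out
}

# site_ids in descending total time, ties by smallest residue index
number_sites <- function(sites) {
  if (nrow(sites) == 0) {
    sites$site_id <- integer(0)
    return(sites[c("site_id", setdiff(names(sites), "site_id"))])
  }
  total <- vapply(sites$time_table, sum, numeric(1))
  min_res <- vapply(sites$residues, min, numeric(1))
  ord <- order(-total, min_res)
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- seq_len(nrow(sites))
  sites[c("site_id", setdiff(names(sites), "site_id"))]
}

#' Merge per-substrate binding sites into one cross-substrate site map
#'
#' Sites discovered separately for each substrate are merged when their
#' residue sets are similar (Jaccard distance at most `jaccard_cutoff`,
#' same agglomeration as the other stages). A merged site keeps one
#' time-table entry per contributing substrate; site ids are reassigned in
#' descending order of total time, ties broken by smallest residue index.
#'
#' @param per_substrate_sites A list of `binding_sites` tibbles (or one
#'   already-combined tibble), one per substrate.
#' @param jaccard_cutoff,linkage As elsewhere.
#' @param aggregator How to combine several same-substrate contributions to
#'   one merged site (default `"median"`, `"sum"` available).
#' @return A `binding_sites` tibble with multi-substrate time tables.
#' @export
merge_sites_across_substrates <- function(per_substrate_sites,
                                          jaccard_cutoff = 0.65,
                                          linkage = "average",
                                          aggregator = c("median", "sum")) {
  aggregator <- match.arg(aggregator)
  if (inherits(per_substrate_sites, "data.frame")) {
    sites <- per_substrate_sites
  } else {
    sites <- bind_rows(per_substrate_sites)
  }
  if (nrow(sites) == 0) abort("no sites to merge")
  d <- jaccard_dist_matrix(sites$residues)
  labels <- agglomerate(d, cutoff = jaccard_cutoff, linkage = linkage)
  agg_fun <- if (aggregator == "median") median else sum

  out <- lapply(sort(unique(labels)), function(k) {
    mem <- sites[labels == k, , drop = FALSE]
    residues <- sort(unique(unlist(mem$residues)))
    tts <- unlist(mem$time_table)
    tt <- vapply(split(unname(tts), names(tts)), agg_fun, numeric(1))
    members <- bind_rows(mem$members)
    n_res <- length(residues)
    tibble(residues = list(residues), n_residues = n_res,
           time_table = list(tt), members = list(members))
  })
  out <- number_sites(bind_rows(out))
  class(out) <- c("binding_sites", class(tibble()))
  out
}

#' Site-by-substrate interaction-time table
#'
#' Spreads the per-site time tables into a wide tibble, one row per site
#' and one column per substrate, `NA` where a substrate never contributed
#' a local cluster to the site.
#'
#' @param sites A `binding_sites` tibble, or a long tibble with columns
#'   `site_id`, `substrate`, `time_ns`.
#' @param substrates Optional column order.
#' @return A tibble: `site_id` plus one numeric column per substrate.
#' @export
site_time_table <- function(sites, substrates = NULL) {
  long <- site_times_long(sites)
  if (is.null(substrates)) substrates <- unique(long$substrate)
  wide <- tidyr::pivot_wider(long, names_from = "substrate",
                             values_from = "time_ns")
  cols <- c("site_id", intersect(substrates, names(wide)))
  wide[order(wide$site_id), cols]
}

site_times_long <- function(sites) {
  if (all(c("site_id", "substrate", "time_ns") %in% names(sites))) {
    return(as_tibble(sites[c("site_id", "substrate", "time_ns")]))
  }
  stopifnot(inherits(sites, "binding_sites"))
  purrr::map2_dfr(sites$site_id, sites$time_table, function(id, tt) {
    tibble(site_id = id, substrate = names(tt), time_ns = unname(tt))
  })
}

#' Write / read a site-by-substrate time report
#'
#' Plain TSV, sites as rows and substrates as columns, times in ns with one
#' decimal and `-` marking site/substrate pairs with no observed
#' interaction. `read_time_table()` reads the same dialect back into a
#' wide tibble (so a packaged report round-trips exactly).
#'
#' @param x A wide tibble from [site_time_table()] (or a `binding_sites`
#'   tibble, converted automatically).
#' @param path Output file.
#' @param comments Optional `#`-prefixed header lines (e.g. a config hash).
#' @return `path` invisibly; for `read_time_table()`, a wide tibble with
#'   `site_id` and one numeric column per substrate (`NA` for `-`).
#' @export
write_time_table <- function(x, path, comments = NULL) {
  if (inherits(x, "binding_sites")) x <- site_time_table(x)
  subs <- setdiff(names(x), "site_id")
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character(0)
  if (!is.null(comments)) lines <- paste0("#", comments)
  lines <- c(lines, paste(c("site_id", subs), collapse = "\t"))
  for (i in seq_len(nrow(x))) {
    vals <- vapply(subs, function(s) {
      v <- x[[s]][i]
      if (is.na(v)) "-" else sprintf("%.1f", v)
    }, character(1))
    lines <- c(lines, paste(c(x$site_id[i], vals), collapse = "\t"))
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_time_table
#' @export
read_time_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- parts[[1]]
  if (hdr[1] != "site_id") abort("time table must start with a site_id column")
  body <- parts[-1]
  vals <- lapply(body, function(p) {
    v <- p[-1]
    suppressWarnings(as.numeric(ifelse(v == "-", NA, v)))
  })
  out <- tibble(site_id = as.integer(vapply(body, `[[`, "", 1)))
  for (k in seq_along(hdr[-1])) {
    out[[hdr[k + 1]]] <- vapply(vals, `[[`, numeric(1), k)
  }
  out
}

#' Write / read binding sites as JSON
#'
#' @param sites A `binding_sites` tibble.
#' @param path JSON file path.
#' @param config_hash Optional hash string embedded in the file.
#' @return `path` invisibly; `read_sites_json()` returns the
#'   `binding_sites` tibble.
#' @export
write_sites_json <- function(sites, path, config_hash = NULL) {
  stopifnot(inherits(sites, "binding_sites"))
  payload <- list(
    config_hash = config_hash,
    sites = lapply(seq_len(nrow(sites)), function(i) {
      mem <- sites$members[[i]]
      list(
        site_id = sites$site_id[i],
        residues = sites$residues[[i]],
        time_table = as.list(sites$time_table[[i]]),
        members = if (!is.null(mem) && nrow(mem) > 0) {
          lapply(seq_len(nrow(mem)), function(j) {
            list(substrate = mem$substrate[j], replica = mem$replica[j],
                 residues = mem$residues[[j]],
                 per_residue_time_ns = as.list(mem$per_residue_time_ns[[j]]),
                 cluster_time_ns = mem$cluster_time_ns[j])
          })
        } else list()
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_sites_json
#' @export
read_sites_json <- function(path) {
  payload <- jsonlite::read_json(path)
  rows <- lapply(payload$sites, function(s) {
    mem <- bind_rows(lapply(s$members, function(m) {
      prt <- unlist(m$per_residue_time_ns)
      tibble(substrate = m$substrate, replica = m$replica,
             residues = list(as.integer(unlist(m$residues))),
             per_residue_time_ns = list(prt),
             cluster_time_ns = as.numeric(m$cluster_time_ns),
             n_residues = length(m$residues))
    }))
    tt <- vapply(s$time_table, as.numeric, numeric(1))
    tibble(site_id = as.integer(s$site_id),
           residues = list(as.integer(unlist(s$residues))),
           n_residues = length(s$residues),
           time_table = list(tt),
           members = list(mem))
  })
  out <- bind_rows(rows)
  class(out) <- c("binding_sites", class(tibble()))
  out
}
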