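#' Pipeline configuration
#'
#' Gathers every tunable of the contact-to-library workflow in one
#' range-checked list: the contact cutoff (2.7 angstrom), the Jaccard
#' dendrogram cut (0.65), the minimum cluster size (3), the
#' fraction-of-maximum key-site rule (0.33), and the library-design caps
#' (at most 10 mutants, 3 per position, ddG at most 0.5 kcal/mol).
#'
#' @param cutoff_angstrom Contact distance cutoff.
#' @param jaccard_cutoff Dendrogram cut height (distance scale).
#' @param min_cluster_size Minimum residues per cluster.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @param aggregator `"median"` or `"sum"` for site times.
#' @param fraction Key-site fraction-of-maximum threshold.
#' @param excluded_residues Transport-pathway residues to exclude.
#' @param ddg_max_kcal_mol Stability filter for candidates.
#' @param max_size,max_variants_per_position Library caps.
#' @param dt_ps Frame spacing.
#' @param seed Seed for any stochastic stage.
#' @return A list of class `run_config` with a `hash` attribute.
#' @export
run_config <- function(cutoff_angstrom = 2.7, jaccard_cutoff = 0.65,
                       min_cluster_size = 3, linkage = "average",
                       aggregator = "median", fraction = 0.33,
                       excluded_residues = integer(),
                       ddg_max_kcal_mol = 0.5, max_size = 10,
                       max_variants_per_position = 3, dt_ps = 2, seed = 1L) {
  stopifnot(cutoff_angstrom > 0, jaccard_cutoff >= 0, jaccard_cutoff <= 1,
            min_cluster_size >= 1, fraction > 0, fraction <= 1,
            max_size >= 0, max_variants_per_position >= 1, dt_ps > 0)
  linkage <- match.arg(linkage, c("average", "single", "complete"))
  aggregator <- match.arg(aggregator, c("median", "sum"))
  cfg <- list(cutoff_angstrom = cutoff_angstrom,
              jaccard_cutoff = jaccard_cutoff,
              min_cluster_size = as.integer(min_cluster_size),
              linkage = linkage, aggregator = aggregator,
              fraction = fraction,
              excluded_residues = sort(as.integer(excluded_residues)),
              ddg_max_kcal_mol = ddg_max_kcal_mol,
              max_size = as.integer(max_size),
              max_variants_per_position = as.integer(max_variants_per_position),
              dt_ps = dt_ps, seed = as.integer(seed))
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate replicas of a synthetic experiment
#'
#' @param spec A [synthetic_spec()].
#' @param n_replicas Number of replicas (default 10, the usual replication
#'   depth of the MD design this emulates).
#' @param substrate Substrate id attached to every replica.
#' @return A list with `matrices` (list of [contact_matrix()]) and `truth`
#'   (the planted-site labels, shared by all replicas).
#' @export
simulate_replicas <- function(spec, n_replicas = 10, substrate = "synthetic") {
  out <- lapply(seq_len(n_replicas), function(i) {
    generate_contact_matrix(spec, substrate = substrate,
                            replica = sprintf("r%d", i),
                            seed_offset = i - 1L)
  })
  list(matrices = lapply(out, `[[`, "matrix"), truth = out[[1]]$truth)
}

#' Run the contact-to-library pipeline
#'
#' Executes the staged workflow: local clustering of each contact matrix,
#' global clustering per substrate, cross-substrate site merging, key-site
#' selection (per substrate, unioned), residue profiling and key-residue
#' classification, and — when a ddG table is supplied — smart-library
#' design. Deterministic given the inputs and configuration; when
#' `out_dir` is given, all result files are written there with the config
#' hash embedded in each header.
#'
#' @param contact_matrices A list of [contact_matrix()] objects (any mix
#'   of substrates and replicas).
#' @param config A [run_config()].
#' @param ddg Optional `ddg_table` for library design.
#' @param out_dir Optional output directory (`sites.json`,
#'   `site_times.tsv`, `key_residues.json`, `library.tsv`).
#' @return A list of class `tbs_run`: `sites` (merged `binding_sites`),
#'   `site_times` (wide tibble), `key_sites` (named list per substrate),
#'   `profiles`, `key_residues`, `library` (or `NULL`), `config`.
#' @export
run_pipeline <- function(contact_matrices, config = run_config(),
                         ddg = NULL, out_dir = NULL) {
  if (length(contact_matrices) == 0) abort("stage contacts: no input matrices")
  locals <- bind_rows(lapply(contact_matrices, function(m) {
    local_cluster(m, jaccard_cutoff = config$jaccard_cutoff,
                  min_cluster_size = config$min_cluster_size,
                  linkage = config$linkage)
  }))
  if (nrow(locals) == 0) abort("stage cluster: no local clusters found")
  per_sub <- lapply(split(locals, locals$substrate), function(ls) {
    global_cluster(ls, jaccard_cutoff = config$jaccard_cutoff,
                   min_cluster_size = config$min_cluster_size,
                   linkage = config$linkage, aggregator = config$aggregator)
  })
  sites <- merge_sites_across_substrates(per_sub,
                                         jaccard_cutoff = config$jaccard_cutoff,
                                         linkage = config$linkage,
                                         aggregator = config$aggregator)
  site_times <- site_time_table(sites)
  site_sets <- stats::setNames(sites$residues, sites$site_id)
  cfg_sel <- selection_config(fraction = config$fraction,
                              excluded_residues = config$excluded_residues)
  substrates <- setdiff(names(site_times), "site_id")
  key_sites <- lapply(stats::setNames(substrates, substrates), function(s) {
    select_key_sites(substrate_times(site_times, s), sites = site_sets,
                     config = cfg_sel)
  })
  key_union <- sort(unique(unlist(key_sites)))
  if (length(key_union) == 0) {
    abort("stage select: no key sites under the current configuration")
  }
  profiles <- build_residue_profiles(
    sites[sites$site_id %in% key_union, , drop = FALSE])
  key_residues <- select_key_residues(profiles)
  lib <- NULL
  if (!is.null(ddg)) {
    lib <- propose_library(
      profiles[profiles$residue %in% key_residues, , drop = FALSE],
      ddg, max_size = config$max_size,
      ddg_max_kcal_mol = config$ddg_max_kcal_mol,
      max_variants_per_position = config$max_variants_per_position)
  }
  res <- list(sites = sites, site_times = site_times, key_sites = key_sites,
              profiles = profiles, key_residues = key_residues,
              library = lib, config = config)
  class(res) <- "tbs_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- attr(config, "hash")
    write_sites_json(sites, file.path(out_dir, "sites.json"),
                     config_hash = h)
    write_time_table(site_times, file.path(out_dir, "site_times.tsv"),
                     comments = sprintf("config_hash=%s", h))
    jsonlite::write_json(
      list(config_hash = h, key_sites = key_sites,
           key_residues = key_residues),
      file.path(out_dir, "key_residues.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(lib)) {
      write_library_tsv(lib, file.path(out_dir, "library.tsv"),
                        comments = sprintf("config_hash=%s", h))
    }
  }
  res
}

#' @export
print.tbs_run <- function(x, ...) {
  cat(sprintf("<tbs_run> %d binding sites, %d key residues%s\n",
              nrow(x$sites), length(x$key_residues),
              if (!is.null(x$library))
                sprintf(", library of %d mutants", nrow(x$library)) else ""))
  invisible(x)
}
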