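#' Tidy a binding-sites table
#'
#' One row per (site, substrate) with the interaction time, the broom-style
#' long view of the site map.
#'
#' @param x A `binding_sites` tibble.
#' @param ... Unused.
#' @return A tibble: `site_id`, `substrate`, `time_ns`, `n_residues`.
#' @export
tidy.binding_sites <- function(x, ...) {
  long <- site_times_long(x)
  sizes <- tibble(site_id = x$site_id, n_residues = x$n_residues)
  left_join(long, sizes, by = "site_id")
}

#' @rdname tidy.binding_sites
#' @return For `glance()`: a one-row tibble with `n_sites`,
#'   `n_substrates`, `n_residues` (distinct residues over all sites),
#'   `total_time_ns`, `max_time_ns`.
#' @export
glance.binding_sites <- function(x, ...) {
  long <- site_times_long(x)
  tibble(n_sites = nrow(x),
         n_substrates = length(unique(long$substrate)),
         n_residues = length(unique(unlist(x$residues))),
         total_time_ns = sum(long$time_ns),
         max_time_ns = if (nrow(long) > 0) max(long$time_ns) else NA_real_)
}

#' Tidy a mutant library
#'
#' @param x A `mutant_library` tibble.
#' @param ... Unused.
#' @return The candidate table as a plain tibble (already tidy: one row
#'   per proposed mutant, in rank order).
#' @export
tidy.mutant_library <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.mutant_library
#' @return For `glance()`: one row with `n_mutants`, `n_positions`,
#'   `mean_ddg`, `n_stabilizing` (ddG < 0).
#' @export
glance.mutant_library <- function(x, ...) {
  tibble(n_mutants = nrow(x),
         n_positions = length(unique(x$position)),
         mean_ddg = if (nrow(x) > 0) mean(x$ddg_kcal_mol) else NA_real_,
         n_stabilizing = sum(x$ddg_kcal_mol < 0))
}
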