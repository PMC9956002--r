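#' Selection configuration for key sites
#'
#' @param fraction Minimum fraction of the longest per-substrate site time a
#'   site must reach to be kept (default 0.33, a hair under one third so a
#'   site at ratio 0.331 — which the strict fraction would reject — stays
#'   in, matching how the rule resolves in practice on real site tables).
#' @param excluded_residues Residues whose sites are excluded (typically
#'   the entrance of the main transport tunnel, whose long interaction
#'   times would otherwise swamp the surface signal).
#' @param exclusion_overlap_min A site is excluded when it shares at least
#'   this many residues with `excluded_residues` (default 1).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(fraction = 0.33, excluded_residues = integer(),
                             exclusion_overlap_min = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1]")
  }
  if (exclusion_overlap_min < 1) {
    abort("`exclusion_overlap_min` must be >= 1")
  }
  structure(list(fraction = fraction,
                 excluded_residues = as.integer(excluded_residues),
                 exclusion_overlap_min = as.integer(exclusion_overlap_min)),
            class = "selection_config")
}

#' Select key binding sites for one substrate
#'
#' A site is excluded when its residue set overlaps the exclusion list by
#' at least `exclusion_overlap_min` residues (or when it is named in
#' `excluded_sites`). The longest binding time `T_max` is taken over ALL
#' sites, excluded ones included; the key sites are the non-excluded sites
#' whose time is at least `fraction * T_max`.
#'
#' @param time_table Named numeric vector or two-column tibble
#'   (`site_id`, `time_ns`) of per-site interaction times for one substrate.
#' @param sites Optional named list mapping site id to its residue set,
#'   used for the residue-overlap exclusion.
#' @param config A [selection_config()].
#' @param excluded_sites Optional site ids to exclude directly (useful when
#'   only a published time table, not the residue sets, is available).
#' @return Integer vector of selected site ids (sorted). Empty, with a
#'   warning, if every site is excluded.
#' @examples
#' tt <- c(`1` = 82.9, `3` = 68.9, `4` = 45.8, `5` = 32.8, `6` = 16.5)
#' select_key_sites(tt, excluded_sites = 1) # 3 4 5
#' @export
select_key_sites <- function(time_table, sites = NULL,
                             config = selection_config(),
                             excluded_sites = integer()) {
  if (inherits(time_table, "data.frame")) {
    tt <- stats::setNames(time_table$time_ns, time_table$site_id)
  } else {
    tt <- time_table
  }
  tt <- tt[!is.na(tt)]
  if (length(tt) == 0) abort("empty time table")
  if (any(tt < 0)) abort("negative interaction time")
  ids <- as.integer(names(tt))
  excluded <- ids %in% as.integer(excluded_sites)
  if (!is.null(sites)) {
    overlap <- vapply(as.character(ids), function(id) {
      rs <- sites[[id]]
      if (is.null(rs)) 0L else length(intersect(as.integer(rs),
                                                config$excluded_residues))
    }, integer(1))
    excluded <- excluded | overlap >= config$exclusion_overlap_min
  }
  t_max <- max(tt)
  keep <- !excluded & tt / t_max >= config$fraction
  if (all(excluded)) {
    warn("all sites excluded; no key sites selected")
  }
  sort(ids[keep])
}

#' Per-residue interaction-time profiles across key sites
#'
#' Gathers, for every residue appearing in the key sites, the interaction
#' times of that residue in each member local cluster containing it, and
#' summarises them by the median (mean-of-middle-two for even counts, the
#' standard convention).
#'
#' @param sites A `binding_sites` tibble restricted to key sites (e.g.
#'   `dplyr::filter(sites, site_id %in% key)`).
#' @return A tibble of class `residue_profiles`: `residue`, `times_ns`
#'   (list column of per-local-cluster times), `n_obs`, `median_time_ns`.
#' @export
build_residue_profiles <- function(sites) {
  stopifnot(inherits(sites, "binding_sites"))
  members <- bind_rows(sites$members)
  if (nrow(members) == 0) abort("sites carry no member local clusters")
  long <- purrr::pmap_dfr(
    list(members$substrate, members$replica, members$per_residue_time_ns),
    function(sub, rep, prt) {
      tibble(substrate = sub, replica = rep,
             residue = as.integer(names(prt)), time_ns = unname(prt))
    })
  out <- long %>%
    group_by(.data$residue) %>%
    summarise(times_ns = list(.data$time_ns), n_obs = n(),
              median_time_ns = median(.data$time_ns), .groups = "drop") %>%
    arrange(.data$residue)
  class(out) <- c("residue_profiles", class(tibble()))
  out
}

#' Classify key residues by the median-of-medians rule
#'
#' Let `M` be the median over residues of the per-residue median
#' interaction times. Every residue whose median time is greater than or
#' equal to `M` is a key residue; by construction at least half the
#' profiled residues qualify.
#'
#' @param profiles A `residue_profiles` tibble from
#'   [build_residue_profiles()].
#' @return Sorted integer vector of key residue indices.
#' @export
select_key_residues <- function(profiles) {
  if (nrow(profiles) == 0) abort("no residue profiles")
  M <- median(profiles$median_time_ns)
  sort(profiles$residue[profiles$median_time_ns >= M])
}

#' Compare wild-type and mutant per-site interaction times
#'
#' Percent change per site, `100 * (mut - wt) / wt`, flagged `substantial`
#' when its magnitude exceeds 50 and `minor` when it is below 20 — the
#' thresholds used to judge whether a mutation perturbed its own binding
#' site while leaving the rest of the surface map intact. A site with zero
#' or missing wild-type time but mutant signal is reported as `new` with no
#' percentage.
#'
#' @param wt_site_times,mut_site_times Named numeric vectors (site id ->
#'   time in ns) over a shared site universe.
#' @param mutated_site Site id carrying the mutation; must be present in
#'   both tables (validation error otherwise) and is marked in the output.
#' @return A tibble: `site_id`, `wt_ns`, `mut_ns`, `pct_change`, `flag`
#'   (`substantial` / `minor` / `intermediate` / `new`), `is_mutated_site`.
#' @export
compare_profiles <- function(wt_site_times, mut_site_times, mutated_site) {
  wt <- wt_site_times
  mut <- mut_site_times
  ids <- union(names(wt), names(mut))
  ms <- as.character(mutated_site)
  if (!(ms %in% names(wt)) || !(ms %in% names(mut))) {
    abort("`mutated_site` must be present in both time tables")
  }
  rows <- lapply(ids, function(id) {
    w <- if (id %in% names(wt)) wt[[id]] else NA_real_
    m <- if (id %in% names(mut)) mut[[id]] else NA_real_
    if (is.na(w) || w == 0) {
      pct <- NA_real_
      flag <- if (!is.na(m) && m > 0) "new" else "minor"
    } else {
      m0 <- if (is.na(m)) 0 else m
      pct <- 100 * (m0 - w) / w
      flag <- if (abs(pct) > 50) "substantial"
              else if (abs(pct) < 20) "minor" else "intermediate"
    }
    tibble(site_id = id, wt_ns = w, mut_ns = m, pct_change = pct,
           flag = flag, is_mutated_site = id == ms)
  })
  bind_rows(rows) %>% arrange(.data$site_id)
}

#' Read a residue exclusion list
#'
#' One residue index per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return Sorted integer vector.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.integer(lines))
  if (anyNA(vals)) abort("non-integer entry in exclusion list")
  sort(unique(vals))
}
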