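#' Published site-by-substrate interaction-time table for LinB
#'
#' The packaged reference table of cumulative interaction times (ns)
#' between seven haloalkane substrates and the nine transient binding
#' sites mapped on the surface of the haloalkane dehalogenase LinB:
#' 1-chlorohexane (1CH), 1-bromobutane (1BB), 1-iodopropane (1IP),
#' 1,2-dibromoethane (12DBE), 1,2-dibromopropane (12DBP),
#' bromocyclohexane (BCH) and chlorocyclopentane (CCP). Site 1 is the
#' entrance of the main p1 transport tunnel. Absent cells (`NA`) mean the
#' site was not observed for that substrate.
#'
#' @return A wide tibble: `site_id` plus one numeric column per substrate
#'   code.
#' @examples
#' tt <- load_site_times()
#' tt$`1CH`[tt$site_id == 5] # 96.6
#' @export
load_site_times <- function() {
  path <- system.file("extdata", "linb_site_times.tsv", package = "tbsmap",
                      mustWork = TRUE)
  read_time_table(path)
}

#' One substrate column of a wide time table, as a named vector
#'
#' @param time_table A wide tibble from [load_site_times()] or
#'   [site_time_table()].
#' @param substrate Column name.
#' @param drop_na Drop absent sites (default TRUE).
#' @return Named numeric vector (site id -> time in ns).
#' @export
substrate_times <- function(time_table, substrate, drop_na = TRUE) {
  if (!substrate %in% names(time_table)) {
    abort(sprintf("no substrate column '%s'", substrate))
  }
  v <- stats::setNames(time_table[[substrate]], time_table$site_id)
  if (drop_na) v <- v[!is.na(v)]
  v
}
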