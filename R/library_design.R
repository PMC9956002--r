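#' Read a folding free-energy change (ddG) table
#'
#' TSV with columns `position`, `wt_aa`, `mut_aa`, `ddg_kcal_mol` — the
#' layout produced by exhaustive single-point mutational scanning with a
#' stability predictor (positions x 19 substitutions). Positive values are
#' destabilizing in the standard convention.
#'
#' @param path TSV path (a header row with these column names is expected;
#'   `#` comment lines are skipped).
#' @param flip_sign If `TRUE` all ddG values are negated, for tables
#'   exported with the opposite sign convention.
#' @return A tibble of class `ddg_table` with columns `position`, `wt_aa`,
#'   `mut_aa`, `ddg_kcal_mol`. Duplicate (position, mut_aa) rows keep the
#'   last value, with a warning. An empty file yields an empty table with
#'   a warning.
#' @export
read_ddg_table <- function(path, flip_sign = FALSE) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_guess(),
                                                wt_aa = readr::col_character(),
                                                mut_aa = readr::col_character()))
  if (nrow(df) == 0) {
    warn(sprintf("ddG table %s is empty", path))
    out <- tibble(position = integer(), wt_aa = character(),
                  mut_aa = character(), ddg_kcal_mol = numeric())
    class(out) <- c("ddg_table", class(out))
    return(out)
  }
  need <- c("position", "wt_aa", "mut_aa", "ddg_kcal_mol")
  if (!all(need %in% names(df))) {
    abort(sprintf("ddG table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  df <- df %>%
    mutate(position = as.integer(.data$position),
           wt_aa = toupper(.data$wt_aa), mut_aa = toupper(.data$mut_aa),
           ddg_kcal_mol = as.numeric(.data$ddg_kcal_mol))
  bad <- !(df$wt_aa %in% AA_LETTERS) | !(df$mut_aa %in% AA_LETTERS)
  if (any(bad)) {
    abort(sprintf("invalid amino-acid letter in ddG table row %d",
                  which(bad)[1]))
  }
  if (any(df$wt_aa == df$mut_aa)) {
    abort(sprintf("wild-type equals mutant in ddG table row %d",
                  which(df$wt_aa == df$mut_aa)[1]))
  }
  dup <- duplicated(df[c("position", "mut_aa")], fromLast = TRUE)
  if (any(dup)) {
    warn(sprintf("%d duplicate (position, mut_aa) rows; keeping last",
                 sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  # one wild-type identity per position
  wt_chk <- df %>% group_by(.data$position) %>%
    summarise(k = dplyr::n_distinct(.data$wt_aa), .groups = "drop")
  if (any(wt_chk$k > 1)) {
    abort(sprintf("conflicting wild-type letters at position %d",
                  wt_chk$position[wt_chk$k > 1][1]))
  }
  if (flip_sign) df$ddg_kcal_mol <- -df$ddg_kcal_mol
  out <- arrange(df, .data$position, .data$mut_aa)
  class(out) <- c("ddg_table", class(tibble()))
  out
}

#' Physicochemical-change score of a substitution
#'
#' Scores how strongly a substitution changes residue character, using five
#' classes: aliphatic/small (A V L I M G P), aromatic (F W Y),
#' polar-uncharged (S T N Q C), positive (K R H), negative (D E).
#' Preferred character-flipping swaps score 2: aliphatic/aromatic in either
#' direction, charged to polar-uncharged (and back, e.g. a glutamate to its
#' amide counterpart glutamine), positive/negative, and charge-introducing
#' swaps from nonpolar to charged. Any other cross-class change scores 1;
#' within-class changes score 0.
#'
#' @param wt_aa,mut_aa Single amino-acid letters (vectorised).
#' @return Integer score(s) in `{0, 1, 2}`.
#' @examples
#' physchem_change_score("A", "F") # 2
#' physchem_change_score("E", "Q") # 2
#' physchem_change_score("A", "V") # 0
#' @export
physchem_change_score <- function(wt_aa, mut_aa) {
  wt_aa <- toupper(wt_aa)
  mut_aa <- toupper(mut_aa)
  if (!all(wt_aa %in% AA_LETTERS) || !all(mut_aa %in% AA_LETTERS)) {
    abort("invalid amino-acid letter")
  }
  score1 <- function(w, m) {
    cw <- AA_CLASS[[w]]
    cm <- AA_CLASS[[m]]
    if (cw == cm) return(0L)
    pair <- sort(c(cw, cm))
    charged <- c("positive", "negative")
    nonpolar <- c("aliphatic", "aromatic")
    preferred <-
      identical(pair, c("aliphatic", "aromatic")) ||
      identical(pair, c("negative", "positive")) ||
      (any(pair %in% charged) && "polar" %in% pair) ||
      (any(pair %in% charged) && any(pair %in% nonpolar))
    if (preferred) 2L else 1L
  }
  mapply(score1, wt_aa, mut_aa, USE.NAMES = FALSE)
}

#' Propose a ranked smart library of single-point mutants
#'
#' Candidates are every (key residue, substitution) pair in the ddG table
#' passing the stability filter `ddg <= ddg_max_kcal_mol` (neutral or
#' stabilizing by default). Ranking is a deterministic total order:
#' physicochemical-change score descending, then ddG ascending, then the
#' residue's median interaction time descending, then position, then
#' substitution letter. The list is truncated to at most
#' `max_variants_per_position` per position and `max_size` overall.
#'
#' @param key_residues Either an integer vector of residue positions or a
#'   tibble/`residue_profiles` with columns `residue` and `median_time_ns`
#'   (times feed the third ranking criterion; absent times count as 0).
#' @param ddg A `ddg_table` from [read_ddg_table()].
#' @param max_size Library size cap (default 10).
#' @param ddg_max_kcal_mol Stability filter threshold (default 0.5).
#' @param max_variants_per_position Per-position cap (default 3).
#' @return A tibble of class `mutant_library`: `rank`, `mutation` (e.g.
#'   `"A189F"`), `position`, `wt_aa`, `mut_aa`, `ddg_kcal_mol`,
#'   `physchem_score`, `median_time_ns`. Key residues missing from the ddG
#'   table are reported in a warning and skipped.
#' @export
propose_library <- function(key_residues, ddg, max_size = 10,
                            ddg_max_kcal_mol = 0.5,
                            max_variants_per_position = 3) {
  if (inherits(key_residues, "data.frame")) {
    pos <- as.integer(key_residues$residue)
    times <- stats::setNames(as.numeric(key_residues$median_time_ns),
                             pos)
  } else {
    pos <- as.integer(key_residues)
    times <- stats::setNames(rep(0, length(pos)), pos)
  }
  empty <- tibble(rank = integer(), mutation = character(),
                  position = integer(), wt_aa = character(),
                  mut_aa = character(), ddg_kcal_mol = numeric(),
                  physchem_score = integer(), median_time_ns = numeric())
  class(empty) <- c("mutant_library", class(empty))
  if (length(pos) == 0) return(empty)
  missing <- setdiff(pos, unique(ddg$position))
  if (length(missing) > 0) {
    warn(sprintf("key residues absent from ddG table, skipped: %s",
                 paste(sort(missing), collapse = ", ")))
  }
  cand <- ddg %>%
    filter(.data$position %in% pos,
           .data$ddg_kcal_mol <= ddg_max_kcal_mol)
  if (nrow(cand) == 0) return(empty)
  cand <- cand %>%
    mutate(physchem_score = physchem_change_score(.data$wt_aa, .data$mut_aa),
           median_time_ns = unname(times[as.character(.data$position)]),
           median_time_ns = dplyr::coalesce(.data$median_time_ns, 0)) %>%
    arrange(desc(.data$physchem_score), .data$ddg_kcal_mol,
            desc(.data$median_time_ns), .data$position, .data$mut_aa) %>%
    group_by(.data$position) %>%
    mutate(.per_pos = row_number()) %>%
    ungroup() %>%
    filter(.data$.per_pos <= max_variants_per_position) %>%
    select(-".per_pos") %>%
    utils::head(max_size) %>%
    mutate(rank = row_number(),
           mutation = paste0(.data$wt_aa, .data$position, .data$mut_aa)) %>%
    select("rank", "mutation", "position", "wt_aa", "mut_aa",
           "ddg_kcal_mol", "physchem_score", "median_time_ns")
  class(cand) <- c("mutant_library", class(tibble()))
  cand
}

#' Write a mutant library TSV
#'
#' @param lib A `mutant_library` tibble.
#' @param path Output path.
#' @param comments Optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path, comments = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character(0)
  if (!is.null(comments)) lines <- paste0("#", comments)
  lines <- c(lines,
             "rank\tmutation\tddg_kcal_mol\tphyschem_score\tmedian_time_ns")
  lines <- c(lines, sprintf("%d\t%s\t%.3f\t%d\t%.4f",
                            lib$rank, lib$mutation, lib$ddg_kcal_mol,
                            lib$physchem_score, lib$median_time_ns))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
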