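#' Sparse binary contact matrix for one (substrate, replica)
#'
#' A contact matrix records, for one simulation replica of one substrate,
#' which protein residues are in contact with any ligand copy at each saved
#' frame. Because transient binding events are rare relative to the
#' trajectory length, the matrix is sparse and is stored as a tibble of
#' (residue, frame) entries rather than a dense residue-by-frame array.
#'
#' @param entries A tibble or data frame with integer columns `residue`
#'   (1-based) and `frame` (0-based). Duplicate rows are collapsed: the
#'   matrix is binary.
#' @param n_residues,n_frames Matrix dimensions. Every `residue` must lie in
#'   `[1, n_residues]` and every `frame` in `[0, n_frames - 1]`.
#' @param dt_ps Time between saved frames in picoseconds (default 2, the
#'   typical save interval for the trajectories this analysis targets).
#' @param substrate,replica Identifiers carried through clustering and
#'   reporting.
#'
#' @return A tibble of class `contact_matrix` with columns `residue` and
#'   `frame`, sorted, plus metadata attributes `substrate`, `replica`,
#'   `n_residues`, `n_frames`, `dt_ps`.
#' @examples
#' m <- contact_matrix(tibble::tibble(residue = c(3L, 3L), frame = c(0L, 1L)),
#'                     n_residues = 5, n_frames = 10)
#' residue_interaction_time(m)
#' @export
contact_matrix <- function(entries, n_residues, n_frames, dt_ps = 2,
                           substrate = "substrate", replica = "r1") {
  entries <- as_tibble(entries)
  if (!all(c("residue", "frame") %in% names(entries))) {
    abort("`entries` must have columns `residue` and `frame`.")
  }
  n_residues <- as.integer(n_residues)
  n_frames <- as.integer(n_frames)
  if (length(n_residues) != 1 || is.na(n_residues) || n_residues < 1) {
    abort("`n_residues` must be a single positive integer.")
  }
  if (length(n_frames) != 1 || is.na(n_frames) || n_frames < 1) {
    abort("`n_frames` must be a single positive integer.")
  }
  if (!is.numeric(dt_ps) || length(dt_ps) != 1 || is.na(dt_ps) || dt_ps <= 0) {
    abort("`dt_ps` must be a single positive number.")
  }
  entries <- entries %>%
    mutate(residue = as.integer(.data$residue),
           frame = as.integer(.data$frame)) %>%
    distinct(.data$residue, .data$frame) %>%
    arrange(.data$residue, .data$frame)
  if (nrow(entries) > 0) {
    bad_r <- entries$residue < 1L | entries$residue > n_residues
    if (any(bad_r)) {
      abort(sprintf("residue index out of range [1, %d]: %s",
                    n_residues,
                    paste(unique(entries$residue[bad_r]), collapse = ", ")))
    }
    bad_f <- entries$frame < 0L | entries$frame > n_frames - 1L
    if (any(bad_f)) {
      abort(sprintf("frame index out of range [0, %d]: %s",
                    n_frames - 1L,
                    paste(unique(entries$frame[bad_f]), collapse = ", ")))
    }
  }
  structure(
    entries,
    substrate = as.character(substrate),
    replica = as.character(replica),
    n_residues = n_residues,
    n_frames = n_frames,
    dt_ps = as.numeric(dt_ps),
    class = c("contact_matrix", class(tibble()))
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> substrate=%s replica=%s  %d residues x %d frames, dt=%g ps, %d entries\n",
    attr(x, "substrate"), attr(x, "replica"),
    attr(x, "n_residues"), attr(x, "n_frames"), attr(x, "dt_ps"), nrow(x)))
  NextMethod()
}

cm_meta <- function(m) {
  list(substrate = attr(m, "substrate"), replica = attr(m, "replica"),
       n_residues = attr(m, "n_residues"), n_frames = attr(m, "n_frames"),
       dt_ps = attr(m, "dt_ps"))
}

#' Per-residue frame supports of a contact matrix
#'
#' Returns, for each residue with at least one contact, the set of frames at
#' which it touches the ligand. These supports are the binary fingerprints
#' that enter Jaccard clustering.
#'
#' @param m A [contact_matrix()].
#' @return A named list mapping residue index (as character name) to a sorted
#'   integer vector of 0-based frame indices. Residues with no contacts are
#'   omitted.
#' @export
frame_supports <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  split(m$frame, m$residue)
}

#' Total ligand-interaction time per residue
#'
#' The interaction time of a residue is the number of frames in which it
#' contacts any ligand copy, times the frame spacing. Reported in
#' nanoseconds.
#'
#' @param m A [contact_matrix()].
#' @param residues Optional integer vector of residue indices to report; by
#'   default all residues `1:n_residues` (zero time for residues without
#'   contacts). Out-of-range indices are an error.
#' @return A tibble with columns `residue`, `n_contact_frames`, `time_ns`.
#' @export
residue_interaction_time <- function(m, residues = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  meta <- cm_meta(m)
  if (is.null(residues)) {
    residues <- seq_len(meta$n_residues)
  }
  residues <- as.integer(residues)
  if (any(residues < 1L | residues > meta$n_residues)) {
    abort(sprintf("residue index out of range [1, %d]", meta$n_residues))
  }
  counts <- m %>%
    group_by(.data$residue) %>%
    summarise(n_contact_frames = n(), .groups = "drop")
  tibble(residue = residues) %>%
    left_join(counts, by = "residue") %>%
    mutate(n_contact_frames = dplyr::coalesce(.data$n_contact_frames, 0L),
           time_ns = .data$n_contact_frames * meta$dt_ps / 1000)
}

#' Read a contact table TSV
#'
#' The contact-table dialect is a plain TSV with metadata header lines
#' (`#substrate=`, `#replica=`, `#n_residues=`, `#n_frames=`, `#dt_ps=`)
#' followed by one `residue<TAB>frame` row per contact entry. It round-trips
#' exactly with [write_contact_table()].
#'
#' @param path Path to a contact TSV.
#' @return A [contact_matrix()].
#' @export
read_contact_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  hdr <- hdr[grepl("=", hdr, fixed = TRUE)]
  keys <- sub("^#([^=]+)=.*$", "\\1", hdr)
  vals <- sub("^#[^=]+=", "", hdr)
  meta <- stats::setNames(as.list(vals), keys)
  required <- c("substrate", "replica", "n_residues", "n_frames", "dt_ps")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("contact table %s is missing header keys: %s",
                  path, paste(missing, collapse = ", ")))
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) > 0) {
    parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
    ok <- lengths(parts) == 2
    if (!all(ok)) {
      abort(sprintf("malformed contact row at line %d of %s",
                    body_idx[which(!ok)[1]], path))
    }
    res <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
    frm <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
    if (anyNA(res) || anyNA(frm)) {
      bad <- body_idx[which(is.na(res) | is.na(frm))[1]]
      abort(sprintf("non-integer contact row at line %d of %s", bad, path))
    }
    n_res <- as.integer(meta$n_residues)
    n_frm <- as.integer(meta$n_frames)
    bad <- res < 1L | res > n_res | frm < 0L | frm > n_frm - 1L
    if (any(bad)) {
      abort(sprintf("index out of range at line %d of %s",
                    body_idx[which(bad)[1]], path))
    }
    entries <- tibble(residue = res, frame = frm)
  } else {
    entries <- tibble(residue = integer(), frame = integer())
  }
  contact_matrix(entries,
                 n_residues = as.integer(meta$n_residues),
                 n_frames = as.integer(meta$n_frames),
                 dt_ps = as.numeric(meta$dt_ps),
                 substrate = meta$substrate,
                 replica = meta$replica)
}

#' Write a contact table TSV
#'
#' @param m A [contact_matrix()].
#' @param path Output path. UTF-8, LF newlines.
#' @return `path`, invisibly.
#' @rdname read_contact_table
#' @export
write_contact_table <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  meta <- cm_meta(m)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    sprintf("#substrate=%s", meta$substrate),
    sprintf("#replica=%s", meta$replica),
    sprintf("#n_residues=%d", meta$n_residues),
    sprintf("#n_frames=%d", meta$n_frames),
    sprintf("#dt_ps=%s", format(meta$dt_ps, scientific = FALSE))
  )
  body <- sprintf("%d\t%d", m$residue, m$frame)
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
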