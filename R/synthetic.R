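#' Specify a planted transient binding site
#'
#' A planted site is a disjoint group of residues that the synthetic
#' generator touches together in episodes: binding events start at random
#' while the site is idle, last a geometrically distributed number of
#' frames (discrete memoryless dwell), and during an event each member
#' residue registers a contact independently per frame.
#'
#' @param residues Integer vector of member residue indices (non-empty).
#' @param event_rate_per_frame Probability an idle site starts an episode
#'   at a given frame (default 0.01).
#' @param mean_dwell_frames Mean episode length in frames (default 30; at
#'   2 ps per frame that is a 60 ps dwell, a short-lived surface visit).
#' @param co_contact_prob Per-frame contact probability of each member
#'   residue during an episode (default 0.9).
#' @return A list of class `planted_site`.
#' @export
planted_site <- function(residues, event_rate_per_frame = 0.01,
                         mean_dwell_frames = 30, co_contact_prob = 0.9) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0) abort("planted site needs residues")
  stopifnot(event_rate_per_frame >= 0, event_rate_per_frame <= 1,
            mean_dwell_frames >= 1,
            co_contact_prob >= 0, co_contact_prob <= 1)
  structure(list(residues = residues,
                 event_rate_per_frame = event_rate_per_frame,
                 mean_dwell_frames = mean_dwell_frames,
                 co_contact_prob = co_contact_prob),
            class = "planted_site")
}

#' Specify a synthetic contact-matrix experiment
#'
#' @param n_residues,n_frames Matrix dimensions (defaults 60 residues,
#'   2000 frames — a desk-scale stand-in for a long production run).
#' @param dt_ps Frame spacing (default 2 ps).
#' @param sites List of [planted_site()]s; residue sets must be pairwise
#'   disjoint so ground truth is a partition.
#' @param background_rate_per_residue_frame Independent per-(residue,
#'   frame) contact probability outside episodes (default 0.005).
#' @param seed Integer seed; identical specs give identical matrices.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 60, n_frames = 2000, dt_ps = 2,
                           sites = list(),
                           background_rate_per_residue_frame = 0.005,
                           seed = 1L) {
  stopifnot(n_residues >= 1, n_frames >= 1, dt_ps > 0,
            background_rate_per_residue_frame >= 0,
            background_rate_per_residue_frame <= 1)
  all_res <- unlist(lapply(sites, `[[`, "residues"))
  if (anyDuplicated(all_res)) abort("planted sites must be pairwise disjoint")
  if (length(all_res) > 0 && (min(all_res) < 1 || max(all_res) > n_residues)) {
    abort("planted-site residues out of range")
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 sites = sites,
                 background_rate_per_residue_frame =
                   background_rate_per_residue_frame,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# episode occupancy (0/1 per frame) for one site: alternating geometric
# idle gaps and dwells
simulate_occupancy <- function(n_frames, event_rate, mean_dwell) {
  occupied <- logical(n_frames)
  if (event_rate <= 0) return(occupied)
  f <- 1L
  while (f <= n_frames) {
    gap <- stats::rgeom(1, prob = event_rate)      # idle frames before start
    start <- f + gap
    if (start > n_frames) break
    dwell <- 1L + stats::rgeom(1, prob = 1 / mean_dwell)
    end <- min(start + dwell - 1L, n_frames)
    occupied[start:end] <- TRUE
    f <- end + 1L
  }
  occupied
}

#' Generate a synthetic contact matrix with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param substrate,replica Identifiers for the resulting matrix.
#' @param seed_offset Added to `spec$seed`, so replicas of one spec differ
#'   reproducibly.
#' @return A list with `matrix` (a [contact_matrix()]) and `truth` (a
#'   tibble `residue`, `site` — the planted-site label per residue, 0 for
#'   background).
#' @export
generate_contact_matrix <- function(spec, substrate = "synthetic",
                                    replica = "r1", seed_offset = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed + as.integer(seed_offset), {
    rows <- list()
    for (s in spec$sites) {
      occ <- simulate_occupancy(spec$n_frames, s$event_rate_per_frame,
                                s$mean_dwell_frames)
      occ_frames <- which(occ)
      if (length(occ_frames) > 0) {
        for (r in s$residues) {
          hit <- occ_frames[stats::runif(length(occ_frames)) <=
                              s$co_contact_prob]
          if (length(hit) > 0) {
            rows[[length(rows) + 1L]] <-
              tibble(residue = r, frame = hit - 1L)
          }
        }
      }
    }
    bg <- spec$background_rate_per_residue_frame
    if (bg > 0) {
      n_total <- spec$n_residues * spec$n_frames
      n_bg <- stats::rbinom(1, n_total, bg)
      if (n_bg > 0) {
        cells <- sample.int(n_total, n_bg)
        rows[[length(rows) + 1L]] <-
          tibble(residue = ((cells - 1L) %% spec$n_residues) + 1L,
                 frame = (cells - 1L) %/% spec$n_residues)
      }
    }
    entries <- if (length(rows) > 0) bind_rows(rows) else
      tibble(residue = integer(), frame = integer())
  })
  m <- contact_matrix(entries, n_residues = spec$n_residues,
                      n_frames = spec$n_frames, dt_ps = spec$dt_ps,
                      substrate = substrate, replica = replica)
  truth <- tibble(residue = seq_len(spec$n_residues), site = 0L)
  for (k in seq_along(spec$sites)) {
    truth$site[spec$sites[[k]]$residues] <- k
  }
  list(matrix = m, truth = truth)
}

#' Generate a toy multi-model PDB trajectory
#'
#' Builds a minimal protein (one CA atom per residue on a line, 5 angstrom
#' apart) and a single-atom ligand that approaches a designated residue,
#' sits at a scripted distance for a window of frames, and departs. Useful
#' for exercising contact detection end to end, including the boundary
#' case of a contact at exactly the cutoff distance.
#'
#' @param n_residues Number of protein residues (>= 2).
#' @param n_frames Trajectory length.
#' @param contact_frames 0-based frames at which the ligand is in contact.
#' @param target_residue Residue the ligand approaches (default 1).
#' @param contact_distance Ligand-CA distance during contact frames
#'   (default 2.5); set 2.7 to probe the boundary rule.
#' @param away_distance Distance in non-contact frames (default 20).
#' @param path Output PDB path.
#' @return `path`, invisibly. The file holds `n_frames` MODEL blocks with
#'   residues `ALA` chain A and a ligand `LIG` chain L.
#' @export
generate_toy_system <- function(n_residues, n_frames, contact_frames,
                                target_residue = 1, contact_distance = 2.5,
                                away_distance = 20, path = tempfile(fileext = ".pdb")) {
  stopifnot(n_residues >= 2, n_frames >= 1)
  contact_frames <- as.integer(contact_frames)
  stopifnot(all(contact_frames >= 0), all(contact_frames <= n_frames - 1))
  lines <- character(0)
  ca_x <- (seq_len(n_residues) - 1) * 5
  for (f in seq_len(n_frames) - 1L) {
    lines <- c(lines, sprintf("MODEL     %4d", f + 1L))
    for (r in seq_len(n_residues)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        r, r, ca_x[r], 0, 0))
    }
    d <- if (f %in% contact_frames) contact_distance else away_distance
    lines <- c(lines, sprintf(
      "HETATM%5d  C1  LIG L%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      n_residues + 1L, 900L, ca_x[target_residue], d, 0))
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}
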