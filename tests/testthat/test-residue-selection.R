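test_that("key-site rule reproduces the published per-substrate selections", {
  tt <- load_site_times()
  bch <- substrate_times(tt, "BCH")
  expect_equal(bch[["1"]], 82.9)
  expect_equal(select_key_sites(bch, excluded_sites = 1), c(3L, 4L, 5L))
  ch <- substrate_times(tt, "1CH")
  # 32.0 / 96.6 = 0.331 clears the 0.33 fraction; 23.0 / 96.6 does not
  expect_equal(select_key_sites(ch, excluded_sites = 1), c(4L, 5L, 7L))
})

test_that("a single non-excluded site with positive time is selected", {
  expect_equal(select_key_sites(c(`2` = 5)), 2L)
})

test_that("exclusion works through residue overlap with the exclusion list", {
  tt <- c(`1` = 100, `2` = 60, `3` = 40)
  sites <- list(`1` = c(10L, 11L), `2` = c(20L, 21L), `3` = c(30L, 31L))
  cfg <- selection_config(excluded_residues = c(11L))
  got <- select_key_sites(tt, sites = sites, config = cfg)
  expect_equal(got, c(2L, 3L)) # T_max still from excluded site 1
  # overlap below the minimum is not excluded
  cfg2 <- selection_config(excluded_residues = c(11L),
                           exclusion_overlap_min = 2L)
  expect_equal(select_key_sites(tt, sites = sites, config = cfg2), 1:3)
  # selected sites never overlap the exclusion list at the threshold
  for (id in got) {
    expect_lt(length(intersect(sites[[as.character(id)]],
                               cfg$excluded_residues)), 1)
  }
})

test_that("raising the fraction never enlarges the selection", {
  set.seed(67)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    tt <- stats::setNames(round(runif(n, 1, 100), 1), seq_len(n))
    prev <- NULL
    for (f in c(0.1, 0.33, 0.5, 0.8, 1)) {
      cur <- select_key_sites(tt, config = selection_config(fraction = f))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("all-excluded tables warn and select nothing", {
  expect_warning(got <- select_key_sites(c(`1` = 10), excluded_sites = 1),
                 "all sites excluded")
  expect_length(got, 0)
})

test_that("residue profiles pool local-cluster times and take medians", {
  sites <- make_sites(
    list(c(5L, 6L, 7L)),
    list(dplyr::bind_rows(
      member_row("s1", "r1", c(5, 6, 7), c(4, 4, 10), 10),
      member_row("s1", "r2", c(5, 6), c(6, 6), 8),
      member_row("s1", "r3", c(5,  7), c(10, 2), 10)
    ))
  )
  prof <- build_residue_profiles(sites)
  expect_equal(prof$residue, 5:7)
  expect_equal(prof$median_time_ns[prof$residue == 5], 6)   # 4, 6, 10
  expect_equal(prof$median_time_ns[prof$residue == 6], 5)   # 4, 6 -> 5
  expect_equal(prof$median_time_ns[prof$residue == 7], 6)   # 10, 2 -> 6
})

test_that("median-of-medians rule keeps residues at or above the median", {
  prof <- tibble::tibble(residue = 1:3, times_ns = list(5, 10, 15),
                         n_obs = 1L, median_time_ns = c(5, 10, 15))
  class(prof) <- c("residue_profiles", class(tibble::tibble()))
  expect_equal(select_key_residues(prof), c(2L, 3L))
  prof$median_time_ns <- c(7, 7, 7)
  expect_equal(select_key_residues(prof), 1:3)
  expect_equal(select_key_residues(prof[1, ]), 1L)
})

test_that("at least half the profiled residues are always key residues", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(1:15, 1)
    prof <- tibble::tibble(residue = seq_len(n),
                           times_ns = as.list(runif(n)),
                           n_obs = 1L,
                           median_time_ns = round(runif(n, 0, 20), 2))
    class(prof) <- c("residue_profiles", class(tibble::tibble()))
    expect_gte(length(select_key_residues(prof)), ceiling(n / 2))
  }
})

test_that("profile comparison flags the published thresholds", {
  got <- compare_profiles(c(`1` = 40), c(`1` = 18), mutated_site = 1)
  expect_equal(got$pct_change, -55)
  expect_equal(got$flag, "substantial")
  expect_true(got$is_mutated_site)

  same <- compare_profiles(c(`1` = 10, `2` = 3), c(`1` = 10, `2` = 3), 1)
  expect_true(all(same$pct_change == 0))
  expect_true(all(same$flag == "minor"))

  minor <- compare_profiles(c(`1` = 10), c(`1` = 11.5), 1)
  expect_equal(minor$pct_change, 15)
  expect_equal(minor$flag, "minor")
})

test_that("comparison handles new sites and validates the mutated site", {
  got <- compare_profiles(c(`1` = 10, `2` = 0), c(`1` = 10, `2` = 4), 1)
  expect_equal(got$flag[got$site_id == "2"], "new")
  expect_true(is.na(got$pct_change[got$site_id == "2"]))
  expect_error(compare_profiles(c(`1` = 10), c(`2` = 10), 2),
               "mutated_site")
})

test_that("swapping wild type and mutant flips the sign of the change", {
  set.seed(73)
  for (rep in 1:10) {
    wt <- stats::setNames(runif(4, 5, 50), 1:4)
    mut <- stats::setNames(runif(4, 5, 50), 1:4)
    ab <- compare_profiles(wt, mut, 2)
    ba <- compare_profiles(mut, wt, 2)
    expect_equal(sign(ab$pct_change), -sign(ba$pct_change))
    # magnitudes correspond through the change of percent base
    expect_equal(ba$pct_change, 100 * (wt - mut)[ab$site_id] / mut[ab$site_id],
                 ignore_attr = TRUE)
  }
})

test_that("exclusion lists parse indices, comments and blank lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# p1 tunnel entrance", "140", "141", "", "38 # hinge"), path)
  expect_equal(read_exclusion_list(path), c(38L, 140L, 141L))
  writeLines(c("abc"), path)
  expect_error(read_exclusion_list(path), "non-integer")
})
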