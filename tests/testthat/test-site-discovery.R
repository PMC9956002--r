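cm_from_supports <- function(supports, n_frames = 100, dt_ps = 2,
                             substrate = "s1", replica = "r1") {
  entries <- dplyr::bind_rows(lapply(seq_along(supports), function(r) {
    if (length(supports[[r]]) == 0) return(NULL)
    tibble::tibble(residue = r, frame = supports[[r]])
  }))
  contact_matrix(entries, n_residues = length(supports), n_frames = n_frames,
                 dt_ps = dt_ps, substrate = substrate, replica = replica)
}

test_that("co-supported residues form one local cluster, singletons drop", {
  sup <- list(c(0, 5, 9), c(0, 5, 9), c(0, 5, 9), c(20, 21), c(40, 41))
  lc <- local_cluster(cm_from_supports(sup))
  expect_equal(nrow(lc), 1)
  expect_equal(lc$residues[[1]], 1:3)
  # per-residue time: 3 frames x 2 ps; cluster time is the union, identical
  expect_equal(unname(lc$per_residue_time_ns[[1]]), rep(0.006, 3))
  expect_equal(lc$cluster_time_ns, 0.006)
})

test_that("identical supports collapse into a single all-residue cluster", {
  sup <- rep(list(c(1, 2, 3, 7)), 5)
  lc <- local_cluster(cm_from_supports(sup))
  expect_equal(nrow(lc), 1)
  expect_equal(lc$residues[[1]], 1:5)
})

test_that("two tight groups with disjoint supports give two clusters", {
  sup <- c(rep(list(c(0, 1, 2)), 3), rep(list(c(50, 51, 52)), 3))
  lc <- local_cluster(cm_from_supports(sup))
  expect_equal(nrow(lc), 2)
  expect_equal(lc$residues, list(1:3, 4:6))
})

test_that("local clustering partitions contacting residues", {
  set.seed(53)
  for (rep in 1:10) {
    sup <- random_supports(12, universe = 40, min_size = 1, max_size = 15)
    lc <- local_cluster(cm_from_supports(sup), min_cluster_size = 1)
    all_members <- unlist(lc$residues)
    expect_false(any(duplicated(all_members)))
    expect_setequal(all_members, 1:12)
  }
})

test_that("cluster time lies between max per-residue time and their sum", {
  set.seed(59)
  for (rep in 1:10) {
    sup <- random_supports(6, universe = 50, min_size = 3, max_size = 20)
    lc <- local_cluster(cm_from_supports(sup), min_cluster_size = 1)
    for (i in seq_len(nrow(lc))) {
      prt <- lc$per_residue_time_ns[[i]]
      expect_gte(lc$cluster_time_ns[i], max(prt) - 1e-12)
      expect_lte(lc$cluster_time_ns[i], sum(prt) + 1e-12)
    }
  }
})

test_that("empty matrices cluster to an empty result, not an error", {
  m <- contact_matrix(tibble::tibble(residue = integer(), frame = integer()),
                      n_residues = 5, n_frames = 10)
  expect_equal(nrow(local_cluster(m)), 0)
})

test_that("identical local clusters from ten replicas merge into one site", {
  locals <- dplyr::bind_rows(lapply(1:10, function(i) {
    lc <- local_cluster(cm_from_supports(rep(list(c(0, 1, 2)), 3),
                                         replica = sprintf("r%d", i)))
    lc
  }))
  sites <- global_cluster(locals)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$residues[[1]], 1:3)
  expect_equal(sites$n_residues, 3L)
  expect_equal(length(sites$members[[1]]$replica), 10)
})

test_that("a singleton local cluster becomes its own site with its time", {
  lc <- local_cluster(cm_from_supports(rep(list(c(0, 1, 2, 3)), 3)))
  sites <- global_cluster(lc)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$time_table[[1]][["s1"]], lc$cluster_time_ns[1])
})

test_that("disjoint local-cluster families give separate sites", {
  a <- local_cluster(cm_from_supports(c(rep(list(c(0, 1, 2)), 3),
                                        rep(list(c(50, 51, 52)), 3)),
                                      replica = "r1"))
  b <- local_cluster(cm_from_supports(c(rep(list(c(0, 1, 2)), 3),
                                        rep(list(c(50, 51, 52)), 3)),
                                      replica = "r2"))
  sites <- global_cluster(dplyr::bind_rows(a, b))
  expect_equal(nrow(sites), 2)
  # the oracle agrees on the stage-2 grouping
  D <- tbsmap:::jaccard_dist_matrix(dplyr::bind_rows(a, b)$residues)
  expect_equal(canonical_partition(agglomerate(D, 0.65)),
               canonical_partition(naive_agglomerate(D, 0.65)))
})

test_that("median site times sit inside the member time range", {
  set.seed(61)
  for (rep in 1:10) {
    locals <- dplyr::bind_rows(lapply(1:6, function(i) {
      sup <- lapply(1:4, function(r) sort(sample(0:99, sample(5:30, 1))))
      local_cluster(cm_from_supports(sup, replica = sprintf("r%d", i)),
                    min_cluster_size = 1)
    }))
    sites <- global_cluster(locals, aggregator = "median",
                            min_cluster_size = 1)
    expect_gte(nrow(sites), 1)
    for (i in seq_len(nrow(sites))) {
      mem_t <- sites$members[[i]]$cluster_time_ns
      expect_gte(sites$time_table[[i]][["s1"]], min(mem_t))
      expect_lte(sites$time_table[[i]][["s1"]], max(mem_t))
    }
  }
})

test_that("sites merge across substrates with per-substrate time entries", {
  mk <- function(substrate, support, time_frames) {
    lc <- local_cluster(cm_from_supports(rep(list(time_frames), 3),
                                         substrate = substrate))
    global_cluster(lc)
  }
  s1 <- mk("s1", c(0, 1, 2), 0:9)        # 10 frames -> 0.02 ns
  s2 <- mk("s2", c(0, 1, 2), 0:19)       # 20 frames -> 0.04 ns
  merged <- merge_sites_across_substrates(list(s1, s2))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_residues, lengths(merged$residues))
  expect_equal(sort(names(merged$time_table[[1]])), c("s1", "s2"))
  expect_equal(merged$time_table[[1]][["s1"]], 0.02)
  expect_equal(merged$time_table[[1]][["s2"]], 0.04)

  # disjoint residue sets stay separate, one-entry tables each
  far <- global_cluster(local_cluster(
    cm_from_supports(c(rep(list(integer(0)), 10), rep(list(0:9), 3)),
                     substrate = "s3")))
  merged2 <- merge_sites_across_substrates(list(s1, far))
  expect_equal(nrow(merged2), 2)
  expect_equal(lengths(merged2$time_table), c(1L, 1L))
})

test_that("site ids order by descending total time with index tie-break", {
  a <- make_sites(list(c(1L, 2L, 3L)),
                  list(member_row("s1", "r1", 1:3, c(1, 1, 1), 5)))
  b <- make_sites(list(c(10L, 11L, 12L)),
                  list(member_row("s2", "r1", 10:12, c(1, 1, 1), 50)))
  merged <- merge_sites_across_substrates(list(a, b))
  expect_equal(merged$site_id, c(1L, 2L))
  expect_equal(merged$residues[[1]], 10:12) # larger total time first
})

test_that("the packaged site-time report round-trips byte-identically", {
  src <- system.file("extdata", "linb_site_times.tsv", package = "tbsmap")
  tt <- read_time_table(src)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_time_table(tt, out)
  expect_identical(readLines(out), readLines(src))
})

test_that("1x1 and absent-cell reports format as specified", {
  tt <- tibble::tibble(site_id = 1L, sub = 12.34)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_time_table(tt, out)
  expect_equal(readLines(out), c("site_id\tsub", "1\t12.3"))
  tt2 <- tibble::tibble(site_id = 1:2, a = c(1, NA), b = c(NA, 2))
  write_time_table(tt2, out)
  expect_equal(readLines(out)[2:3], c("1\t1.0\t-", "2\t-\t2.0"))
})

test_that("binding sites round-trip through the JSON dialect", {
  lc1 <- local_cluster(cm_from_supports(rep(list(c(0, 1, 2)), 3),
                                        substrate = "BCH", replica = "r1"))
  lc2 <- local_cluster(cm_from_supports(rep(list(c(0, 1, 2, 3)), 3),
                                        substrate = "BCH", replica = "r2"))
  sites <- global_cluster(dplyr::bind_rows(lc1, lc2))
  path <- withr::local_tempfile(fileext = ".json")
  write_sites_json(sites, path, config_hash = "abc")
  back <- read_sites_json(path)
  expect_equal(back$site_id, sites$site_id)
  expect_equal(back$residues, sites$residues)
  expect_equal(back$time_table, sites$time_table)
  expect_equal(back$members[[1]]$cluster_time_ns,
               sites$members[[1]]$cluster_time_ns)
})
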