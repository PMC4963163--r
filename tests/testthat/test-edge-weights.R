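spec4 <- parcellation_spec(
  voxel_volume_mm3 = 1, seeds_per_voxel = 125,
  surface_areas_mm2 = c(roi1 = 100, roi2 = 100, roi3 = 80, roi4 = 120))

streams_df <- function(node_a, node_b, length_mm, seed_in_node = FALSE) {
  n <- max(length(node_a), length(node_b), length(length_mm))
  data.frame(stream_id = sprintf("s%03d", seq_len(n)),
             seed_voxel = seq_len(n), length_mm = length_mm,
             node_a = node_a, node_b = node_b,
             seed_in_node = seed_in_node, stringsAsFactors = FALSE)
}

test_that("characteristic filter selects the pair's streamlines", {
  st <- streams_df(c("roi1", "roi1", "roi2"), c("roi2", "roi3", "roi1"),
                   c(2, 3, 4))
  r <- characteristic_filter(st, "roi1", "roi2")
  expect_equal(nrow(r), 2)                 # both orientations retained
  expect_setequal(r$stream_id, c("s001", "s003"))
  expect_error(characteristic_filter(st, "roi1", "roi1"), "self-edges")

  # seed-in-node exclusion honors the flag
  st$seed_in_node <- c(TRUE, FALSE, FALSE)
  expect_equal(nrow(characteristic_filter(st, "roi1", "roi2",
                                          exclude_seed_in_node = TRUE)), 1)
  expect_equal(nrow(characteristic_filter(st, "roi1", "roi2",
                                          exclude_seed_in_node = FALSE)), 2)

  # null endpoints are skipped with a message
  st$node_b[2] <- NA
  expect_message(r <- characteristic_filter(st, "roi1", "roi2", FALSE),
                 "missing endpoint")
  expect_equal(nrow(r), 2)
})

test_that("characteristic filter equals a brute-force scan on random tables", {
  set.seed(9)
  labs <- paste0("roi", 1:5)
  for (rep in 1:10) {
    ends <- t(replicate(60, sample(labs, 2)))
    st <- streams_df(ends[, 1], ends[, 2], runif(60, 1, 30),
                     seed_in_node = runif(60) < 0.3)
    got <- characteristic_filter(st, "roi1", "roi2")
    want <- st[((st$node_a == "roi1" & st$node_b == "roi2") |
                (st$node_a == "roi2" & st$node_b == "roi1")) &
               !st$seed_in_node, ]
    expect_identical(got$stream_id, want$stream_id)
  }
})

test_that("edge weight matches the closed form", {
  sp <- parcellation_spec(1, 1, c(i = 1, j = 1))
  R1 <- streams_df("i", "j", 2)
  # w = (V/P) * 2/(A_i+A_j) * 1/l = 1 * (2/2) * (1/2)
  expect_equal(edge_weight(R1, sp, "i", "j"), 0.5)

  # 250 equal streamlines, the worked ceiling case
  R250 <- streams_df(rep("roi1", 250), rep("roi2", 250), rep(2, 250))
  expect_equal(edge_weight(R250, spec4, "roi1", "roi2"),
               (1 / 125) * (2 / 200) * (250 / 2))
  expect_equal(edge_weight(R250, spec4, "roi1", "roi2"), 0.01)

  expect_equal(edge_weight(R250[0, ], spec4, "roi1", "roi2"), 0)
  expect_error(edge_weight(R1, sp, "i", "missing"), "surface area")
  R_bad <- streams_df("i", "j", -1)
  expect_error(edge_weight(R_bad, sp, "i", "j"), "positive")
})

test_that("edge weight is dimensionless: invariant under uniform rescaling", {
  set.seed(4)
  R <- streams_df(rep("roi1", 40), rep("roi2", 40), runif(40, 1, 60))
  base <- edge_weight(R, spec4, "roi1", "roi2")
  for (s in c(0.5, 2, 10)) {
    sp_s <- parcellation_spec(
      spec4$voxel_volume_mm3 * s^3, spec4$seeds_per_voxel,
      spec4$surface_areas_mm2 * s^2)
    R_s <- R
    R_s$length_mm <- R$length_mm * s
    expect_equal(edge_weight(R_s, sp_s, "roi1", "roi2"), base,
                 tolerance = 1e-12)
  }
})

test_that("edge weight is additive over disjoint streamline sets", {
  set.seed(5)
  R <- streams_df(rep("roi1", 30), rep("roi2", 30), runif(30, 2, 40))
  split_at <- 12
  w_all <- edge_weight(R, spec4, "roi1", "roi2")
  w_a <- edge_weight(R[1:split_at, ], spec4, "roi1", "roi2")
  w_b <- edge_weight(R[(split_at + 1):30, ], spec4, "roi1", "roi2")
  expect_equal(w_all, w_a + w_b)
})

test_that("build_connectome reproduces per-pair filter + weight calls", {
  set.seed(6)
  labs <- paste0("roi", 1:4)
  ends <- t(replicate(120, sample(labs, 2)))
  st <- streams_df(ends[, 1], ends[, 2], runif(120, 1, 50),
                   seed_in_node = runif(120) < 0.2)
  cn <- build_connectome(st, spec4, labs)
  expect_length(validate_connectome(cn), 0)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      R <- characteristic_filter(st, labs[i], labs[j])
      expect_equal(unname(cn$counts[i, j]), nrow(R))
      expect_equal(unname(cn$weights[i, j]),
                   unname(edge_weight(R, spec4, labs[i], labs[j])))
    }
  }

  # empty table -> edgeless connectome; unknown labels rejected
  empty <- st[0, ]
  expect_equal(edge_count(build_connectome(empty, spec4, labs)), 0)
  st_bad <- streams_df("roiX", "roi1", 5)
  expect_error(build_connectome(st_bad, spec4, labs), "unknown node label")
})

test_that("streamline count ceiling follows M x P", {
  expect_identical(max_possible_streamlines(2, spec4), 250L)
  sp1 <- parcellation_spec(1, 1, c(a = 1))
  expect_identical(max_possible_streamlines(1, sp1), 1L)
  # a threshold of 25 retains edges with >= 10% of the ceiling
  expect_equal(25 / max_possible_streamlines(2, spec4), 0.10)
  expect_error(max_possible_streamlines(0, spec4), "positive integer")
})

test_that("streamline and parcellation files round trip", {
  st <- streams_df(c("roi1", "roi2", NA), c("roi2", "roi3", "roi1"),
                   c(2, 3, 4))
  sp_path <- withr::local_tempfile(fileext = ".txt")
  st_path <- withr::local_tempfile(fileext = ".tsv")
  write_streamlines(st, st_path)
  back <- read_streamlines(st_path)
  expect_equal(back$node_a, st$node_a)
  expect_equal(back$length_mm, st$length_mm)
  write_parcellation(spec4, sp_path)
  sp_back <- read_parcellation(sp_path)
  expect_equal(sp_back$voxel_volume_mm3, spec4$voxel_volume_mm3)
  expect_identical(sp_back$seeds_per_voxel, spec4$seeds_per_voxel)
  expect_equal(sp_back$surface_areas_mm2, spec4$surface_areas_mm2)
})
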