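test_that("session z-scoring centres and scales each session independently", {
  tb <- trial_betas(matrix(c(1, 2, 3), 3, 1), rep("i1", 3), rep("s1", 3),
                    "p1", "V1")
  # sample-sd convention: (1,2,3) -> (-1, 0, 1)
  expect_equal(zscore_per_session(tb, "sample")$betas,
               matrix(c(-1, 0, 1), 3, 1))
  # population-sd convention: sd = sqrt(2/3)
  expect_equal(zscore_per_session(tb, "population")$betas,
               matrix(c(-1, 0, 1) / sqrt(2 / 3), 3, 1))

  # two sessions with different offsets are centred independently
  tb2 <- trial_betas(matrix(c(1, 2, 3, 101, 102, 103), 6, 1),
                     rep(c("i1", "i2", "i3"), 2),
                     rep(c("s1", "s2"), each = 3), "p1", "V1")
  z2 <- zscore_per_session(tb2, "sample")
  expect_equal(z2$betas[, 1], c(-1, 0, 1, -1, 0, 1))

  # idempotence: z-scoring twice is the identity
  z_again <- zscore_per_session(z2, "sample")
  expect_equal(z_again$betas, z2$betas, tolerance = 1e-12)

  # zero-variance slice names voxel and session
  tb3 <- trial_betas(matrix(c(5, 5, 5, 1, 2, 3), 3, 2), paste0("i", 1:3),
                     rep("sA", 3), "p1", "V1")
  expect_error(zscore_per_session(tb3), "voxel 1.*sA")
})

test_that("repeat averaging is a per-image mean in first-appearance order", {
  tb <- trial_betas(matrix(c(0, 1, 2), 3, 1), rep("i1", 3), rep("s", 3),
                    "p", "A")
  expect_equal(average_repeats(tb)$responses, matrix(1, 1, 1))

  # identical repeats reproduce the repeat
  tb2 <- trial_betas(matrix(rep(c(3, 7), 3), 6, 1, byrow = TRUE),
                     rep(c("a", "b"), 3), rep("s", 6), "p", "A")
  rs2 <- average_repeats(tb2)
  expect_equal(rs2$responses, matrix(c(3, 7), 2, 1))
  expect_equal(rs2$image_ids, c("a", "b"))

  # unequal repeat counts: per-image means, no cross-image weighting
  tb3 <- trial_betas(matrix(c(10, 1, 3), 3, 1), c("a", "b", "b"),
                     rep("s", 3), "p", "A")
  expect_equal(average_repeats(tb3)$responses, matrix(c(10, 2), 2, 1))

  # invariance to trial permutation
  set.seed(1)
  perm <- sample(6)
  tb_perm <- trial_betas(tb2$betas[perm, , drop = FALSE],
                         tb2$image_id[perm], tb2$session_id[perm], "p", "A")
  rs_perm <- average_repeats(tb_perm)
  expect_equal(rs_perm$responses[match(rs2$image_ids, rs_perm$image_ids), ,
                                 drop = FALSE],
               rs2$responses)
})

test_that("univariate profile is the voxel mean and commutes with voxel permutation", {
  rs <- make_rs(matrix(c(1, 2, 3, 4), 2, 2), c("a", "b"))
  expect_equal(univariate_profile(rs)$value, c(2, 3))

  # single voxel: profile equals that column
  rs1 <- make_rs(matrix(c(5, -1), 2, 1), c("a", "b"))
  expect_equal(univariate_profile(rs1)$value, c(5, -1))

  # all-zero matrix
  expect_equal(univariate_profile(make_rs(matrix(0, 3, 4)))$value, rep(0, 3))

  # voxel permutation invariance
  set.seed(2)
  m <- matrix(rnorm(40), 5, 8)
  perm <- sample(8)
  expect_equal(univariate_profile(make_rs(m))$value,
               univariate_profile(make_rs(m[, perm]))$value)
})

test_that("NCSNR voxel filter keeps strictly-above-threshold voxels", {
  rs <- make_rs(matrix(1:4, 2, 2), c("a", "b"), ncsnr = c(0.4, 0.6))
  kept <- filter_voxels_by_ncsnr(rs, 0.5)
  expect_equal(ncol(kept$responses), 1)
  expect_equal(kept$voxel_meta$ncsnr, 0.6)

  # threshold below every value keeps everything (identity up to metadata)
  all_kept <- filter_voxels_by_ncsnr(rs, -1)
  expect_equal(all_kept$responses, rs$responses)

  # empty survivor set advises a lower threshold
  rs2 <- make_rs(matrix(1:4, 2, 2), c("a", "b"), ncsnr = c(0.3, 0.3))
  expect_error(filter_voxels_by_ncsnr(rs2, 0.5), "lower")

  # ties are excluded (strict inequality)
  rs3 <- make_rs(matrix(1:4, 2, 2), c("a", "b"), ncsnr = c(0.5, 0.6))
  expect_equal(ncol(filter_voxels_by_ncsnr(rs3, 0.5)$responses), 1)
})

test_that("store write-then-read round-trips both container types", {
  path <- withr::local_tempdir()
  set.seed(3)
  rs <- make_rs(matrix(rnorm(12), 3, 4), paste0("im", 1:3),
                ncsnr = c(0.1, 0.7, 2.3, Inf))
  rs$voxel_meta$visual_field <- c("lower", "upper", "none", "none")
  write_response_store(rs, path)
  back <- read_response_store(path, "p1", "A")
  expect_equal(back$responses, rs$responses, tolerance = 1e-12)
  expect_identical(back$image_ids, rs$image_ids)
  expect_equal(back$voxel_meta, rs$voxel_meta)

  tb <- trial_betas(matrix(rnorm(6), 3, 2), c("x", "x", "y"),
                    c("s1", "s1", "s2"), "p2", "B")
  write_response_store(tb, path)
  tback <- read_response_store(path, "p2", "B")
  expect_equal(tback$betas, tb$betas, tolerance = 1e-12)
  expect_identical(tback$image_id, tb$image_id)
  expect_identical(tback$session_id, tb$session_id)
})

test_that("store addresses per-(participant, area) groups and rejects schema mismatch", {
  path <- withr::local_tempdir()
  objs <- list()
  for (p in paste0("sub", 1:8)) for (a in c("V1", "V2", "V3", "V4")) {
    objs[[length(objs) + 1L]] <-
      make_rs(matrix(seq_len(4), 2, 2), c("i1", "i2"), participant = p,
              area = a)
  }
  write_response_store(objs, path)
  groups <- response_store_groups(path)
  expect_equal(nrow(groups), 32)
  expect_setequal(unique(groups$participant), paste0("sub", 1:8))
  one <- read_response_store(path, "sub5", "V3")
  expect_equal(one$participant, "sub5")
  expect_equal(one$area, "V3")
  expect_error(read_response_store(path, "sub9", "V1"), "no group")

  man <- jsonlite::read_json(file.path(path, "manifest.json"))
  man$schema_version <- "rnc-store/99"
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(read_response_store(path, "sub1", "V1"), "schema mismatch")
})

test_that("an empty-image-set store is explicit and readable", {
  path <- withr::local_tempdir()
  rs <- make_rs(matrix(numeric(0), 0, 2), character(0))
  write_response_store(rs, path)
  back <- read_response_store(path, "p1", "A")
  expect_equal(nrow(back$responses), 0)
  expect_equal(ncol(back$responses), 2)
})
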