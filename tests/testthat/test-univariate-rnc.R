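test_that("univariate null distribution and baseline behave as specified", {
  # constant profile: every batch scores c and the baseline scores c
  pc <- make_profile(rep(1.5, 40))
  null_c <- build_univariate_null(pc, 10, 500, seed = 31)
  expect_true(all(null_c$sample_scores == 1.5))
  expect_equal(null_c$baseline_score, 1.5)

  # a single sample is its own baseline
  p <- make_profile(c(3, 1, 4, 1, 5, 9, 2, 6))
  null_1 <- build_univariate_null(p, 3, 1, seed = 32)
  expect_equal(null_1$baseline_score, null_1$sample_scores[1])
  expect_equal(length(null_1$baseline_image_ids), 3)

  # skewed profile, batch size 1: baseline is one of the zeros
  pz <- make_profile(c(rep(0, 49), 10))
  null_z <- build_univariate_null(pz, 1, 5000, seed = 33)
  expect_equal(pz$value[match(null_z$baseline_image_ids, pz$image_id)], 0)

  # reproducible bit-exactly under a fixed seed
  null_a <- build_univariate_null(p, 3, 2000, seed = 34)
  null_b <- build_univariate_null(p, 3, 2000, seed = 34)
  expect_identical(null_a$sample_scores, null_b$sample_scores)
  expect_identical(null_a$baseline_image_ids, null_b$baseline_image_ids)

  expect_error(build_univariate_null(p, 99, 10), "batch_size")
})

test_that("margin-constrained selection matches the hand-worked example", {
  a <- make_profile(c(0, 1, 2, -1, 0.5))
  b <- make_profile(c(0, -1, 2, 1, 0.5), area = "B")
  pick1 <- function(cond) {
    select_univariate_controls(a, b, 0.3, 0.3, cond, margin = 0.04,
                               n_select = 1)$image_id
  }
  expect_equal(pick1("drive_both"), "img3")
  expect_equal(pick1("drive_A_suppress_B"), "img2")
  expect_equal(pick1("suppress_both"), "img1")

  # equal profiles cannot be disentangled around equal baselines
  same <- select_univariate_controls(a, a, 0.3, 0.3, "drive_A_suppress_B")
  expect_equal(nrow(same), 0)
  expect_false(attr(same, "complete"))

  # margin 0, n_select = all: every image above both baselines, by sum
  big_a <- make_profile(c(5, 3, 4, 2))
  big_b <- make_profile(c(1, 2, 3, 4), area = "B")
  all_sel <- select_univariate_controls(big_a, big_b, 0, 0, "drive_both",
                                        margin = 0, n_select = 4)
  expect_equal(all_sel$image_id,
               oracle_select(big_a$value, big_b$value, 0, 0, "drive_both",
                             0, 4, big_a$image_id))
})

test_that("selection equals the brute-force oracle on random instances", {
  set.seed(35)
  for (rep in 1:10) {
    n <- 200
    va <- rnorm(n); vb <- rnorm(n)
    ids <- paste0("im", sample(1000, n))
    pa <- make_profile(va, ids); pb <- make_profile(vb, ids, area = "B")
    ba <- rnorm(1, 0, 0.2); bb <- rnorm(1, 0, 0.2)
    for (cond in c("drive_both", "suppress_both", "drive_A_suppress_B",
                   "drive_B_suppress_A")) {
      got <- select_univariate_controls(pa, pb, ba, bb, cond)$image_id
      want <- oracle_select(va, vb, ba, bb, cond, 0.04, 25, ids)
      expect_identical(got, want)
    }
  }
})

test_that("disentangling is symmetric under swapping the two areas", {
  set.seed(36)
  pa <- make_profile(rnorm(100)); pb <- make_profile(rnorm(100), area = "B")
  ab <- select_univariate_controls(pa, pb, 0.1, -0.1, "drive_A_suppress_B")
  ba <- select_univariate_controls(pb, pa, -0.1, 0.1, "drive_B_suppress_A")
  expect_identical(ab$image_id, ba$image_id)
})

test_that("leave-one-out cross-validation yields one solution per participant", {
  set.seed(37)
  vals <- rnorm(60)
  profs_a <- lapply(1:8, function(i) make_profile(vals, participant = i))
  profs_b <- lapply(1:8, function(i) make_profile(vals + rnorm(60, 0, 1e-9),
                                                  participant = i,
                                                  area = "B"))
  names(profs_a) <- names(profs_b) <- paste0("sub", 1:8)
  cv <- crossval_univariate(profs_a, profs_b, "drive_both",
                            batch_size = 5, n_samples = 200, seed = 38)
  expect_length(cv$folds, 8)
  # identical participants select identical image sets across folds
  sets <- unique(lapply(cv$folds, function(s) s$image_id))
  expect_length(sets, 1)
  expect_error(crossval_univariate(profs_a[1], profs_b[1], "drive_both"),
               "2")
})

test_that("cross-validated disentanglement beats baseline on the synthetic hierarchy", {
  cfg <- synthetic_cortex_config(n_participants = 8, n_images = 1000,
                                 voxels_per_area = 40, noise_sd = 0.3,
                                 seed = 39)
  sim <- simulate_hierarchy(cfg)
  profs_a <- lapply(sim$responses, function(p) univariate_profile(p$V1))
  profs_b <- lapply(sim$responses, function(p) univariate_profile(p$V4))
  cv <- crossval_univariate(profs_a, profs_b, "drive_A_suppress_B",
                            n_samples = 2000, seed = 40)
  ev <- cv$eval
  ok_a <- ev$control_mean[ev$area == "A"] > ev$baseline_mean[ev$area == "A"]
  ok_b <- ev$control_mean[ev$area == "B"] < ev$baseline_mean[ev$area == "B"]
  expect_gte(sum(ok_a & ok_b), 7)
})

test_that("profile correlation handles hand cases and degenerate input", {
  p1 <- make_profile(c(1, 2, 3))
  expect_equal(profile_correlation(p1, p1), 1)
  expect_equal(profile_correlation(p1, make_profile(-c(1, 2, 3))), -1)
  expect_equal(profile_correlation(p1, make_profile(c(1, 2, 4))),
               0.9819805, tolerance = 1e-6)
  expect_warning(r <- profile_correlation(p1, make_profile(c(2, 2, 2))),
                 "zero-variance")
  expect_true(is.nan(r))
  expect_error(profile_correlation(p1, make_profile(c(1, 2), c("x", "y"))),
               "3 images")
})

test_that("pair-group aggregation reproduces the chain and group layouts", {
  chain <- pair_grouping_stepwise(c("V1", "V2", "V3", "V4"))
  expect_equal(unname(table(chain$group)[c("1", "2", "3")]),
               c(3L, 2L, 1L), ignore_attr = TRUE)

  stats <- tibble::tibble(area_x = chain$area_x, area_y = chain$area_y,
                          stat = 2.5)
  agg <- aggregate_by_pair_group(stats, chain)
  expect_true(all(agg$mean_stat == 2.5))
  expect_equal(agg$n_pairs[order(agg$group)], c(3L, 2L, 1L))

  wb <- pair_grouping_within_between(c(EBA = "animate", FFA = "animate",
                                       PPA = "scene", RSC = "scene"))
  within <- wb[wb$group == "within", ]
  expect_setequal(paste(within$area_x, within$area_y),
                  c("EBA FFA", "PPA RSC"))
  expect_equal(sum(wb$group == "between"), 4)

  bad <- tibble::tibble(area_x = "V1", area_y = "LOC", stat = 1)
  expect_error(aggregate_by_pair_group(bad, chain), "unmapped")
})

test_that("subset contrast computes block means over image-by-voxel partitions", {
  rs <- make_rs(matrix(c(1, 2, 3, 4), 2, 2), c("a", "b"))
  # single all-covering block: overall mean
  one <- subset_contrast(rs, c("all", "all"), c("all", "all"))
  expect_equal(one$mean_response, 2.5)

  # 2x2 toy: four scalar cells
  cells <- subset_contrast(rs, c("sky", "nosky"), c("lower", "upper"))
  expect_equal(
    cells$mean_response[cells$image_subset == "sky" &
                          cells$voxel_subset == "lower"], 1)
  expect_equal(
    cells$mean_response[cells$image_subset == "nosky" &
                          cells$voxel_subset == "upper"], 4)

  # permuting voxels within a label leaves cells unchanged
  rs2 <- make_rs(matrix(c(1, 2, 5, 6, 3, 4), 2, 3), c("a", "b"))
  lab <- c("lower", "upper", "lower")
  c1 <- subset_contrast(rs2, c("s", "s"), lab)
  perm <- c(3, 2, 1)
  rs3 <- make_rs(rs2$responses[, perm], c("a", "b"))
  c2 <- subset_contrast(rs3, c("s", "s"), lab[perm])
  expect_equal(dplyr::arrange(c1, voxel_subset),
               dplyr::arrange(c2, voxel_subset))

  # label lengths must match the container
  expect_error(subset_contrast(rs, c("a", "b", "c"), c("l", "u")))
})
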