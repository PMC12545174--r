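test_that("hierarchy simulator plants the configured shared-content structure", {
  # no decay, no noise: all areas carry identical profiles
  cfg0 <- synthetic_cortex_config(n_participants = 2, n_images = 300,
                                  voxels_per_area = 20, share_decay = 0,
                                  noise_sd = 0, seed = 21)
  sim0 <- simulate_hierarchy(cfg0)
  p1 <- univariate_profile(sim0$responses$sub1$V1)
  p4 <- univariate_profile(sim0$responses$sub1$V4)
  expect_equal(profile_correlation(p1, p4), 1, tolerance = 1e-9)

  # full decay: independent pools, |r| small at 2,000 images (a rich
  # latent space keeps the chance alignment of two random pools low)
  cfg1 <- synthetic_cortex_config(n_participants = 1, n_images = 2000,
                                  voxels_per_area = 10, latent_dim = 2000,
                                  share_decay = 1, noise_sd = 0, seed = 22)
  sim1 <- simulate_hierarchy(cfg1)
  r <- profile_correlation(univariate_profile(sim1$responses$sub1$V1),
                           univariate_profile(sim1$responses$sub1$V4))
  expect_lt(abs(r), 0.1)

  # pure function of (config, seed)
  sim0b <- simulate_hierarchy(cfg0)
  expect_identical(sim0$responses$sub2$V3$responses,
                   sim0b$responses$sub2$V3$responses)

  # planted correlation matrix is non-increasing in hierarchy distance
  gt <- sim0$ground_truth
  expect_equal(dim(gt$planted_cor), c(4, 4))
  cfg2 <- synthetic_cortex_config(share_decay = 0.3, seed = 1)
  d <- abs(outer(cfg2$areas$position, cfg2$areas$position, "-"))
  expect_equal(simulate_hierarchy(
    synthetic_cortex_config(n_participants = 1, n_images = 10,
                            voxels_per_area = 2, share_decay = 0.3,
                            seed = 1))$ground_truth$planted_cor,
    0.7^d)
})

test_that("measured cross-area profile correlation decreases with stepwise distance", {
  cfg <- synthetic_cortex_config(n_participants = 2, n_images = 2000,
                                 voxels_per_area = 50, seed = 23)
  sim <- simulate_hierarchy(cfg)
  areas <- cfg$areas$area
  profs <- lapply(areas, function(a) univariate_profile(sim$responses$sub1[[a]]))
  names(profs) <- areas
  pairs <- utils::combn(areas, 2)
  dist <- apply(pairs, 2, function(p) abs(match(p[2], areas) - match(p[1], areas)))
  pc <- apply(pairs, 2, function(p) profile_correlation(profs[[p[1]]],
                                                        profs[[p[2]]]))
  expect_lt(spearman(dist, pc), 0)
})

test_that("grouped variant: within-group RSA on random batches exceeds between-group", {
  cfg <- synthetic_cortex_config(n_participants = 2,
                                 areas = areas_grouped(), n_images = 600,
                                 voxels_per_area = 50, seed = 24)
  sim <- simulate_hierarchy(cfg)
  areas <- cfg$areas$area
  rs <- sim$responses$sub1
  set.seed(25)
  pairs <- utils::combn(areas, 2)
  stats <- purrr::map_dfr(1:5, function(b) {
    batch <- sample(rs[[1]]$image_ids, 50)
    tibble::tibble(
      area_x = pairs[1, ], area_y = pairs[2, ],
      stat = apply(pairs, 2, function(p) {
        rsa_score(compute_rsm(rs[[p[1]]], batch),
                  compute_rsm(rs[[p[2]]], batch))
      }))
  })
  agg <- aggregate_by_pair_group(
    stats, pair_grouping_within_between(
      stats::setNames(areas_grouped()$group, areas)))
  expect_gt(agg$mean_stat[agg$group == "within"],
            agg$mean_stat[agg$group == "between"])
})

test_that("trial simulator plants a recoverable NCSNR", {
  set.seed(26)
  rs <- make_rs(scale(matrix(rnorm(4000 * 5), 4000, 5)) *
                  sqrt(4000 / 3999), paste0("i", 1:4000))
  # noise_sd -> 0: identical repeats, NCSNR = +Inf
  tb0 <- simulate_trials(rs, repeats = 3, noise_sd = 0, seed = 27)
  expect_equal(suppressWarnings(compute_ncsnr(tb0))$ncsnr, rep(Inf, 5))

  # signal and noise variance equal after scaling: NCSNR ~ 1
  tb1 <- simulate_trials(rs, repeats = 3, noise_sd = 1, seed = 28)
  np <- compute_ncsnr(tb1)
  expect_true(all(abs(np$ncsnr - 1) < 0.1))
})

test_that("toy encoders respond to their planted features", {
  enc <- toy_models()
  u <- uniform_image()
  fr_u <- mean(predict_responses(enc$freq, u))
  bl_u <- mean(predict_responses(enc$blob, u))

  ch <- checkerboard_image()
  fr_ch <- mean(predict_responses(enc$freq, ch))
  bl_ch <- mean(predict_responses(enc$blob, ch))

  dk <- disks_image()
  fr_dk <- mean(predict_responses(enc$freq, dk))
  bl_dk <- mean(predict_responses(enc$blob, dk))

  # uniform mid-gray: both near their minimum (suppress-both analogue)
  expect_lt(fr_u, -1)
  expect_equal(bl_u, min(bl_u, bl_ch, bl_dk))
  # fine checkerboard: freq high, blob low
  expect_gt(fr_ch, 2)
  expect_equal(bl_ch, bl_u)  # no countable components
  # five disjoint disks: blob high, freq low
  expect_gt(bl_dk, bl_u + 0.3)
  expect_lt(fr_dk, 0)
  expect_gt(bl_dk, fr_dk)

  # determinism
  expect_identical(predict_responses(enc$freq, dk),
                   predict_responses(enc$freq, dk))
})

test_that("image batches are validated", {
  enc <- toy_models()
  expect_error(predict_responses(enc$blob, array(0.5, c(64, 64, 2))),
               "H x W x 3")
  expect_error(predict_responses(enc$blob, array(300L, c(64, 64, 3))),
               "0, 255")
  expect_error(predict_responses(enc$blob, array(0.25, c(64, 64, 3))),
               "0, 255")
})

test_that("toy generator is deterministic with a structured latent space", {
  gen <- toy_generator()
  z0 <- rep(0, 64)
  img0 <- generate_images(gen, z0)
  # zero latent: uniform background
  expect_equal(length(unique(as.vector(img0))), 1)

  set.seed(29)
  z <- rnorm(64)
  expect_identical(generate_images(gen, z), generate_images(gen, z))

  # sinusoid-only latent drives the freq encoder above background
  zs <- rep(0, 64)
  zs[33:36] <- c(2, 0, 0, 2)  # high frequency, high contrast
  imgs <- generate_images(gen, zs)
  enc <- toy_models()
  expect_gt(mean(predict_responses(enc$freq, imgs)),
            mean(predict_responses(enc$freq, img0)))

  # latent length mismatch
  expect_error(generate_images(gen, rep(0, 63)), "latent")
  expect_error(toy_generator(latent_dim = 4), "latent_dim")
})
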