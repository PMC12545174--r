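#' Configuration for the synthetic visual-cortex simulator
#'
#' The simulator emulates the structure the control analyses assume: several
#' participants viewing one shared image set, a chain of areas whose shared
#' representational content decays with hierarchy distance, optional
#' categorical area groups, per-voxel noise heterogeneity, and repeated
#' trials for noise-ceiling estimation.
#'
#' @param n_participants Number of simulated participants (default 8,
#'   matching a typical densely sampled fMRI cohort).
#' @param areas Tibble with columns `area`, `position` (integer hierarchy
#'   position) and optional `group`; see [areas_chain()] and
#'   [areas_grouped()].
#' @param voxels_per_area Voxels simulated per area.
#' @param n_images Number of images in the shared stimulus set.
#' @param latent_dim Dimensionality of the latent image features.
#' @param share_decay Fraction of representational content lost per
#'   hierarchy step, in `[0, 1]`: planted cross-area signal correlation is
#'   `(1 - share_decay)^distance`.
#' @param noise_sd Participant-specific voxel noise sd, z-units.
#' @param seed Integer seed; simulators are pure functions of (config, seed).
#' @return A list of class `rnc_cortex_config`.
#' @export
synthetic_cortex_config <- function(n_participants = 8,
                                    areas = areas_chain(),
                                    voxels_per_area = 100,
                                    n_images = 2000,
                                    latent_dim = 50,
                                    share_decay = 0.3,
                                    noise_sd = 0.2,
                                    seed = 1) {
  stopifnot(n_participants >= 1, voxels_per_area >= 1, n_images >= 1,
            latent_dim >= 1, share_decay >= 0, share_decay <= 1,
            noise_sd >= 0, all(c("area", "position") %in% names(areas)))
  if (!"group" %in% names(areas)) areas$group <- NA_character_
  structure(list(n_participants = as.integer(n_participants),
                 areas = tibble::as_tibble(areas),
                 voxels_per_area = as.integer(voxels_per_area),
                 n_images = as.integer(n_images),
                 latent_dim = as.integer(latent_dim),
                 share_decay = share_decay, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "rnc_cortex_config")
}

#' Stepwise area chain (early/mid visual hierarchy analogue)
#' @return Tibble with areas V1-V4 at positions 1-4, no groups.
#' @export
areas_chain <- function() {
  tibble::tibble(area = c("V1", "V2", "V3", "V4"), position = 1:4,
                 group = NA_character_)
}

#' Two categorical-selectivity groups (high-level areas analogue)
#'
#' Encodes two 2-area groups (animate: EBA/FFA-like; scene: PPA/RSC-like)
#' through hierarchy positions 1,2,4,5, so within-group pairs are one step
#' apart and between-group pairs two to four.
#' @return Tibble with columns `area`, `position`, `group`.
#' @export
areas_grouped <- function() {
  tibble::tibble(area = c("EBA", "FFA", "PPA", "RSC"),
                 position = c(1L, 2L, 4L, 5L),
                 group = c("animate", "animate", "scene", "scene"))
}

#' Simulate a multi-area, multi-participant response hierarchy
#'
#' Image latents are drawn once and shared across participants. Each area's
#' voxel tuning mixes a pool shared along the hierarchy chain with an
#' area-unique pool: tuning vectors follow an exponential-kernel process
#' across hierarchy positions with per-step correlation `1 - share_decay`,
#' so the planted cross-area signal correlation is
#' `(1 - share_decay)^|pos_i - pos_j|`. Participant-specific Gaussian voxel
#' noise of sd `noise_sd` is added and every voxel is z-scored across images.
#'
#' @param cfg A [synthetic_cortex_config()].
#' @return List with `responses` (nested named list,
#'   `responses[[participant]][[area]]`, each an [response_set()]) and
#'   `ground_truth` (planted cross-area correlation matrix, loadings,
#'   latents, config).
#' @export
simulate_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "rnc_cortex_config"))
  set.seed(cfg$seed)
  A <- nrow(cfg$areas)
  rho <- 1 - cfg$share_decay
  d <- abs(outer(cfg$areas$position, cfg$areas$position, "-"))
  planted <- rho^d
  Z <- matrix(stats::rnorm(cfg$n_images * cfg$latent_dim),
              cfg$n_images, cfg$latent_dim)
  # correlated loading stack across areas: rows iid with covariance `planted`
  G <- matrix(stats::rnorm(cfg$latent_dim * cfg$voxels_per_area * A),
              cfg$latent_dim * cfg$voxels_per_area, A)
  U_flat <- if (rho == 1) {
    G[, rep(1L, A), drop = FALSE]
  } else if (rho == 0) {
    G
  } else {
    G %*% chol(planted)
  }
  loadings <- lapply(seq_len(A), function(a) {
    matrix(U_flat[, a], cfg$latent_dim, cfg$voxels_per_area)
  })
  names(loadings) <- cfg$areas$area
  signal <- lapply(loadings, function(U) Z %*% U / sqrt(cfg$latent_dim))
  participants <- paste0("sub", seq_len(cfg$n_participants))
  image_ids <- paste0("img", seq_len(cfg$n_images))
  responses <- lapply(participants, function(p) {
    per_area <- lapply(seq_len(A), function(a) {
      resp <- signal[[a]]
      if (cfg$noise_sd > 0) {
        resp <- resp + cfg$noise_sd *
          matrix(stats::rnorm(length(resp)), nrow(resp), ncol(resp))
      }
      resp <- scale(resp) * sqrt(nrow(resp) / (nrow(resp) - 1))  # population sd 1
      response_set(resp, image_ids,
                   ncsnr = rep(NA_real_, cfg$voxels_per_area),
                   participant = p, area = cfg$areas$area[a])
    })
    names(per_area) <- cfg$areas$area
    per_area
  })
  names(responses) <- participants
  list(responses = responses,
       ground_truth = list(planted_cor = planted, loadings = loadings,
                           latents = Z, config = cfg))
}

#' Simulate repeated trials around an image-level response set
#'
#' Each image is replicated `repeats` times with additive Gaussian noise of
#' sd `noise_sd`, then z-scored across all trials of the (single) session.
#' Because the image-level responses carry unit variance, the planted NCSNR
#' is `1 / noise_sd`.
#'
#' @param rs An [response_set()] serving as the noiseless signal.
#' @param repeats Number of repeats per image (>= 2; default 3).
#' @param noise_sd Trial noise sd in z-units.
#' @param seed Integer seed.
#' @return z-scored [trial_betas()].
#' @export
simulate_trials <- function(rs, repeats = 3, noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(rs, "rnc_response_set"), repeats >= 2)
  set.seed(seed)
  n <- nrow(rs$responses)
  betas <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    rs$responses + noise_sd *
      matrix(stats::rnorm(length(rs$responses)), n, ncol(rs$responses))
  }))
  tb <- trial_betas(betas, rep(rs$image_ids, times = repeats),
                    rep("session1", n * repeats),
                    participant = rs$participant, area = rs$area)
  zscore_per_session(tb)
}

# ---- toy image-computable encoders ----------------------------------------

as_image_batch <- function(images) {
  if (is.list(images)) {
    images <- simplify2array(images)
    images <- aperm(images, c(4, 1, 2, 3))
  }
  if (length(dim(images)) == 3) {
    images <- array(images, c(1, dim(images)))
  }
  if (length(dim(images)) != 4 || dim(images)[4] != 3) {
    stop("images must be H x W x 3 arrays (or a batch of them).", call. = FALSE)
  }
  if (!is.numeric(images) || any(images < 0) || any(images > 255) ||
      any(images != floor(images))) {
    stop("images must hold integer values in [0, 255] (uint8 convention).",
         call. = FALSE)
  }
  images
}

grid_windows <- function(h, w, grid) {
  rows <- split(seq_len(h), cut(seq_len(h), grid, labels = FALSE))
  cols <- split(seq_len(w), cut(seq_len(w), grid, labels = FALSE))
  out <- list()
  for (i in seq_len(grid)) for (j in seq_len(grid)) {
    out[[length(out) + 1L]] <- list(rows = rows[[i]], cols = cols[[j]])
  }
  out
}

freq_raw_scores <- function(images, grid) {
  images <- as_image_batch(images)
  n <- dim(images)[1]; h <- dim(images)[2]; w <- dim(images)[3]
  wins <- grid_windows(h, w, grid)
  t(vapply(seq_len(n), function(k) {
    g <- (images[k, , , 1] + images[k, , , 2] + images[k, , , 3]) / (3 * 255)
    gx <- abs(g[-1, ] - g[-h, ]); gx <- rbind(gx, gx[h - 1, ])
    gy <- abs(g[, -1] - g[, -w]); gy <- cbind(gy, gy[, w - 1])
    gm <- gx + gy
    vapply(wins, function(win) mean(gm[win$rows, win$cols]), numeric(1))
  }, numeric(length(wins))))
}

blob_raw_scores <- function(images, grid, band = 0.12,
                            area_min = 20, area_max = 150) {
  images <- as_image_batch(images)
  n <- dim(images)[1]; h <- dim(images)[2]; w <- dim(images)[3]
  t(vapply(seq_len(n), function(k) {
    g <- (images[k, , , 1] + images[k, , , 2] + images[k, , , 3]) / (3 * 255)
    # band threshold around mid-gray: bright and dark compact shapes count
    lab <- EBImage::bwlabel(abs(g - 0.5) > band)
    counts <- numeric(grid * grid)
    nlab <- max(lab)
    if (nlab > 0) {
      areas <- tabulate(lab, nbins = nlab)
      idx <- which(lab > 0, arr.ind = TRUE)
      labs_at <- lab[idx]
      cent <- rowsum(idx, labs_at) / as.numeric(areas[sort(unique(labs_at))])
      lab_of_row <- sort(unique(labs_at))
      # border-touching components are clipped shapes, not countable blobs
      on_border <- idx[, 1] == 1 | idx[, 1] == h | idx[, 2] == 1 |
        idx[, 2] == w
      border_labs <- unique(labs_at[on_border])
      keep <- which(areas[lab_of_row] >= area_min &
                      areas[lab_of_row] <= area_max &
                      !(lab_of_row %in% border_labs))
      for (kk in keep) {
        wi <- min(grid, 1 + floor((cent[kk, 1] - 1) / (h / grid)))
        wj <- min(grid, 1 + floor((cent[kk, 2] - 1) / (w / grid)))
        cell <- (wi - 1) * grid + wj
        counts[cell] <- counts[cell] + 1
      }
    }
    counts
  }, numeric(grid * grid)))
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Toy image-computable encoding models
#'
#' Two deterministic pixel-level encoders, each with one voxel per cell of a
#' `grid` by `grid` subwindow lattice. The `"freq"` model responds to mean
#' absolute pixel-gradient magnitude in its subwindow (a spatial-frequency
#' energy analogue); the `"blob"` model responds to the count of connected
#' components with area inside configured bounds after grayscale
#' thresholding (an object-like-shape analogue). Raw scores are standardized
#' against a frozen 256-image reference set (toy-generator outputs under a
#' fixed internal seed), so outputs live in z-like units and "baseline plus
#' margin" semantics carry over.
#'
#' @param grid Subwindow lattice size; `grid^2` voxels per model.
#' @param image_size Side length of the (square) images the models accept.
#' @param participant Identifier stamped on both models.
#' @return Named list with elements `freq` and `blob`, both
#'   [encoding_model()]s taking pixel image batches.
#' @export
toy_image_encoders <- function(grid = 4, image_size = 64, participant = "toy") {
  gen <- toy_generator(latent_dim = 64, image_size = image_size)
  ref <- with_preserved_seed(20240607, {
    lat <- matrix(stats::rnorm(256 * gen$latent_dim), 256, gen$latent_dim)
    generate_images(gen, lat)
  })
  standardize <- function(raw, mu, sdv) sweep(sweep(raw, 2, mu), 2, sdv, "/")
  f_raw <- freq_raw_scores(ref, grid)
  f_mu <- colMeans(f_raw)
  f_sd <- pmax(apply(f_raw, 2, stats::sd), 1e-12)
  b_raw <- blob_raw_scores(ref, grid)
  b_mu <- colMeans(b_raw)
  b_sd <- pmax(apply(b_raw, 2, stats::sd), 1e-12)
  freq <- encoding_model(participant, "freq", grid^2,
    predict = function(model, stimuli) {
      standardize(freq_raw_scores(stimuli, model$grid), model$ref_mean,
                  model$ref_sd)
    }, grid = grid, ref_mean = f_mu, ref_sd = f_sd)
  blob <- encoding_model(participant, "blob", grid^2,
    predict = function(model, stimuli) {
      standardize(blob_raw_scores(stimuli, model$grid), model$ref_mean,
                  model$ref_sd)
    }, grid = grid, ref_mean = b_mu, ref_sd = b_sd)
  list(freq = freq, blob = blob)
}

# ---- toy parametric image generator ----------------------------------------

#' Toy parametric image generator
#'
#' A deterministic stand-in for a learned image generator: the first half of
#' the latent vector controls a grid of Gaussian blob intensities and sizes,
#' the second half the frequency, phase and contrast of an additive
#' sinusoidal grating. The zero latent maps to a uniform mid-gray image;
#' outputs are clamped to `[0, 255]`.
#'
#' @param latent_dim Latent dimensionality (>= 8; default 64).
#' @param image_size Output side length (images are square RGB; default 64).
#' @return An object of class `rnc_generator` with fields `latent_dim`,
#'   `image_size` and `generate`.
#' @export
toy_generator <- function(latent_dim = 64, image_size = 64) {
  stopifnot(latent_dim >= 8)
  nb <- latent_dim %/% 2
  gcells <- nb %/% 2
  ggrid <- max(1L, floor(sqrt(gcells)))
  h <- image_size
  centers <- (seq_len(ggrid) - 0.5) * h / ggrid
  xs <- matrix(seq_len(h), h, h)
  ys <- t(xs)
  generate_one <- function(z) {
    img <- matrix(128, h, h)
    ints <- z[seq_len(ggrid^2)]
    sizes <- z[gcells + seq_len(ggrid^2)]
    for (i in seq_len(ggrid)) for (j in seq_len(ggrid)) {
      k <- (i - 1) * ggrid + j
      amp <- 90 * tanh(ints[k])
      if (abs(amp) < 4) next
      r <- 2.5 + 1.5 * abs(tanh(sizes[k]))
      d2 <- (xs - centers[i])^2 + (ys - centers[j])^2
      img <- img + amp * exp(-d2 / (2 * r^2))
    }
    s <- z[(nb + 1):length(z)]
    fx <- 8 * abs(tanh(s[1]))
    fy <- 8 * abs(tanh(s[2]))
    contrast <- 60 * abs(tanh(s[4]))
    if (contrast >= 1e-8) {
      img <- img + contrast * sin(2 * pi * (fx * xs + fy * ys) / h)
    }
    round(pmin(pmax(img, 0), 255))
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 image_size = as.integer(image_size),
                 generate_one = generate_one),
            class = "rnc_generator")
}

#' Generate images from latent vectors
#'
#' @param generator An `rnc_generator` (e.g. [toy_generator()]).
#' @param latents Matrix, latents by `latent_dim` (a single vector is
#'   treated as one latent).
#' @return Array `[n, H, W, 3]` with integer values in `[0, 255]`.
#' @export
generate_images <- function(generator, latents) {
  stopifnot(inherits(generator, "rnc_generator"))
  if (is.vector(latents)) latents <- matrix(latents, 1)
  if (ncol(latents) != generator$latent_dim) {
    stop(sprintf("latent length %d does not match generator latent_dim %d.",
                 ncol(latents), generator$latent_dim), call. = FALSE)
  }
  h <- generator$image_size
  out <- array(0, c(nrow(latents), h, h, 3))
  for (k in seq_len(nrow(latents))) {
    img <- generator$generate_one(latents[k, ])
    out[k, , , 1] <- img; out[k, , , 2] <- img; out[k, , , 3] <- img
  }
  out
}
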