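#' PNG-compressed size of an image, as a complexity measure
#'
#' Losslessly encodes the image as PNG and returns the byte count — a cheap,
#' monotone proxy for image complexity used as the second-phase objective of
#' generative control (simpler image, smaller file).
#'
#' @param image `H x W x 3` array with integer values in `[0, 255]`.
#' @return Byte count of the encoding (deterministic for a fixed encoder).
#' @export
png_complexity <- function(image) {
  image <- as_image_batch(image)
  if (dim(image)[1] != 1) {
    stop("png_complexity takes a single image.", call. = FALSE)
  }
  arr <- array(image[1, , , ] / 255, dim(image)[2:4])
  length(png::writePNG(arr, target = raw(0)))
}

#' Two-phase global score of a candidate latent
#'
#' Until a candidate's responses satisfy both areas' thresholds, its score
#' is the condition-signed objective value (lower = better) plus a large
#' constant penalty; once both thresholds pass, the score is the PNG byte
#' count of its image. Because the penalty exceeds any file size, every
#' threshold-passing candidate ranks better than every failing one, and
#' among failing candidates the ordering follows the response objective.
#'
#' @param resp_a,resp_b Univariate responses (z-units), vectorized.
#' @param objective_value Condition-signed sum/difference score, lower =
#'   better (vectorized).
#' @param thresholds List with elements `a` and `b`, each
#'   `list(direction = "above"|"below", level = <z-units>)`; level is
#'   baseline plus/minus the threshold margin.
#' @param png_bytes PNG sizes of the candidates' images (vectorized; only
#'   consulted for passing candidates).
#' @param penalty Constant penalty (default 1e10).
#' @return Numeric vector of global scores, lower = better.
#' @export
global_score <- function(resp_a, resp_b, objective_value, thresholds,
                         png_bytes, penalty = 1e10) {
  pass <- threshold_pass(resp_a, resp_b, thresholds)
  ifelse(pass, png_bytes, objective_value + penalty)
}

threshold_pass <- function(resp_a, resp_b, thresholds) {
  chk <- function(x, th) {
    if (identical(th$direction, "above")) x > th$level else x < th$level
  }
  chk(resp_a, thresholds$a) & chk(resp_b, thresholds$b)
}

#' Selection probabilities from global scores
#'
#' Fitness is the negated score (lower score = better). Fitness values are
#' z-scored, scaled by `softmax_scale`, and passed through a softmax, so
#' better-scoring candidates receive higher selection probability. All-equal
#' scores yield the uniform distribution.
#'
#' @param scores Finite numeric vector, length >= 2.
#' @param softmax_scale Scaling applied after z-scoring (default 0.5).
#' @return Probability vector summing to 1.
#' @export
selection_probabilities <- function(scores, softmax_scale = 0.5) {
  stopifnot(length(scores) >= 2, all(is.finite(scores)))
  fitness <- -scores
  s <- sqrt(mean((fitness - mean(fitness))^2))   # population-sd z-scoring
  z <- if (s == 0) rep(0, length(fitness)) else (fitness - mean(fitness)) / s
  w <- exp(softmax_scale * z - max(softmax_scale * z))
  w / sum(w)
}

#' Configuration of generative latent evolution
#'
#' @param condition Univariate control condition (see
#'   [select_univariate_controls()]).
#' @param population Latents per generation (default 1000).
#' @param n_elite Latents kept untouched (default 250).
#' @param n_children New children per generation (default 750;
#'   `n_elite + n_children` must equal `population`).
#' @param parent_mix Component fractions contributed by the
#'   higher-/lower-probability parent (default `c(0.75, 0.25)`).
#' @param mutation_prob Per-component mutation probability (default 0.25).
#' @param mutation_sd Sd of the additive zero-centred Gaussian mutation
#'   (default 0.75).
#' @param softmax_scale See [selection_probabilities()] (default 0.5).
#' @param penalty Below-threshold penalty (default 1e10).
#' @param generations Number of generations (default 500).
#' @param threshold_margin Margin added to (or subtracted from) each area's
#'   baseline to form its response threshold (default 0.6 z-units).
#' @param png_level Note recording the PNG encoder/compression setting used
#'   for byte counts.
#' @param seed Integer seed.
#' @return List of class `rnc_gen_config`.
#' @export
generative_config <- function(condition, population = 1000, n_elite = 250,
                              n_children = 750, parent_mix = c(0.75, 0.25),
                              mutation_prob = 0.25, mutation_sd = 0.75,
                              softmax_scale = 0.5, penalty = 1e10,
                              generations = 500, threshold_margin = 0.6,
                              png_level = "png package default (libpng)",
                              seed = 1) {
  condition_spec(condition)  # validates the label
  if (n_elite + n_children != population) {
    stop("n_elite + n_children must equal population.", call. = FALSE)
  }
  stopifnot(abs(sum(parent_mix) - 1) < 1e-12, mutation_prob >= 0,
            mutation_prob <= 1, mutation_sd >= 0)
  structure(list(condition = condition, population = as.integer(population),
                 n_elite = as.integer(n_elite),
                 n_children = as.integer(n_children),
                 parent_mix = parent_mix, mutation_prob = mutation_prob,
                 mutation_sd = mutation_sd, softmax_scale = softmax_scale,
                 penalty = penalty, generations = as.integer(generations),
                 threshold_margin = threshold_margin, png_level = png_level,
                 seed = as.integer(seed)),
            class = "rnc_gen_config")
}

#' Breed the next generation of latent vectors
#'
#' The `n_elite` highest-probability latents are copied untouched. Each of
#' the `n_children` children takes its components elementwise from two
#' probability-sampled parents — `parent_mix[1]` of them from the
#' higher-probability parent — and every component is then mutated with
#' probability `mutation_prob` by adding a `Normal(0, mutation_sd^2)` draw.
#' Uses the current RNG stream; seed at the caller.
#'
#' @param latents Matrix, population by latent_dim.
#' @param probabilities Selection probabilities (length = population).
#' @param cfg A [generative_config()].
#' @return Matrix of the same shape.
#' @export
make_next_generation <- function(latents, probabilities, cfg) {
  stopifnot(nrow(latents) == cfg$population,
            length(probabilities) == cfg$population)
  ord <- order(probabilities, decreasing = TRUE)
  elite <- latents[ord[seq_len(cfg$n_elite)], , drop = FALSE]
  ld <- ncol(latents)
  children <- matrix(0, cfg$n_children, ld)
  for (k in seq_len(cfg$n_children)) {
    par <- sample.int(cfg$population, 2, replace = FALSE,
                      prob = probabilities)
    hi <- if (probabilities[par[1]] >= probabilities[par[2]]) par[1] else par[2]
    lo <- if (hi == par[1]) par[2] else par[1]
    from_hi <- stats::runif(ld) < cfg$parent_mix[1]
    child <- ifelse(from_hi, latents[hi, ], latents[lo, ])
    mut <- stats::runif(ld) < cfg$mutation_prob
    child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, cfg$mutation_sd)
    children[k, ] <- child
  }
  rbind(elite, children)
}

signed_objective <- function(resp_a, resp_b, condition) {
  cs <- condition_spec(condition)
  raw <- if (cs$score == "sum") resp_a + resp_b else resp_a - resp_b
  if (cs$decreasing) -raw else raw    # lower = better
}

condition_thresholds <- function(condition, base_a, base_b, margin) {
  cs <- condition_spec(condition)
  th <- function(dir, base) {
    if (dir > 0) list(direction = "above", level = base + margin)
    else list(direction = "below", level = base - margin)
  }
  list(a = th(cs$dir_a, base_a), b = th(cs$dir_b, base_b))
}

#' Baseline responses of two encoders over unoptimized generator output
#'
#' Samples standard-normal latents, generates their images, and builds a
#' random-batch null ([build_univariate_null()]) over each area's univariate
#' responses; the two baseline scores anchor the thresholds of
#' [evolve_controlling_image()].
#'
#' @param generator An `rnc_generator`.
#' @param model_a,model_b [encoding_model()]s for the two areas.
#' @param n_images Generator images sampled (default 300).
#' @param batch_size,n_samples Null parameters (defaults 25, 2000).
#' @param seed Integer seed.
#' @return Named numeric `c(a = , b = )` of baseline univariate responses.
#' @export
generator_baselines <- function(generator, model_a, model_b, n_images = 300,
                                batch_size = 25, n_samples = 2000, seed = 1) {
  set.seed(seed)
  lat <- matrix(stats::rnorm(n_images * generator$latent_dim), n_images,
                generator$latent_dim)
  imgs <- generate_images(generator, lat)
  ids <- paste0("gen", seq_len(n_images))
  base_of <- function(model, offset) {
    prof <- new_profile(tibble::tibble(
      image_id = ids, value = rowMeans(predict_responses(model, imgs))),
      "generator", model$area)
    build_univariate_null(prof, batch_size, n_samples,
                          seed = seed + offset)$baseline_score
  }
  c(a = base_of(model_a, 1L), b = base_of(model_b, 2L))
}

#' Evolve a controlling image by genetic latent optimization
#'
#' Initializes `population` standard-normal latents and iterates: generate
#' images, predict both areas' responses with the encoding models (averaged
#' across voxels, and across models when several are supplied per area),
#' compute the condition-signed objective, assign two-phase global scores
#' ([global_score()]), convert them to selection probabilities and breed the
#' next generation ([make_next_generation()]). The first phase pushes
#' responses toward both areas' thresholds (baseline plus/minus
#' `threshold_margin`); after the phase switch the optimization minimizes
#' PNG file size while elitism keeps the thresholds satisfied.
#'
#' @param generator An `rnc_generator`.
#' @param models_a,models_b One [encoding_model()] or a list of them per
#'   area; responses are averaged across voxels and models.
#' @param baselines Numeric `c(a = , b = )` baseline univariate responses.
#' @param cfg A [generative_config()].
#' @return Object of class `rnc_evolution`: per-generation `trace` tibble
#'   (`generation`, `resp_a`, `resp_b`, `png_bytes`, `score`, `passed`),
#'   `phase_switch` (first generation whose best latent passes both
#'   thresholds, or `NA`), `best_latent`, `best_image`.
#' @export
evolve_controlling_image <- function(generator, models_a, models_b,
                                     baselines, cfg) {
  stopifnot(inherits(generator, "rnc_generator"),
            inherits(cfg, "rnc_gen_config"))
  if (inherits(models_a, "rnc_encoding_model")) models_a <- list(models_a)
  if (inherits(models_b, "rnc_encoding_model")) models_b <- list(models_b)
  thresholds <- condition_thresholds(cfg$condition, baselines[["a"]],
                                     baselines[["b"]], cfg$threshold_margin)
  uni_response <- function(models, images) {
    rowMeans(vapply(models, function(m) {
      rowMeans(predict_responses(m, images))
    }, numeric(dim(images)[1])))
  }
  set.seed(cfg$seed)
  latents <- matrix(stats::rnorm(cfg$population * generator$latent_dim),
                    cfg$population, generator$latent_dim)
  trace <- vector("list", cfg$generations)
  phase_switch <- NA_integer_
  best_latent <- NULL; best_image <- NULL
  for (g in seq_len(cfg$generations)) {
    images <- generate_images(generator, latents)
    resp_a <- uni_response(models_a, images)
    resp_b <- uni_response(models_b, images)
    obj <- signed_objective(resp_a, resp_b, cfg$condition)
    pass <- threshold_pass(resp_a, resp_b, thresholds)
    png_bytes <- rep(NA_real_, cfg$population)
    for (i in which(pass)) {
      png_bytes[i] <- png_complexity(images[i, , , , drop = FALSE])
    }
    scores <- ifelse(pass, png_bytes, obj + cfg$penalty)
    best <- which.min(scores)
    if (is.na(phase_switch) && pass[best]) phase_switch <- g
    best_latent <- latents[best, ]
    best_image <- array(images[best, , , ], dim(images)[2:4])
    trace[[g]] <- tibble::tibble(
      generation = g, resp_a = resp_a[best], resp_b = resp_b[best],
      png_bytes = if (pass[best]) png_bytes[best] else
        png_complexity(images[best, , , , drop = FALSE]),
      score = scores[best], passed = pass[best])
    if (g == cfg$generations) break
    probs <- selection_probabilities(scores, cfg$softmax_scale)
    latents <- make_next_generation(latents, probs, cfg)
  }
  structure(list(condition = cfg$condition,
                 trace = dplyr::bind_rows(trace),
                 phase_switch = phase_switch,
                 thresholds = thresholds,
                 best_latent = best_latent, best_image = best_image,
                 config = cfg),
            class = "rnc_evolution")
}

#' @export
print.rnc_evolution <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<rnc_evolution> condition %s: phase switch at generation %s, final PNG %s bytes (responses %.2f / %.2f)\n",
              x$condition,
              ifelse(is.na(x$phase_switch), "none", x$phase_switch),
              format(last$png_bytes), last$resp_a, last$resp_b))
  invisible(x)
}

#' @export
tidy.rnc_evolution <- function(x, ...) x$trace

#' @export
glance.rnc_evolution <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(condition = x$condition, generations = nrow(x$trace),
                 phase_switch = x$phase_switch,
                 final_png_bytes = last$png_bytes,
                 final_resp_a = last$resp_a, final_resp_b = last$resp_b,
                 final_score = last$score)
}

#' @export
autoplot.rnc_evolution <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace,
                            c("resp_a", "resp_b", "png_bytes"),
                            names_to = "quantity")
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation,
                                        y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = sprintf("latent evolution (%s)", object$condition))
  if (!is.na(object$phase_switch)) {
    p <- p + ggplot2::geom_vline(xintercept = object$phase_switch,
                                 linetype = 2, colour = "firebrick")
  }
  p
}
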