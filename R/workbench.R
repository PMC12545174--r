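#' Configuration for the end-to-end synthetic demonstration
#'
#' Bundles the sizes and seeds of the demo pipeline. The reduced defaults
#' keep a full run (simulation, nulls, univariate and multivariate control
#' with cross-validation, inference, embedding) in the tens of seconds; all
#' stages use the identical code paths as full-scale runs.
#'
#' @param seed Master seed; every stage derives its seed from it.
#' @param n_participants,n_images,voxels_per_area,noise_sd,share_decay
#'   Synthetic-cortex sizes (see [synthetic_cortex_config()]).
#' @param n_null Random batches per null distribution.
#' @param uni_condition Univariate condition demonstrated with
#'   cross-validation.
#' @param search_generations,search_population,search_elite,search_mutations,search_random,search_batch
#'   Genetic batch-search sizes for the multivariate stage.
#' @param n_perm Permutations per within-participant test.
#' @param n_boot Bootstrap resamples.
#' @return List of class `rnc_demo_config`.
#' @export
demo_config <- function(seed = 1, n_participants = 4, n_images = 500,
                        voxels_per_area = 50, noise_sd = 0.2,
                        share_decay = 0.3, n_null = 2000,
                        uni_condition = "drive_A_suppress_B",
                        search_generations = 25, search_population = 120,
                        search_elite = 10, search_mutations = c(1, 5, 12),
                        search_random = 80, search_batch = 50,
                        n_perm = 1000, n_boot = 2000) {
  structure(as.list(environment()), class = "rnc_demo_config")
}

#' Run the full synthetic control pipeline
#'
#' Simulates the 4-area chain, builds univariate nulls, runs the
#' cross-validated univariate control for one condition on the most distant
#' pair, runs the pooled disentangling selection for all six pairs and
#' aggregates the control effect by stepwise distance, runs the genetic
#' multivariate search on the most distant pair, performs within-participant
#' permutation tests with Benjamini-Hochberg correction, the population
#' prevalence test and a bootstrap confidence interval, embeds the areas
#' with MDS, and writes all results to `out_dir` (JSON/CSV, with a
#' provenance block). Fully reproducible from (config, seed).
#'
#' @param cfg A [demo_config()].
#' @param out_dir Output directory (created if missing).
#' @return The report list, invisibly; `report.json` and CSVs in `out_dir`.
#' @export
run_demo <- function(cfg = demo_config(), out_dir = tempfile("rnc_demo_")) {
  stopifnot(inherits(cfg, "rnc_demo_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  report <- tryCatch({
    ccfg <- synthetic_cortex_config(
      n_participants = cfg$n_participants, areas = areas_chain(),
      voxels_per_area = cfg$voxels_per_area, n_images = cfg$n_images,
      share_decay = cfg$share_decay, noise_sd = cfg$noise_sd,
      seed = cfg$seed)
    sim <- simulate_hierarchy(ccfg)
    areas <- ccfg$areas$area
    participants <- names(sim$responses)
    profiles <- lapply(areas, function(a) {
      lapply(sim$responses, function(pr) univariate_profile(pr[[a]]))
    })
    names(profiles) <- areas
    pooled <- lapply(profiles, average_profiles)

    stage <- "univariate_nulls"
    nulls <- lapply(seq_along(areas), function(i) {
      build_univariate_null(pooled[[i]], batch_size = 25,
                            n_samples = cfg$n_null, seed = cfg$seed + i)
    })
    names(nulls) <- areas

    stage <- "univariate_cv"
    far <- c(areas[1], areas[length(areas)])
    uni_cv <- crossval_univariate(profiles[[far[1]]], profiles[[far[2]]],
                                  condition = cfg$uni_condition,
                                  n_samples = cfg$n_null,
                                  seed = cfg$seed + 100)

    stage <- "univariate_distance"
    pairs <- utils::combn(areas, 2)
    pair_stats <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      sol <- select_univariate_controls(
        pooled[[a]], pooled[[b]], nulls[[a]]$baseline_score,
        nulls[[b]]$baseline_score, "drive_A_suppress_B")
      eff <- purrr::map_dbl(participants, function(p) {
        pa <- profiles[[a]][[p]]; pb <- profiles[[b]][[p]]
        ctl_a <- mean(pa$value[match(sol$image_id, pa$image_id)])
        ctl_b <- mean(pb$value[match(sol$image_id, pb$image_id)])
        bas_a <- mean(pa$value[match(nulls[[a]]$baseline_image_ids, pa$image_id)])
        bas_b <- mean(pb$value[match(nulls[[b]]$baseline_image_ids, pb$image_id)])
        (abs(ctl_a - bas_a) + abs(ctl_b - bas_b)) / 2
      })
      tibble::tibble(area_x = a, area_y = b, stat = mean(eff),
                     profile_cor = profile_correlation(pooled[[a]], pooled[[b]]))
    })
    by_distance <- aggregate_by_pair_group(pair_stats,
                                           pair_grouping_stepwise(areas))

    stage <- "multivariate_search"
    mcfg <- batch_search_config(
      objective = "disentangle", population = cfg$search_population,
      batch_size = cfg$search_batch, n_elite = cfg$search_elite,
      mutation_counts = cfg$search_mutations, n_random = cfg$search_random,
      generations = cfg$search_generations, seed = cfg$seed + 200)
    rs_far_a <- lapply(sim$responses, function(pr) pr[[far[1]]])
    rs_far_b <- lapply(sim$responses, function(pr) pr[[far[2]]])
    pooled_rs <- function(rs_list) {
      resp <- Reduce(`+`, lapply(rs_list, function(r) r$responses)) /
        length(rs_list)
      response_set(resp, rs_list[[1]]$image_ids, participant = "average",
                   area = rs_list[[1]]$area)
    }
    msearch <- search_controlling_batches(pooled_rs(rs_far_a),
                                          pooled_rs(rs_far_b), mcfg)

    stage <- "inference"
    per_participant <- purrr::map_dfr(participants, function(p) {
      pa <- profiles[[far[1]]][[p]]
      sol <- uni_cv$folds[[match(p, participants)]]
      base_ids <- nulls[[far[1]]]$baseline_image_ids
      dat <- tibble::tibble(
        condition = rep(c("control", "baseline"),
                        c(nrow(sol), length(base_ids))),
        value = c(pa$value[match(sol$image_id, pa$image_id)],
                  pa$value[match(base_ids, pa$image_id)]))
      pt <- permutation_test(
        dat, function(d) mean(d$value[d$condition == "control"]) -
          mean(d$value[d$condition == "baseline"]),
        scheme_image_conditions(), n_perm = cfg$n_perm, sidedness = "one",
        seed = cfg$seed + 300 + match(p, participants))
      tibble::tibble(participant = p, observed = pt$observed, p = pt$p)
    })
    per_participant$p_adj <- bh_adjust(per_participant$p)
    k <- sum(per_participant$p_adj < 0.05)
    prev <- prevalence_pvalue(k, length(participants))
    ci <- bootstrap_ci(per_participant$observed, n_boot = cfg$n_boot,
                       seed = cfg$seed + 400)

    stage <- "embedding"
    emb <- embed_univariate(pooled, seed = cfg$seed + 500)
    opacity <- proximity_opacity(emb$embedded_distances)

    list(
      provenance = list(package = "rnc",
                        version = as.character(utils::packageVersion("rnc")),
                        seed = cfg$seed, config_hash = rlang::hash(cfg)),
      stages = c("simulate", "univariate_nulls", "univariate_cv",
                 "univariate_distance", "multivariate_search", "inference",
                 "embedding"),
      baselines = purrr::map_dbl(nulls, "baseline_score"),
      univariate_cv = uni_cv$eval,
      pair_stats = pair_stats,
      by_distance = by_distance,
      multivariate = list(objective = msearch$objective,
                          best_score = msearch$best_score,
                          n_generations = nrow(msearch$trace)),
      inference = list(per_participant = per_participant,
                       k_significant = k, prevalence_p = prev$p,
                       ci = c(ci$lower, ci$upper)),
      embedding = emb$coords,
      opacity = opacity)
  }, error = function(e) {
    stop(sprintf("demo aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  readr::write_csv(report$univariate_cv,
                   file.path(out_dir, "univariate_cv.csv"), progress = FALSE)
  readr::write_csv(report$by_distance,
                   file.path(out_dir, "stepwise_distance.csv"),
                   progress = FALSE)
  readr::write_csv(report$embedding, file.path(out_dir, "embedding.csv"),
                   progress = FALSE)
  invisible(report)
}
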