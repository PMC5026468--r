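#' Spacing metrics for one image
#'
#' Convenience wrapper computing the three mosaic-regularity summaries used
#' for genotype comparison — packing factor (from the DRP), Voronoi domain
#' variance-to-mean ratio, and the random-normalized NNRI — for a single
#' point pattern.
#'
#' @param pattern a `ppattern`.
#' @param bin_width,max_radius DRP binning (see [compute_drp()]).
#' @param nn_reps random arrays for the NNRI normalization.
#' @param seed integer seed for the NNRI normalization.
#' @return one-row data.frame: `image_id`, `retina_id`, `genotype`, `n`,
#'   `density`, `packing_factor`, `effective_radius`, `vmr`, `cv2`,
#'   `nnri`, `nnri_ratio`.
#' @export
mosaic_metrics <- function(pattern, bin_width = NULL, max_radius = NULL,
                           nn_reps = 99, seed = 1) {
  drp <- compute_drp(pattern, bin_width = bin_width, max_radius = max_radius)
  vor <- compute_domains(pattern)
  nnr <- nnri_ratio(pattern, n_reps = nn_reps, seed = seed)
  data.frame(image_id = pattern$image_id, retina_id = pattern$retina_id,
             genotype = pattern$genotype, n = pattern$n,
             density = drp$overall_density,
             packing_factor = drp$packing_factor,
             effective_radius = drp$effective_radius,
             vmr = vor$vmr, cv2 = vor$cv2,
             nnri = nnr$nnri_measured, nnri_ratio = nnr$nnri_ratio,
             stringsAsFactors = FALSE)
}

#' Default configuration for the end-to-end demo pipeline
#'
#' Two synthetic cohorts: a "wildtype" exclusion-zone (dmin) mosaic and a
#' "mutant" clustered arrangement, with a configurable number of retinas
#' and images per retina, plus DRP/NNRI/Elo settings. All randomness
#' derives from `seed`.
#'
#' @param seed master integer seed.
#' @param out_dir output directory for result files.
#' @param n_retinas retinas per genotype.
#' @param images_per_retina images per retina.
#' @param n_cells cells per image.
#' @param window observation window in micrometres.
#' @param dmin exclusion distance of the wildtype mosaic.
#' @param cluster_sd dispersal of the mutant clusters.
#' @param nn_reps,bin_width NNRI and DRP settings.
#' @return a named list (`run_config`).
#' @export
run_config <- function(seed = 1, out_dir = tempfile("mosaic_run_"),
                       n_retinas = 6, images_per_retina = 3,
                       n_cells = 150, window = c(0, 0, 1000, 1000),
                       dmin = 50, cluster_sd = 15, nn_reps = 25,
                       bin_width = NULL) {
  list(seed = seed, out_dir = out_dir, n_retinas = n_retinas,
       images_per_retina = images_per_retina, n_cells = n_cells,
       window = window, dmin = dmin, cluster_sd = cluster_sd,
       nn_reps = nn_reps, bin_width = bin_width)
}

#' Generate the demo cohorts of a run configuration
#'
#' @param config a [run_config()].
#' @return list of `ppattern`s with image/retina/genotype metadata.
#' @export
simulate_cohorts <- function(config) {
  patterns <- list()
  k <- 0L
  for (geno in c("wildtype", "mutant")) {
    for (r in seq_len(config$n_retinas)) {
      for (i in seq_len(config$images_per_retina)) {
        k <- k + 1L
        sd_k <- (config$seed * 1000L + k) %% .Machine$integer.max
        rid <- sprintf("%s_retina%02d", geno, r)
        iid <- sprintf("%s_img%02d", rid, i)
        patterns[[k]] <- if (geno == "wildtype") {
          gen_dmin(config$n_cells, config$window, dmin = config$dmin,
                   seed = sd_k, image_id = iid, retina_id = rid,
                   genotype = geno)
        } else {
          gen_clustered(n_parents = max(2, round(config$n_cells / 5)),
                        offspring_mean = 5, cluster_sd = config$cluster_sd,
                        window = config$window, seed = sd_k,
                        image_id = iid, retina_id = rid, genotype = geno)
        }
      }
    }
  }
  patterns
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Composes the modules end to end: simulate (or accept) per-image point
#' patterns, compute per-image spacing metrics, aggregate to retinal means,
#' and compare genotypes (t-test per metric for two genotypes, one-way
#' ANOVA + Tukey otherwise). Writes per-image metrics, the per-retina group
#' table, the statistics, and a manifest recording the seed and
#' configuration, all under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param patterns optional list of `ppattern`s; simulated from the config
#'   when omitted.
#' @return invisibly, a list with `per_image`, `per_retina`, `stats`,
#'   `files`.
#' @export
run_pipeline <- function(config = run_config(), patterns = NULL) {
  if (is.null(patterns)) patterns <- simulate_cohorts(config)
  per_image <- do.call(rbind, lapply(seq_along(patterns), function(k) {
    p <- patterns[[k]]
    m <- mosaic_metrics(p, bin_width = config$bin_width,
                        nn_reps = config$nn_reps,
                        seed = (config$seed + k) %% .Machine$integer.max)
    m
  }))
  long <- do.call(rbind, lapply(
    c("packing_factor", "vmr", "nnri_ratio"),
    function(metric) data.frame(image_id = per_image$image_id,
                                retina_id = per_image$retina_id,
                                genotype = per_image$genotype,
                                metric = metric,
                                value = per_image[[metric]],
                                stringsAsFactors = FALSE)))
  per_retina <- retina_means(long)
  metrics <- unique(per_retina$metric)
  n_geno <- length(unique(per_retina$genotype))
  stats_out <- lapply(metrics, function(m) {
    tab <- per_retina[per_retina$metric == m, ]
    if (n_geno == 2) t_test_groups(tab) else anova_tukey(tab)$anova
  })
  names(stats_out) <- metrics
  stats_df <- do.call(rbind, lapply(metrics, function(m)
    cbind(metric = m, stats_out[[m]])))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    per_image = file.path(config$out_dir, "per_image_metrics.csv"),
    per_retina = file.path(config$out_dir, "per_retina_means.csv"),
    stats = file.path(config$out_dir, "group_stats.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_results(per_image, files[["per_image"]])
  write_results(per_retina, files[["per_retina"]])
  write_results(stats_df, files[["stats"]])
  jsonlite::write_json(
    list(package = "retmosaic",
         version = as.character(utils::packageVersion("retmosaic")),
         config = config[setdiff(names(config), "out_dir")],
         n_images = length(patterns),
         outputs = as.list(basename(files[1:3]))),
    files[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_image = per_image, per_retina = per_retina,
                 stats = stats_df, files = files))
}
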