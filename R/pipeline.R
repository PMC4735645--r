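# End-to-end two-group synthetic study: simulate -> preprocess -> epoch ->
# spectra/slopes -> connectivity -> graph metrics -> group statistics.
# This is the driver behind the numbered analysis scripts and the
# acceptance run.

#' Configuration of a two-group synthetic study
#'
#' Each group is a set of simulated "subjects" sharing a signal model
#' (spectral exponent, planted couplings); per-subject seeds are derived
#' deterministically from the top-level seed.
#'
#' @param n_subjects Subjects per group (default 20, a typical
#'   resting-state EEG group size; group sample size also drives the
#'   power of the edgewise Fisher-z maps).
#' @param n_channels Channels (montage rows) per recording.
#' @param duration_s Recording length per subject, seconds.
#' @param rate Sampling rate, Hz (nominal processing rate 128).
#' @param groups Named list of exactly two groups (`A`, `B`), each a
#'   list with `alpha_exponent`, `couplings`, `noise_sd` (defaults: pink
#'   background, no couplings, noise_sd 0.5).
#' @param epoch_length_s,overlap Epoching parameters.
#' @param fit_range 1/f fit range `c(f_lo, f_hi)` in Hz.
#' @param alpha_level Significance level for maps and thresholds.
#' @param seed Top-level integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 20, n_channels = 19,
                            duration_s = 60, rate = 128,
                            groups = list(A = list(), B = list()),
                            epoch_length_s = 2, overlap = 0,
                            fit_range = c(2, 43), alpha_level = 0.05,
                            seed = 1) {
  stopifnot(length(groups) == 2, !is.null(names(groups)))
  defaults <- list(alpha_exponent = 1, couplings = list(), noise_sd = 0.5)
  groups <- lapply(groups, function(g) {
    # no modifyList: it would recurse into the unnamed couplings list
    out <- defaults
    out[names(g)] <- g
    out
  })
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 duration_s = duration_s, rate = rate, groups = groups,
                 epoch_length_s = epoch_length_s, overlap = overlap,
                 fit_range = fit_range, alpha_level = alpha_level,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Deterministic per-subject seed, kept well below 2^31.
subject_seed <- function(seed, group_index, subject) {
  (seed * 131071L + group_index * 8191L + subject * 127L) %% 2000000011L
}

#' Simulate and analyse one group
#'
#' Runs the per-subject chain (simulate, band-pass, epoch, spectra,
#' band-wise connectivity) and aggregates: subject-averaged power
#' spectrum, subject-averaged connectivity matrix per band, and graph
#' metrics of the group-average network per band.
#'
#' @param config A `pipeline_config`.
#' @param group Group name in `names(config$groups)`.
#' @return List with `ps` (group-mean `spectral_estimate`), `conn`
#'   (per-band group-mean `connectivity_matrix`), `metrics` (per-band
#'   `graph_metrics` of the group network), `coords`, `n_subjects`.
#' @export
run_group <- function(config, group) {
  gi <- match(group, names(config$groups))
  if (is.na(gi)) stop("unknown group: ", group)
  gcfg <- config$groups[[gi]]
  bands <- canonical_bands()
  ps_acc <- NULL
  conn_acc <- NULL
  coords <- NULL
  for (s in seq_len(config$n_subjects)) {
    sim <- simulation_config(config$n_channels, config$duration_s,
                             rate = config$rate,
                             alpha_exponent = gcfg$alpha_exponent,
                             couplings = gcfg$couplings,
                             noise_sd = gcfg$noise_sd,
                             seed = subject_seed(config$seed, gi, s))
    rec <- preprocess(generate_recording(sim), config$rate, c(2, 44))
    coords <- rec$coords
    ep <- epoch_recording(rec, config$epoch_length_s, config$overlap)
    ps <- power_spectrum(ep)
    cms <- connectivity_matrices(ep, bands)
    if (is.null(ps_acc)) {
      ps_acc <- ps
      conn_acc <- cms
    } else {
      ps_acc$PS <- ps_acc$PS + ps$PS
      for (b in names(cms)) conn_acc[[b]]$W <- conn_acc[[b]]$W + cms[[b]]$W
    }
  }
  ps_acc$PS <- ps_acc$PS / config$n_subjects
  for (b in names(conn_acc)) {
    conn_acc[[b]]$W <- conn_acc[[b]]$W / config$n_subjects
  }
  metrics <- lapply(conn_acc, graph_metrics)
  list(ps = ps_acc, conn = conn_acc, metrics = metrics,
       coords = coords, n_subjects = config$n_subjects)
}

#' Run the full two-group pipeline
#'
#' Simulates both groups and computes every group comparison: the 1/f
#' slope contrast, per-band distance regressions of connectivity and of
#' functional distance (with slope comparisons), per-band node-level
#' ANOVA of strength / clustering / local efficiency, low x high
#' cross-frequency couplings with Fisher z differences, and per-band
#' edgewise significance maps.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_result` list with elements `groups`, `slope_test`,
#'   `slopes`, `distance_reg`, `anova`, `cross_frequency`, `edge_maps`,
#'   `config`.
#' @export
run_group_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gnames <- names(config$groups)
  res <- lapply(gnames, function(g) run_group(config, g))
  names(res) <- gnames
  A <- res[[1]]; B <- res[[2]]
  bands <- names(A$conn)
  P <- physical_distance(A$coords)

  slope_test <- compare_slopes(A$ps, B$ps, config$fit_range[1],
                               config$fit_range[2])
  slopes <- lapply(res, function(r) fit_slope(r$ps, config$fit_range[1],
                                              config$fit_range[2]))

  distance_reg <- lapply(bands, function(b) {
    list(band = b,
         weight = lapply(res, function(r) distance_regression(r$conn[[b]], P)),
         weight_slope_test = compare_regression_slopes(A$conn[[b]],
                                                       B$conn[[b]], P),
         distance = lapply(res, function(r) {
           distance_regression(r$metrics[[b]]$distance, P)
         }),
         distance_slope_test = compare_regression_slopes(
           A$metrics[[b]]$distance, B$metrics[[b]]$distance, P))
  })
  names(distance_reg) <- bands

  metric_mat <- function(r, what) {
    sapply(bands, function(b) r$metrics[[b]][[what]])
  }
  anova <- lapply(c(strength = "strength", clustering = "clustering",
                    local_efficiency = "local_efficiency"),
                  function(w) {
                    group_band_anova(metric_mat(A, w), metric_mat(B, w),
                                     band_names = bands)
                  })

  cf <- list()
  for (lo in intersect(low_bands(), bands)) {
    for (hi in intersect(high_bands(), bands)) {
      ccA <- cross_frequency_coupling(A$metrics[[lo]]$distance,
                                      A$metrics[[hi]]$distance)
      ccB <- cross_frequency_coupling(B$metrics[[lo]]$distance,
                                      B$metrics[[hi]]$distance)
      cmp <- compare_correlations(ccA$r, ccA$n, ccB$r, ccB$n)
      cf[[paste(lo, hi, sep = "-")]] <-
        list(low = lo, high = hi, r_A = ccA$r, r_B = ccB$r,
             n_A = ccA$n, n_B = ccB$n, z = cmp$z, p = cmp$p)
    }
  }

  edge_maps <- lapply(bands, function(b) {
    edgewise_group_map(A$conn[[b]], B$conn[[b]],
                       A$metrics[[b]]$distance, B$metrics[[b]]$distance,
                       A$n_subjects, B$n_subjects, config$alpha_level)
  })
  names(edge_maps) <- bands

  structure(list(groups = res, slope_test = slope_test, slopes = slopes,
                 distance_reg = distance_reg, anova = anova,
                 cross_frequency = cf, edge_maps = edge_maps,
                 config = config),
            class = "pipeline_result")
}

#' Write pipeline results with a manifest
#'
#' Deterministic file layout under `outdir`: JSON summaries, TSV
#' matrices, and a `manifest.json` listing every artifact with its MD5
#' hash plus the configuration and package version. Refuses to write
#' into a non-empty directory unless `force = TRUE`.
#'
#' @param result A `pipeline_result` (or any named list of data frames /
#'   matrices / lists).
#' @param outdir Output directory (created if missing).
#' @param force Overwrite into a non-empty directory.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(result, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory ", outdir,
         " is not empty; use force = TRUE to overwrite")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_json <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    files[[length(files) + 1]] <<- p
  }
  put_tsv <- function(m, name) {
    p <- file.path(outdir, name)
    utils::write.table(m, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    files[[length(files) + 1]] <<- p
  }
  if (inherits(result, "pipeline_result")) {
    put_json(list(slope_test = result$slope_test,
                  cross_frequency = result$cross_frequency,
                  anova = lapply(result$anova, function(a) {
                    list(group = a$group, interaction = a$interaction,
                         contrasts = a$contrasts)
                  })),
             "statistics.json")
    for (g in names(result$groups)) {
      for (b in names(result$groups[[g]]$conn)) {
        put_tsv(result$groups[[g]]$conn[[b]]$W,
                sprintf("conn_%s_%s.tsv", g, b))
      }
      put_tsv(result$slopes[[g]], sprintf("slopes_%s.tsv", g))
    }
    for (b in names(result$edge_maps)) {
      put_tsv(result$edge_maps[[b]]$classes, sprintf("edgemap_%s.tsv", b))
    }
  } else {
    put_json(result, "results.json")
  }
  manifest <- list(
    artifacts = lapply(files, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    n_artifacts = length(files),
    package_version = as.character(utils::packageVersion("lpcnet")),
    config = if (inherits(result, "pipeline_result")) {
      result$config[setdiff(names(result$config), "groups")]
    }
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
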