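#' Pipeline configuration
#'
#' Builds the structured configuration shared by [run_simulate()] and
#' [run_full()]: output paths, per-stage seeds, and the options of every
#' stage. `species` presets set the DEG count threshold (mouse skin: mean
#' normalized count > 3; human fibroblasts: > 4). Any element can be
#' overridden via `...` using the same nesting (e.g.
#' `alignment = list(n_starts = 10)` replaces only that field).
#'
#' @param out_dir output directory.
#' @param species `"mouse"` or `"human"` DEG preset.
#' @param ... named sub-lists merged over the defaults (`seeds`, `slides`,
#'   `counts`, `trajectories`, `histology`, `alignment`, `signature`,
#'   `migration`).
#' @return an object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(out_dir = "dermalign_out", species = "mouse", ...) {
  cfg <- list(
    paths = list(out_dir = out_dir),
    seeds = list(slides = 101, counts = 102, trajectories = 103, fit = 104),
    slides = list(
      n = 4, weights = c(0.5, 0.62, 0.79, 0.95), mu1 = 45, mu2 = 135,
      kappa = 8, n_bundles = 150, canvas = c(500, 700)),
    counts = list(
      n_genes = 600, n_per_group = 10, n_planted = 20, target_r2 = 0.8,
      noise_sd = 0.1, baseline_mean = 200, dispersion = 0.05),
    trajectories = list(
      n_cells = 200, dt = 8, duration = 270, speed_mean = 10,
      persistence = 0.7, knockdown_factor = 0.75),
    histology = list(min_area = 40, threshold_method = "otsu",
                     opening_radius = 1, reference = "global"),
    alignment = list(n_starts = 5, tol = 1e-6, max_iter = 500,
                     min_separation = 20),
    signature = list(species = species,
                     thresholds = c(thickness = 0.7, collagen = 0.4,
                                    alignment = 0.4),
                     scale = "log"),
    migration = list(test = "welch", min_span_frac = 0.5,
                     control = "aligned_ctrl")
  )
  over <- list(...)
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]]))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    else cfg[[k]] <- over[[k]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config` (for `write_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml reads vectors back as lists in some shapes; flatten numeric leaves
  cfg$slides$weights <- as.numeric(cfg$slides$weights)
  cfg$slides$canvas <- as.numeric(cfg$slides$canvas)
  cfg$signature$thresholds <- unlist(cfg$signature$thresholds)
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[dermalign] %s | %s", stage,
                  paste(sprintf("%s=%s", names(c(...)), c(...)), collapse = " ")))
}

#' Generate the full synthetic study bundle
#'
#' Emits slides (image, dermis mask, truth and epidermis CSVs), a count
#' matrix with per-sample metrics and planted-gene truth, trajectory tables
#' for the four substrate/knockdown conditions, and a manifest recording
#' every file with its checksum plus the seeds and parameters used.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) the manifest data.frame.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory ", out)
  files <- character()

  # slides, one per configured mixture weight
  sc <- cfg$slides
  log_stage("simulate/slides", n = sc$n, seed = cfg$seeds$slides)
  for (i in seq_len(sc$n)) {
    w <- sc$weights[(i - 1) %% length(sc$weights) + 1]
    spec <- orientation_mixture_spec(sc$mu1, sc$mu2, sc$kappa, w)
    sl <- generate_slide(spec, n_bundles = sc$n_bundles, canvas = sc$canvas,
                         seed = cfg$seeds$slides + i)
    base <- file.path(out, sprintf("slide_%02d", i))
    p <- write_slide(sl, paste0(base, ".png"))
    write_image(sl$dermis_mask * 1, paste0(base, "_dermis.png"))
    files <- c(files, p, paste0(base, "_dermis.png"))
  }

  # counts with planted metric-correlated genes
  cc <- cfg$counts
  log_stage("simulate/counts", genes = cc$n_genes, seed = cfg$seeds$counts)
  sim <- simulate_count_study(cc, seed = cfg$seeds$counts)
  p <- write_counts(sim, file.path(out, "counts.tsv"),
                    file.path(out, "sample_metrics.csv"),
                    file.path(out, "counts_truth.csv"))
  files <- c(files, p)

  # trajectories: aligned/random substrate x control/knockdown
  tc <- cfg$trajectories
  log_stage("simulate/trajectories", cells = tc$n_cells,
            seed = cfg$seeds$trajectories)
  conds <- expand.grid(substrate = c("aligned", "random"),
                       kd = c(1, tc$knockdown_factor),
                       stringsAsFactors = FALSE)
  trs <- lapply(seq_len(nrow(conds)), function(i) {
    generate_trajectories(
      trajectory_params(n_cells = tc$n_cells, dt = tc$dt,
                        duration = tc$duration, speed_mean = tc$speed_mean,
                        persistence = tc$persistence,
                        substrate = conds$substrate[i],
                        knockdown_factor = conds$kd[i]),
      seed = cfg$seeds$trajectories + i, well = paste0("w", i))
  })
  p <- file.path(out, "trajectories.csv")
  write_trajectories(do.call(rbind, trs), p)
  files <- c(files, p)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  write_config(cfg, file.path(out, "config.yaml"))
  invisible(manifest)
}

# Samples a two-group (saline/bleomycin) study: per-sample metrics with a
# group shift in each metric, and planted genes split across the metrics.
simulate_count_study <- function(cc, seed) {
  with_seed(seed * 2 + 1, {
    n <- cc$n_per_group
    groups <- rep(c("saline", "bleo"), each = n)
    metrics <- data.frame(
      sample = paste0("s", seq_len(2 * n)),
      thickness = stats::rnorm(2 * n, rep(c(40, 60), each = n), 4),
      alignment = stats::rnorm(2 * n, rep(c(0.62, 0.82), each = n), 0.05),
      collagen  = stats::rnorm(2 * n, rep(c(0.30, 0.45), each = n), 0.04))
  })
  k <- cc$n_planted
  planted <- data.frame(
    gene = paste0("gene", seq_len(3 * k)),
    metric = rep(c("alignment", "thickness", "collagen"), each = k),
    slope = NA_real_, noise_sd = cc$noise_sd)
  for (m in unique(planted$metric))
    planted$slope[planted$metric == m] <- slope_for_target_r2(
      cc$target_r2, metrics[[m]], cc$noise_sd, cc$baseline_mean, cc$dispersion)
  sig <- signature_spec(cc$n_genes, planted, cc$baseline_mean, cc$dispersion)
  generate_counts(sig, metrics, groups, seed = seed)
}

#' Run the full synthetic end-to-end study
#'
#' Executes histology (segmentation, geometry, metrics) on every slide,
#' alignment scoring, the signature workflow on the count matrix, and the
#' migration statistics, in order, writing per-stage CSV outputs and a single
#' JSON report. Any stage failure stops with the failing stage named.
#'
#' @param cfg a [pipeline_config()] whose `out_dir` holds [run_simulate()]
#'   outputs (or equivalently formatted user data).
#' @return (invisibly) the report list.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$paths$out_dir
  stage <- function(name, expr) {
    log_stage(name, seed = cfg$seeds$fit)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  slide_imgs <- sort(list.files(out, "^slide_[0-9]+\\.png$", full.names = TRUE))
  if (!length(slide_imgs)) stop("stage 'histology' failed: no slide images in ", out)

  histo <- stage("histology+alignment", {
    lapply(slide_imgs, function(p) {
      img <- read_image(p)
      mask <- read_image(sub("\\.png$", "_dermis.png", p)) > 0.5
      h <- cfg$histology
      m <- histology_metrics(img, mask, min_area = h$min_area,
                             threshold_method = h$threshold_method,
                             opening_radius = h$opening_radius,
                             reference = h$reference,
                             seed = cfg$seeds$fit,
                             n_starts = cfg$alignment$n_starts,
                             tol = cfg$alignment$tol,
                             max_iter = cfg$alignment$max_iter,
                             min_separation = cfg$alignment$min_separation)
      ang_path <- sub("\\.png$", "_angles.csv", p)
      utils::write.csv(data.frame(bundle_id = m$bundles$bundle_id,
                                  cx = m$bundles$cx, cy = m$bundles$cy,
                                  area_px2 = m$bundles$area,
                                  theta_deg = m$bundles$orientation,
                                  theta_rel_deg = fold_axial(m$angles)),
                       ang_path, row.names = FALSE)
      list(slide = basename(p), thickness = m$thickness,
           collagen_fraction = m$collagen_fraction,
           alignment_score = m$alignment_score, n_bundles = m$n_bundles,
           mu = m$decomposition$mu, w = m$decomposition$w,
           converged = m$decomposition$converged)
    })
  })
  metrics_tab <- do.call(rbind, lapply(histo, function(h)
    data.frame(slide = h$slide, thickness = h$thickness,
               collagen_fraction = h$collagen_fraction,
               alignment_score = h$alignment_score, n_bundles = h$n_bundles)))
  utils::write.csv(metrics_tab, file.path(out, "slide_metrics.csv"),
                   row.names = FALSE)

  sig <- stage("signature", {
    counts <- read_counts(file.path(out, "counts.tsv"))
    meta <- utils::read.csv(file.path(out, "sample_metrics.csv"))
    res <- signature_workflow(
      counts, meta, meta$group,
      control = intersect(c("saline", "control"), meta$group)[1],
      crit = deg_criteria(cfg$signature$species),
      thresholds = cfg$signature$thresholds, scale = cfg$signature$scale)
    for (m in names(res$signatures))
      writeLines(res$signatures[[m]]$genes,
                 file.path(out, paste0("signature_", m, ".txt")))
    res
  })

  mig <- stage("migration", {
    tr <- read_trajectories(file.path(out, "trajectories.csv"))
    st <- compute_stats(tr, min_span_frac = cfg$migration$min_span_frac)
    utils::write.csv(st$per_cell, file.path(out, "migration_per_cell.csv"),
                     row.names = FALSE)
    ctrl <- cfg$migration$control
    norm <- normalize_to_control(st, ctrl)
    utils::write.csv(norm, file.path(out, "migration_per_group.csv"),
                     row.names = FALSE)
    cmp <- if (all(c("aligned_ctrl", paste0("aligned_kd",
             cfg$trajectories$knockdown_factor)) %in% norm$condition))
      compare_conditions(st, "aligned_ctrl",
                         paste0("aligned_kd", cfg$trajectories$knockdown_factor),
                         test = cfg$migration$test)
    else NULL
    list(per_group = norm, comparison = cmp)
  })

  report <- list(
    histology = metrics_tab,
    signatures = lapply(sig$signatures, function(s)
      list(metric = s$metric, n_genes = length(s$genes),
           n_unique = length(s$unique_genes), genes = s$genes)),
    n_pooled_degs = length(sig$deg_genes),
    migration = list(per_group = mig$per_group, comparison = mig$comparison),
    seeds = cfg$seeds)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
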