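#' Specify a synthetic count matrix with planted metric-correlated genes
#'
#' Describes a gene-by-sample negative binomial count matrix in which a
#' chosen subset of "planted" genes has expected log2 counts linear in a
#' per-sample histology metric (dermis thickness, total collagen or bundle
#' alignment), while background genes are independent of the metrics.
#' Optional per-gene group effects add treatment-vs-control fold changes.
#'
#' @param n_genes total number of genes.
#' @param planted_genes data.frame with columns `gene` (id within
#'   `gene1..geneN`), `metric` (metric column name), `slope` (log2 units per
#'   metric unit) and `noise_sd` (per-sample log2 biological noise sd). May
#'   have zero rows.
#' @param baseline_mean expected normalized count scale for a gene at the
#'   metric mean (> 0).
#' @param dispersion negative binomial dispersion \eqn{\phi} (> 0);
#'   `var = mu + phi * mu^2`.
#' @param group_effects optional named numeric vector: gene id -> log2 fold
#'   change applied to every non-reference group.
#' @return an object of class `signature_spec`.
#' @export
signature_spec <- function(n_genes, planted_genes = NULL,
                           baseline_mean = 200, dispersion = 0.05,
                           group_effects = NULL) {
  if (baseline_mean <= 0) stop("baseline_mean must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (is.null(planted_genes))
    planted_genes <- data.frame(gene = character(), metric = character(),
                                slope = numeric(), noise_sd = numeric())
  genes <- paste0("gene", seq_len(n_genes))
  if (!all(planted_genes$gene %in% genes))
    stop("planted_genes contains ids outside the gene universe")
  if (anyDuplicated(planted_genes$gene))
    stop("a gene may be planted on at most one metric")
  if (!is.null(group_effects) && !all(names(group_effects) %in% genes))
    stop("group_effects contains ids outside the gene universe")
  structure(list(n_genes = n_genes, genes = genes,
                 planted_genes = planted_genes,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 group_effects = group_effects),
            class = "signature_spec")
}

#' Slope giving a target population r-squared for a planted gene
#'
#' The population squared correlation between a planted gene's log2 counts
#' and its metric is `slope^2 * var(metric)` over the total log2 variance,
#' which also includes the biological noise `noise_sd^2` and the negative
#' binomial sampling noise, approximated on the log2 scale as
#' `(1/mu + phi) / ln(2)^2`.
#'
#' @param r2 target population r-squared in (0, 1).
#' @param metric numeric vector of per-sample metric values.
#' @param noise_sd biological log2 noise sd.
#' @param baseline_mean,dispersion as in [signature_spec()].
#' @return the required slope (log2 units per metric unit).
#' @export
slope_for_target_r2 <- function(r2, metric, noise_sd = 0.1,
                                baseline_mean = 200, dispersion = 0.05) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must be in (0, 1)")
  v_nb <- (1 / baseline_mean + dispersion) / log(2)^2
  sqrt((r2 / (1 - r2)) * (noise_sd^2 + v_nb) / stats::var(metric))
}

#' Generate a count matrix with planted metric-correlated genes
#'
#' Counts are negative binomial with per-sample size factors (log-normal
#' depth variation), so the matrix exercises the same median-of-ratios
#' normalization the signature stage applies. Planted genes track their
#' metric (centred) linearly in log2 expected counts; background genes are
#' flat apart from any `group_effects`.
#'
#' @param sig a [signature_spec()].
#' @param metrics data.frame with a `sample` column plus one numeric column
#'   per metric (e.g. `thickness`, `alignment`, `collagen`).
#' @param groups character/factor vector of group labels, one per sample; the
#'   first level (or `"control"`/`"saline"` if present) is the reference for
#'   `group_effects`.
#' @param seed integer seed.
#' @param sf_sd sd of log-normal size-factor variation (0 for equal depth).
#' @return list with `counts` (integer matrix, genes x samples), `metrics`,
#'   `groups`, `size_factors` (true simulated depth factors) and `truth`
#'   (the planted gene table).
#' @export
generate_counts <- function(sig, metrics, groups, seed, sf_sd = 0.15) {
  stopifnot(inherits(sig, "signature_spec"))
  if (missing(seed)) stop("seed is required")
  if (nrow(metrics) == 0) stop("metrics table is empty")
  if (!"sample" %in% names(metrics)) stop("metrics needs a 'sample' column")
  n_s <- nrow(metrics)
  if (length(groups) != n_s) stop("groups must match the metrics rows")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (min(table(groups)) < 3) stop("need >= 3 samples per group")
  metric_cols <- setdiff(names(metrics), "sample")
  if (!all(sig$planted_genes$metric %in% metric_cols))
    stop("planted gene targets an unknown metric: ",
         paste(setdiff(sig$planted_genes$metric, metric_cols), collapse = ", "))

  ref <- intersect(c("control", "saline"), unique(groups))
  ref <- if (length(ref)) ref[1] else sort(unique(groups))[1]

  with_seed(seed, {
    sf <- exp(stats::rnorm(n_s, 0, sf_sd))
    sf <- sf / exp(mean(log(sf)))
    log2mu <- matrix(log2(sig$baseline_mean), sig$n_genes, n_s,
                     dimnames = list(sig$genes, metrics$sample))
    if (nrow(sig$planted_genes)) {
      for (k in seq_len(nrow(sig$planted_genes))) {
        p <- sig$planted_genes[k, ]
        z <- metrics[[p$metric]] - mean(metrics[[p$metric]])
        log2mu[p$gene, ] <- log2mu[p$gene, ] + p$slope * z +
          stats::rnorm(n_s, 0, p$noise_sd)
      }
    }
    if (!is.null(sig$group_effects)) {
      treated <- groups != ref
      for (g in names(sig$group_effects))
        log2mu[g, treated] <- log2mu[g, treated] + sig$group_effects[[g]]
    }
    mu <- sweep(2^log2mu, 2, sf, `*`)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / sig$dispersion),
      nrow = sig$n_genes, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    list(counts = counts, metrics = metrics, groups = groups,
         size_factors = sf, truth = sig$planted_genes)
  })
}

#' Write a generated count bundle as plain files
#'
#' @param cm the list returned by [generate_counts()].
#' @param counts_path TSV path (rows = genes, columns = samples).
#' @param metrics_path CSV path for per-sample metrics + group.
#' @param truth_path CSV path for the planted-gene table.
#' @return written paths, invisibly.
#' @export
write_counts <- function(cm, counts_path, metrics_path, truth_path) {
  utils::write.table(data.frame(gene = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- cm$metrics; m$group <- cm$groups
  utils::write.csv(m, metrics_path, row.names = FALSE)
  utils::write.csv(cm$truth, truth_path, row.names = FALSE)
  invisible(c(counts = counts_path, metrics = metrics_path, truth = truth_path))
}

#' Read a counts TSV written by [write_counts()]
#'
#' @param counts_path TSV with a `gene` column then one column per sample.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(counts_path) {
  d <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  m
}
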