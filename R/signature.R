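#' Median-of-ratios count normalization
#'
#' Size factor for each sample is the median across genes of the ratio of
#' its counts to the per-gene geometric mean, computed over genes with
#' positive counts in every sample; normalized counts are raw counts divided
#' by the size factor.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @param allow_pseudo if no gene is positive in every sample, compute the
#'   geometric-mean reference over positive counts only instead of erroring.
#' @return list with `normalized` (matrix) and `size_factors` (named vector,
#'   geometric mean 1 is not enforced; raw medians of ratios as in the
#'   standard estimator).
#' @export
normalize_counts <- function(counts, allow_pseudo = FALSE) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be nonnegative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    counts_ref <- counts[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(counts_ref)))
  } else {
    if (!allow_pseudo)
      stop("no gene has positive counts in every sample; ",
           "set allow_pseudo = TRUE to use a positive-count pseudo-reference")
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    ref <- exp(rowMeans(lg, na.rm = TRUE))
    keep <- is.finite(ref) & ref > 0
    counts_ref <- counts[keep, , drop = FALSE]
    ref <- ref[keep]
  }
  sf <- apply(sweep(counts_ref, 1, ref, `/`), 2,
              function(col) stats::median(col[is.finite(col) & col > 0]))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; check for empty samples")
  list(normalized = sweep(counts, 2, sf, `/`), size_factors = sf)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with p-values sorted ascending, the adjusted value at
#' rank i is `min_{j >= i} (n / j) p_(j)`, capped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(cummin(rev(p[o] * n / seq_len(n))), 1)
  out <- numeric(n)
  out[o] <- rev(adj)
  out
}

#' DEG criteria presets
#'
#' Joint differential-expression filters: mean normalized count strictly
#' above `min_norm_count` (mouse skin preset 3, human fibroblast preset 4),
#' absolute fold change above `min_abs_fc` (1.5) and BH-adjusted p below
#' `alpha` (0.05).
#'
#' @param species `"mouse"` or `"human"`, or pass the thresholds directly.
#' @param min_norm_count,min_abs_fc,alpha threshold overrides.
#' @param adjust multiple-testing adjustment (only `"BH"` implemented).
#' @return an object of class `deg_criteria`.
#' @export
deg_criteria <- function(species = c("mouse", "human"),
                         min_norm_count = NULL, min_abs_fc = 1.5,
                         alpha = 0.05, adjust = "BH") {
  species <- match.arg(species)
  if (is.null(min_norm_count))
    min_norm_count <- if (species == "mouse") 3 else 4
  if (min_abs_fc <= 1) stop("min_abs_fc must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (adjust != "BH") stop("only BH adjustment is implemented")
  structure(list(species = species, min_norm_count = min_norm_count,
                 min_abs_fc = min_abs_fc, alpha = alpha, adjust = adjust),
            class = "deg_criteria")
}

#' Call differentially expressed genes for one contrast
#'
#' Per-gene Welch t-test on `log2(normalized + 1)` between the two groups,
#' BH adjustment across all tested genes, fold change from group means of
#' normalized counts with a pseudocount of 1. A gene passes iff its mean
#' normalized count (across the contrast samples) is strictly greater than
#' `crit$min_norm_count`, `|FC| > min_abs_fc` (i.e. FC > 1.5 or < 1/1.5) and
#' `p_adj < alpha`. Genes with zero variance in both groups get p = 1 when
#' the group means are equal and p = 0 when they differ.
#'
#' @param counts raw count matrix, genes x samples.
#' @param groups group label per sample.
#' @param contrast character pair `c(reference, treatment)`.
#' @param crit a [deg_criteria()].
#' @param normalized optionally, a pre-computed [normalize_counts()] result
#'   for the full matrix (so pooling over several contrasts shares size
#'   factors).
#' @return data.frame: `gene`, `log2fc` (treatment over reference), `p`,
#'   `p_adj`, `mean_norm_count`, `pass`.
#' @export
call_degs <- function(counts, groups, contrast, crit = deg_criteria("mouse"),
                      normalized = NULL) {
  groups <- as.character(groups)
  if (length(contrast) != 2 || !all(contrast %in% groups))
    stop("contrast must name two groups present in `groups`")
  ia <- groups == contrast[1]; ib <- groups == contrast[2]
  if (sum(ia) < 2 || sum(ib) < 2) stop("each contrast group needs >= 2 samples")
  if (is.null(normalized)) normalized <- normalize_counts(counts)
  nm <- normalized$normalized
  la <- log2(nm[, ia, drop = FALSE] + 1)
  lb <- log2(nm[, ib, drop = FALSE] + 1)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  na <- sum(ia); nb <- sum(ib)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zerovar <- se2 == 0
  p[zerovar] <- ifelse(ma[zerovar] == mb[zerovar], 1, 0)
  p[!is.finite(p)] <- 1
  fc <- (rowMeans(nm[, ib, drop = FALSE]) + 1) /
        (rowMeans(nm[, ia, drop = FALSE]) + 1)
  mean_norm <- rowMeans(nm[, ia | ib, drop = FALSE])
  p_adj <- bh_adjust(p)
  data.frame(gene = rownames(counts),
             log2fc = log2(fc), p = p, p_adj = p_adj,
             mean_norm_count = mean_norm,
             pass = mean_norm > crit$min_norm_count &
                    (fc > crit$min_abs_fc | fc < 1 / crit$min_abs_fc) &
                    p_adj < crit$alpha,
             row.names = NULL)
}

#' Pool DEGs over all treatment-vs-control contrasts
#'
#' A gene is a pooled DEG if it passes the criteria in any comparison of a
#' non-control group against the control group.
#'
#' @param counts raw count matrix.
#' @param groups group labels per sample.
#' @param control the reference group label.
#' @param crit a [deg_criteria()].
#' @return list with `deg_genes` (character vector) and `tables` (one
#'   [call_degs()] table per contrast).
#' @export
pooled_degs <- function(counts, groups, control, crit = deg_criteria("mouse")) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not found")
  others <- setdiff(unique(groups), control)
  nrm <- normalize_counts(counts)
  tables <- lapply(others, function(g)
    call_degs(counts, groups, c(control, g), crit, normalized = nrm))
  names(tables) <- others
  pass <- unique(unlist(lapply(tables, function(t) t$gene[t$pass])))
  list(deg_genes = pass, tables = tables)
}

#' Correlate every gene's expression to a histology metric
#'
#' Per-gene squared Pearson correlation between per-sample expression
#' (`log2(normalized + 1)` by default, or normalized counts with
#' `scale = "linear"`) and the metric. Genes with zero expression variance
#' get r^2 = 0 by convention.
#'
#' @param normalized normalized count matrix, genes x samples.
#' @param metric numeric metric value per sample.
#' @param scale `"log"` (default) or `"linear"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `gene`, `r2`, `sign` (+1/-1/0).
#' @export
correlate_to_metric <- function(normalized, metric,
                                scale = c("log", "linear"),
                                method = c("pearson", "spearman")) {
  scale <- match.arg(scale); method <- match.arg(method)
  if (length(metric) != ncol(normalized))
    stop("metric must have one value per sample")
  if (any(!is.finite(metric))) stop("metric values must be finite")
  if (ncol(normalized) < 4) stop("need >= 4 samples")
  if (stats::var(metric) == 0) stop("metric is constant across samples")
  x <- if (scale == "log") log2(normalized + 1) else normalized
  if (method == "spearman") {
    metric <- rank(metric)
    x <- t(apply(x, 1, rank))
  }
  xv <- apply(x, 1, stats::var)
  r <- rep(0, nrow(x))
  ok <- xv > 0
  if (any(ok)) r[ok] <- apply(x[ok, , drop = FALSE], 1, stats::cor, y = metric)
  data.frame(gene = rownames(normalized), r2 = r^2, sign = sign(r),
             row.names = NULL)
}

#' Build per-metric gene signatures
#'
#' A metric's signature is the set of genes whose squared correlation with
#' that metric exceeds the metric's cutoff, intersected with the pooled DEG
#' set. Genes belonging to exactly one metric's signature form that metric's
#' unique set (the three unique sets are pairwise disjoint by construction).
#'
#' @param correlations named list of [correlate_to_metric()] tables, one per
#'   metric.
#' @param deg_genes character vector of pooled DEG ids.
#' @param thresholds named numeric vector of r^2 cutoffs; defaults to the
#'   dermal-fibrosis presets `c(thickness = 0.7, collagen = 0.4,
#'   alignment = 0.4)`.
#' @return named list of `metric_signature` objects: each with `metric`,
#'   `genes`, `unique_genes`.
#' @export
build_signatures <- function(correlations, deg_genes,
                             thresholds = c(thickness = 0.7, collagen = 0.4,
                                            alignment = 0.4)) {
  if (!all(names(thresholds) %in% names(correlations)))
    stop("threshold names must match correlation metrics: missing ",
         paste(setdiff(names(thresholds), names(correlations)), collapse = ", "))
  sigs <- lapply(names(thresholds), function(m) {
    co <- correlations[[m]]
    genes <- intersect(co$gene[co$r2 > thresholds[[m]]], deg_genes)
    structure(list(metric = m, genes = genes, unique_genes = character()),
              class = "metric_signature")
  })
  names(sigs) <- names(thresholds)
  for (m in names(sigs)) {
    others <- unlist(lapply(sigs[setdiff(names(sigs), m)], `[[`, "genes"))
    sigs[[m]]$unique_genes <- setdiff(sigs[[m]]$genes, others)
  }
  sigs
}

#' @export
print.metric_signature <- function(x, ...) {
  cat("metric_signature [", x$metric, "]: ", length(x$genes), " genes, ",
      length(x$unique_genes), " unique\n", sep = "")
  invisible(x)
}

#' Run the full histology-correlated signature workflow
#'
#' Normalizes, calls pooled DEGs against the control group, prefilters to
#' expressed genes (mean normalized count above the count threshold across
#' all samples), correlates every expressed gene to each metric, and builds
#' the thresholded, DEG-intersected signatures.
#'
#' @param counts raw count matrix, genes x samples.
#' @param metrics data.frame with `sample` plus one column per metric named
#'   in `thresholds`.
#' @param groups group labels per sample.
#' @param control control group label.
#' @param crit a [deg_criteria()].
#' @param thresholds named r^2 cutoffs (see [build_signatures()]).
#' @param scale correlation scale, see [correlate_to_metric()].
#' @return list with `signatures`, `deg_genes`, `deg_tables`,
#'   `correlations`, `size_factors`, `expressed_genes`.
#' @export
signature_workflow <- function(counts, metrics, groups, control,
                               crit = deg_criteria("mouse"),
                               thresholds = c(thickness = 0.7, collagen = 0.4,
                                              alignment = 0.4),
                               scale = "log") {
  nrm <- normalize_counts(counts)
  degs <- pooled_degs(counts, groups, control, crit)
  expressed <- rowMeans(nrm$normalized) > crit$min_norm_count
  nm <- nrm$normalized[expressed, , drop = FALSE]
  correlations <- lapply(names(thresholds), function(m) {
    if (!m %in% names(metrics)) stop("metrics table lacks column ", m)
    correlate_to_metric(nm, metrics[[m]], scale = scale)
  })
  names(correlations) <- names(thresholds)
  list(signatures = build_signatures(correlations, degs$deg_genes, thresholds),
       deg_genes = degs$deg_genes, deg_tables = degs$tables,
       correlations = correlations, size_factors = nrm$size_factors,
       expressed_genes = rownames(counts)[expressed])
}
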