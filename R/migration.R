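#' Per-cell and per-group migration statistics
#'
#' For every tracked cell: net displacement (straight-line start-to-end
#' distance), accumulated distance (sum of step lengths) and directionality
#' (their ratio, 1 = ballistic, 0 = closed loop). Cells spanning less than
#' `min_span_frac` of the movie are excluded and reported in the QC summary;
#' group means are taken over the retained cells of each condition.
#'
#' @param tr a `trajectory_set` (long data.frame with `cell_id`, `t_min`,
#'   `x_px`, `y_px` and optionally `well`, `condition`).
#' @param min_span_frac minimum fraction of the movie duration a track must
#'   cover to be analyzed (default 0.5).
#' @return an object of class `migration_stats`: list with `per_cell`
#'   (data.frame: `cell_id`, `condition`, `well`, `n_points`,
#'   `net_displacement`, `accumulated_distance`, `directionality`),
#'   `per_group` (data.frame: `condition`, `n_cells`, `mean_displacement`,
#'   `mean_accumulated`, `mean_directionality`) and `qc` (counts of analyzed
#'   and excluded cells).
#' @export
compute_stats <- function(tr, min_span_frac = 0.5) {
  need <- c("cell_id", "t_min", "x_px", "y_px")
  if (!all(need %in% names(tr)))
    stop("trajectory table must have columns ", paste(need, collapse = ", "))
  if (nrow(tr) == 0) stop("trajectory set is empty")
  if (!"condition" %in% names(tr)) tr$condition <- "all"
  if (!"well" %in% names(tr)) tr$well <- "w1"
  movie_span <- max(tr$t_min) - min(tr$t_min)

  key <- paste(tr$condition, tr$well, tr$cell_id, sep = "\r")
  cells <- split(tr[, c("t_min", "x_px", "y_px", "condition", "well",
                        "cell_id")], key)
  per_cell <- do.call(rbind, lapply(cells, function(d) {
    d <- d[order(d$t_min), ]
    if (any(diff(d$t_min) <= 0)) stop("timestamps must be strictly increasing per cell")
    n <- nrow(d)
    net <- sqrt((d$x_px[n] - d$x_px[1])^2 + (d$y_px[n] - d$y_px[1])^2)
    acc <- sum(sqrt(diff(d$x_px)^2 + diff(d$y_px)^2))
    data.frame(cell_id = d$cell_id[1], condition = d$condition[1],
               well = d$well[1], n_points = n,
               span = d$t_min[n] - d$t_min[1],
               net_displacement = net, accumulated_distance = acc,
               directionality = if (acc > 0) net / acc else 0)
  }))
  rownames(per_cell) <- NULL
  short <- per_cell$n_points < 2 |
    (movie_span > 0 & per_cell$span < min_span_frac * movie_span)
  qc <- list(n_total = nrow(per_cell), n_analyzed = sum(!short),
             n_excluded = sum(short))
  per_cell <- per_cell[!short, setdiff(names(per_cell), "span")]
  if (nrow(per_cell) == 0) stop("no cell passes the track-length filter")

  per_group <- do.call(rbind, lapply(split(per_cell, per_cell$condition),
    function(d) data.frame(condition = d$condition[1], n_cells = nrow(d),
                           mean_displacement = mean(d$net_displacement),
                           mean_accumulated = mean(d$accumulated_distance),
                           mean_directionality = mean(d$directionality))))
  rownames(per_group) <- NULL
  structure(list(per_cell = per_cell, per_group = per_group, qc = qc),
            class = "migration_stats")
}

#' @export
print.migration_stats <- function(x, ...) {
  cat("migration_stats:", x$qc$n_analyzed, "cells analyzed (",
      x$qc$n_excluded, "excluded )\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Normalize group mean displacements to a control condition
#'
#' Divides every condition's mean net displacement by the control
#' condition's mean, so the control maps to exactly 1.
#'
#' @param stats a [compute_stats()] result.
#' @param control_label the control condition label.
#' @return `per_group` table with an added `normalized_mean_displacement`
#'   column.
#' @export
normalize_to_control <- function(stats, control_label) {
  stopifnot(inherits(stats, "migration_stats"))
  g <- stats$per_group
  if (!control_label %in% g$condition)
    stop("control condition '", control_label, "' not present")
  ctrl <- g$mean_displacement[g$condition == control_label]
  g$normalized_mean_displacement <- g$mean_displacement / ctrl
  g
}

#' Compare per-cell displacement between two conditions
#'
#' Welch two-sample t-test (default) or Mann-Whitney test on per-cell net
#' displacement, with the effect reported as the ratio of group means
#' (B over A).
#'
#' @param stats a [compute_stats()] result.
#' @param group_a,group_b condition labels (A is the reference of the ratio).
#' @param test `"welch"` (default) or `"wilcox"`.
#' @param metric per-cell column to compare (default `"net_displacement"`).
#' @return list with `ratio` (mean B / mean A), `p_value`, `test`,
#'   `n` (per-group cell counts).
#' @export
compare_conditions <- function(stats, group_a, group_b,
                               test = c("welch", "wilcox"),
                               metric = "net_displacement") {
  test <- match.arg(test)
  stopifnot(inherits(stats, "migration_stats"))
  pc <- stats$per_cell
  a <- pc[[metric]][pc$condition == group_a]
  b <- pc[[metric]][pc$condition == group_b]
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 cells per group")
  p <- if (test == "welch")
    stats::t.test(b, a)$p.value
  else
    stats::wilcox.test(b, a)$p.value
  list(ratio = mean(b) / mean(a), p_value = p, test = test,
       n = c(a = length(a), b = length(b)))
}
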