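make_track <- function(cell_id, xy, condition = "a", dt = 8) {
  data.frame(cell_id = cell_id,
             t_min = seq(0, by = dt, length.out = nrow(xy)),
             x_px = xy[, 1], y_px = xy[, 2], well = "w1",
             condition = condition)
}

test_that("ballistic and closed-loop tracks hit the metric extremes", {
  straight <- make_track(1, cbind(seq(0, 50, by = 10), 0))  # 5 steps of 10
  loop <- make_track(2, cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)))
  st <- compute_stats(rbind(straight, loop), min_span_frac = 0)
  pc <- st$per_cell[order(st$per_cell$cell_id), ]
  expect_equal(pc$net_displacement[1], 50)
  expect_equal(pc$accumulated_distance[1], 50)
  expect_equal(pc$directionality[1], 1)
  expect_equal(pc$net_displacement[2], 0)
  expect_equal(pc$directionality[2], 0)
  expect_error(compute_stats(straight[0, ]), "empty")
})

test_that("accumulated distance is never below net displacement", {
  tr <- generate_trajectories(trajectory_params(n_cells = 200), seed = 61)
  st <- compute_stats(tr)
  expect_true(all(st$per_cell$accumulated_distance >=
                  st$per_cell$net_displacement - 1e-9))
  expect_true(all(st$per_cell$directionality >= 0 &
                  st$per_cell$directionality <= 1))
})

test_that("metrics are invariant under translation, rotation and time relabeling", {
  tr <- generate_trajectories(trajectory_params(n_cells = 30), seed = 62)
  st <- compute_stats(tr)
  shifted <- tr; shifted$x_px <- tr$x_px + 500; shifted$y_px <- tr$y_px - 120
  expect_equal(compute_stats(shifted)$per_cell$net_displacement,
               st$per_cell$net_displacement, tolerance = 1e-9)
  a <- 0.7
  rotated <- tr
  rotated$x_px <- cos(a) * tr$x_px - sin(a) * tr$y_px
  rotated$y_px <- sin(a) * tr$x_px + cos(a) * tr$y_px
  expect_equal(compute_stats(rotated)$per_cell$accumulated_distance,
               st$per_cell$accumulated_distance, tolerance = 1e-9)
  hours <- tr; hours$t_min <- tr$t_min / 60
  expect_equal(compute_stats(hours)$per_cell$net_displacement,
               st$per_cell$net_displacement, tolerance = 1e-12)
})

test_that("short tracks are excluded and reported in QC", {
  full <- make_track(1, cbind(0:10 * 5, 0))
  short <- make_track(2, cbind(c(0, 5, 10), 0))  # spans 16 of 80 minutes
  st <- compute_stats(rbind(full, short), min_span_frac = 0.5)
  expect_equal(st$qc$n_excluded, 1)
  expect_equal(st$per_cell$cell_id, 1)
})

test_that("control normalization maps control to 1 and scales others", {
  ctrl <- make_track(1, cbind(seq(0, 100, by = 10), 0), "ctrl")
  half <- make_track(2, cbind(seq(0, 50, by = 5), 0), "kd")
  st <- compute_stats(rbind(ctrl, half), min_span_frac = 0)
  g <- normalize_to_control(st, "ctrl")
  expect_equal(g$normalized_mean_displacement[g$condition == "ctrl"], 1.0)
  expect_equal(g$normalized_mean_displacement[g$condition == "kd"], 0.5)
  expect_error(normalize_to_control(st, "nope"), "not present")
})

test_that("knockdown factor is recovered as the normalized mean displacement", {
  p_ctrl <- trajectory_params(n_cells = 500, substrate = "aligned")
  p_kd <- trajectory_params(n_cells = 500, substrate = "aligned",
                            knockdown_factor = 0.75)
  tr <- rbind(generate_trajectories(p_ctrl, seed = 63, condition = "ctrl"),
              generate_trajectories(p_kd, seed = 64, condition = "kd"))
  st <- compute_stats(tr)
  g <- normalize_to_control(st, "ctrl")
  expect_equal(g$normalized_mean_displacement[g$condition == "kd"], 0.75,
               tolerance = 0.05 / 0.75)  # +/- 0.05 absolute
  cmp <- compare_conditions(st, "ctrl", "kd")
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$ratio, 0.75, tolerance = 0.05 / 0.75)
})

test_that("condition comparison behaves at the null and separation limits", {
  same <- generate_trajectories(trajectory_params(n_cells = 100), seed = 65)
  stA <- compute_stats(rbind(
    transform(same, condition = "A"),
    transform(same, condition = "B")))
  cmp <- compare_conditions(stA, "A", "B")
  expect_equal(cmp$ratio, 1)
  expect_gt(cmp$p_value, 0.99)
  # disjoint support: p below any conventional threshold
  fast <- do.call(rbind, lapply(1:10, function(i)
    make_track(i, cbind(seq(0, 500 + i, length.out = 11), 0), "B")))
  slow <- do.call(rbind, lapply(11:20, function(i)
    make_track(i, cbind(seq(0, 5 + i / 10, length.out = 11), 0), "A")))
  st2 <- compute_stats(rbind(fast, slow), min_span_frac = 0)
  expect_lt(compare_conditions(st2, "A", "B")$p_value, 1e-8)
  expect_lt(compare_conditions(st2, "A", "B", test = "wilcox")$p_value, 1e-4)
  expect_error(compare_conditions(st2, "A", "missing"), ">= 3 cells")
})
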