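#' Parameters for the persistent-random-walk trajectory simulator
#'
#' Emulates time-lapse tracks of fibroblasts migrating on collagen-coated
#' nanofiber substrates, imaged at fixed intervals. Each cell takes steps of
#' constant length whose headings follow a persistent random walk (von Mises
#' turning noise); on an `aligned` substrate the heading is attracted toward
#' the fiber axis (axially, so both directions along the fiber are
#' equivalent) and the turning noise is damped while the cell moves along
#' the axis (contact guidance). An siRNA knockdown is modeled as a
#' multiplicative factor on step length, which scales expected net
#' displacement by exactly that factor.
#'
#' @param n_cells number of cells (>= 1).
#' @param dt frame interval in minutes (default 8).
#' @param duration movie length in minutes (default 270, i.e. 4.5 h); the
#'   number of steps is `floor(duration / dt)`.
#' @param speed_mean step length in px per frame.
#' @param persistence directional correlation in `[0, 1)`: the mean resultant
#'   length of the per-step turning distribution (0 = uncorrelated headings,
#'   values near 1 = nearly ballistic).
#' @param substrate `"aligned"` or `"random"`.
#' @param axis fiber axis in degrees for the aligned substrate.
#' @param axis_bias strength of the axial attraction per step (radians of
#'   corrective turn at 45 degrees off-axis).
#' @param axis_damp fractional damping of turning noise when moving along
#'   the axis, in `[0, 1)`; turns are scaled by
#'   `1 - axis_damp * cos(2 * (axis - heading))`, so on-axis headings turn
#'   less and off-axis headings turn more.
#' @param knockdown_factor multiplicative displacement effect in (0, 1];
#'   1 = control.
#' @param arena `c(W, H)` px; initial positions are uniform in the arena
#'   (tracks may leave it; no walls are simulated).
#' @return an object of class `trajectory_params`.
#' @export
trajectory_params <- function(n_cells = 100, dt = 8, duration = 270,
                              speed_mean = 10, persistence = 0.7,
                              substrate = c("random", "aligned"),
                              axis = 0, axis_bias = 0.6, axis_damp = 0.5,
                              knockdown_factor = 1,
                              arena = c(1000, 1000)) {
  substrate <- match.arg(substrate)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  if (duration < dt) stop("duration must be >= dt")
  if (persistence < 0 || persistence >= 1)
    stop("persistence must be in [0, 1)")
  if (axis_damp < 0 || axis_damp >= 1)
    stop("axis_damp must be in [0, 1)")
  if (knockdown_factor <= 0 || knockdown_factor > 1)
    stop("knockdown_factor must be in (0, 1]")
  structure(list(n_cells = n_cells, dt = dt, duration = duration,
                 speed_mean = speed_mean, persistence = persistence,
                 substrate = substrate, axis = fold_axial(axis),
                 axis_bias = axis_bias, axis_damp = axis_damp,
                 knockdown_factor = knockdown_factor,
                 arena = arena),
            class = "trajectory_params")
}

#' Simulate cell trajectories
#'
#' @param params a [trajectory_params()].
#' @param seed integer seed.
#' @param well,condition labels attached to every row (condition defaults to
#'   a compact description of substrate and knockdown).
#' @return a long-format data.frame of class `trajectory_set` with columns
#'   `cell_id`, `t_min`, `x_px`, `y_px`, `well`, `condition`; each cell has
#'   `floor(duration/dt) + 1` rows with strictly increasing `t_min`.
#' @examples
#' tr <- generate_trajectories(trajectory_params(n_cells = 5), seed = 1)
#' head(tr)
#' @export
generate_trajectories <- function(params, seed, well = "w1",
                                  condition = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  if (missing(seed)) stop("seed is required")
  if (is.null(condition))
    condition <- paste0(params$substrate,
                        if (params$knockdown_factor < 1)
                          paste0("_kd", params$knockdown_factor) else "_ctrl")
  n <- params$n_cells
  n_steps <- floor(params$duration / params$dt)
  kappa_p <- if (params$persistence > 0) kappa_from_rbar(params$persistence) else 0
  step_len <- params$speed_mean * params$knockdown_factor
  axis_rad <- params$axis * pi / 180

  with_seed(seed, {
    x <- matrix(0, n, n_steps + 1)
    y <- matrix(0, n, n_steps + 1)
    x[, 1] <- stats::runif(n, 0, params$arena[1])
    y[, 1] <- stats::runif(n, 0, params$arena[2])
    heading <- stats::runif(n, -pi, pi)
    for (s in seq_len(n_steps)) {
      turn <- rvonmises(n, 0, kappa_p)
      if (params$substrate == "aligned") {
        heading <- heading +
          params$axis_bias * 0.5 * sin(2 * (axis_rad - heading))
        turn <- turn * (1 - params$axis_damp * cos(2 * (axis_rad - heading)))
      }
      heading <- heading + turn
      # y grows downward in pixel coordinates; headings are CCW from +x
      x[, s + 1] <- x[, s] + step_len * cos(heading)
      y[, s + 1] <- y[, s] - step_len * sin(heading)
    }
    out <- data.frame(
      cell_id = rep(seq_len(n), each = n_steps + 1),
      t_min = rep(seq(0, by = params$dt, length.out = n_steps + 1), n),
      x_px = as.vector(t(x)),
      y_px = as.vector(t(y)),
      well = well, condition = condition)
    class(out) <- c("trajectory_set", "data.frame")
    out
  })
}

#' Write / read trajectory tables
#'
#' @param tr a `trajectory_set` (long-format data.frame).
#' @param path CSV path.
#' @return written path / the read `trajectory_set`, invisibly for the writer.
#' @export
write_trajectories <- function(tr, path) {
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- utils::read.csv(path)
  need <- c("cell_id", "t_min", "x_px", "y_px")
  if (!all(need %in% names(out)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  class(out) <- c("trajectory_set", "data.frame")
  out
}
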