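# Shared fixture builders. Everything is generated in code at test time.

# A blank image with one solid bar of given size/orientation, drawn with the
# package renderer (the renderer itself is validated against geometry in
# test-synthetic-slide.R).
bar_image <- function(H = 120, W = 160, cx = W / 2, cy = H / 2,
                      length_px = 100, width_px = 10, theta = 30) {
  dermalign:::render_capsule(matrix(0, H, W), cx, cy, length_px, width_px, theta)
}

# Hand-built 6-gene x 6-sample toy count matrix (3 control, 3 treated) with
# exactly two planted ~4-fold genes at high counts; all other genes fail one
# named filter. Used with identity size factors so the hand values are exact.
toy_deg_matrix <- function() {
  m <- rbind(
    planted1  = c(20, 22, 18,  80, 85, 90),   # 4-fold up, high counts
    planted2  = c(30, 28, 32, 120, 130, 110), # 4-fold up, high counts
    lowcount  = c(1, 2, 1, 2, 1, 2),          # mean 1.5 <= 3
    boundary3 = c(1, 1, 1, 5, 5, 5),          # mean exactly 3.0, big FC
    flat      = c(50, 52, 48, 49, 51, 50),    # FC ~ 1
    smallfc   = c(40, 42, 38, 50, 52, 48)     # FC = 51/41 = 1.24 < 1.5
  )
  colnames(m) <- paste0("s", 1:6)
  list(counts = m, groups = rep(c("control", "treated"), each = 3),
       identity_norm = list(normalized = m, size_factors = rep(1, 6)))
}

# Two-group (saline/bleomycin) sample metrics for count simulations.
two_group_metrics <- function(n_per_group = 12, seed = 99) {
  dermalign:::with_seed(seed, {
    n <- 2 * n_per_group
    data.frame(
      sample = paste0("s", seq_len(n)),
      thickness = stats::rnorm(n, rep(c(40, 60), each = n_per_group), 4),
      alignment = stats::rnorm(n, rep(c(0.62, 0.82), each = n_per_group), 0.05),
      collagen  = stats::rnorm(n, rep(c(0.30, 0.45), each = n_per_group), 0.04))
  })
}

# Brute-force BH step-up: independent of bh_adjust's implementation.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Fresh temp directory per call
withr_like_tempdir <- function() {
  d <- tempfile("dermalign-test-")
  dir.create(d)
  d
}
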