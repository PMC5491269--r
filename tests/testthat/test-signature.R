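test_that("median-of-ratios normalization matches its definition", {
  # identical samples: size factors (1, 1)
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(normalize_counts(m)$size_factors), c(1, 1))
  # pure depth effect: B = 2A gives factors proportional to (1, 2)
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  sf <- normalize_counts(m2)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2)
  # random NB matrix: factors equal an independent brute-force computation
  set.seed(31)
  m3 <- matrix(rnbinom(200 * 8, mu = 50 * rep(exp(rnorm(8, 0, 0.3)), each = 200),
                       size = 10), 200, 8,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  ref <- exp(rowMeans(log(m3[rowSums(m3 > 0) == 8, ])))
  brute <- apply(m3[rowSums(m3 > 0) == 8, ] / ref, 2, median)
  expect_equal(normalize_counts(m3)$size_factors, brute)
  # all-zero-containing genes only: errors, advising the pseudo-reference
  m4 <- cbind(s1 = c(0, 5), s2 = c(5, 0))
  rownames(m4) <- c("g1", "g2")
  expect_error(normalize_counts(m4), "allow_pseudo")
  expect_silent(normalize_counts(m4, allow_pseudo = TRUE))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    a <- bh_adjust(p)
    expect_equal(a, bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(a, p.adjust(p, "BH"), tolerance = 1e-12)  # library cross-check
    expect_true(all(a[order(p)] == cummax(a[order(p)])))   # monotone
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG filters pass exactly the planted genes on the toy matrix", {
  toy <- toy_deg_matrix()
  tab <- call_degs(toy$counts, toy$groups, c("control", "treated"),
                   deg_criteria("mouse"), normalized = toy$identity_norm)
  expect_setequal(tab$gene[tab$pass], c("planted1", "planted2"))
  # the boundary gene sits at mean normalized count exactly 3.0 and fails
  # on the strict count inequality despite a large fold change
  brow <- tab[tab$gene == "boundary3", ]
  expect_equal(brow$mean_norm_count, 3.0)
  expect_gt(abs(brow$log2fc), log2(1.5))
  expect_false(brow$pass)
  # the identical-distribution gene has log2FC ~ 0 and fails the FC filter
  expect_lt(abs(tab$log2fc[tab$gene == "flat"]), 0.1)
  expect_false(tab$pass[tab$gene == "flat"])
  # human criteria demand counts > 4
  crit_h <- deg_criteria("human")
  expect_equal(crit_h$min_norm_count, 4)
  expect_error(call_degs(toy$counts, toy$groups, c("control", "absent")),
               "contrast")
})

test_that("per-gene metric correlation handles exact and degenerate cases", {
  metric <- c(1, 2, 3, 4, 5, 6)
  nm <- rbind(prop = 3 * metric,          # exactly proportional
              logprop = 2^(metric + 10),  # proportional after log transform
              const = rep(5, 6),          # zero variance -> r2 = 0
              noise = c(5, 1, 4, 2, 6, 3))
  colnames(nm) <- paste0("s", 1:6)
  co_lin <- correlate_to_metric(nm, metric, scale = "linear")
  expect_equal(co_lin$r2[co_lin$gene == "prop"], 1, tolerance = 1e-12)
  co <- correlate_to_metric(nm, metric)   # log2(x + 1) scale
  expect_gt(co$r2[co$gene == "logprop"], 0.999)
  expect_identical(co$r2[co$gene == "const"], 0)
  expect_error(correlate_to_metric(nm, rep(2, 6)), "constant")
  expect_error(correlate_to_metric(nm[, 1:3], metric[1:3]), ">= 4")
})

test_that("signatures are DEG-intersected, thresholded and uniquely partitioned", {
  co <- list(
    thickness = data.frame(gene = c("a", "b", "c", "d"),
                           r2 = c(0.9, 0.2, 0.8, 0.5), sign = 1),
    collagen  = data.frame(gene = c("a", "b", "c", "d"),
                           r2 = c(0.1, 0.6, 0.5, 0.2), sign = 1),
    alignment = data.frame(gene = c("a", "b", "c", "d"),
                           r2 = c(0.1, 0.5, 0.5, 0.1), sign = 1))
  # empty DEG set: all signatures empty
  s0 <- build_signatures(co, character(0))
  expect_true(all(vapply(s0, function(s) length(s$genes) == 0, logical(1))))
  sig <- build_signatures(co, deg_genes = c("a", "b", "c"))
  expect_setequal(sig$thickness$genes, c("a", "c"))
  expect_setequal(sig$collagen$genes, c("b", "c"))
  expect_setequal(sig$alignment$genes, c("b", "c"))
  # unique sets: pairwise disjoint, subset of own signature
  expect_equal(sig$thickness$unique_genes, "a")
  expect_equal(length(sig$alignment$unique_genes), 0)
  uni <- lapply(sig, `[[`, "unique_genes")
  expect_equal(anyDuplicated(unlist(uni)), 0)
  # raising a cutoff never grows the signature
  for (thr in seq(0, 1, by = 0.1)) {
    s_lo <- build_signatures(co, c("a", "b", "c", "d"),
                             c(thickness = thr, collagen = 0.4, alignment = 0.4))
    s_hi <- build_signatures(co, c("a", "b", "c", "d"),
                             c(thickness = min(thr + 0.1, 1), collagen = 0.4,
                               alignment = 0.4))
    expect_true(all(s_hi$thickness$genes %in% s_lo$thickness$genes))
  }
  expect_error(build_signatures(co, "a", c(mrss = 0.5)), "mrss")
})

test_that("planted signatures are recovered with high sensitivity and specificity", {
  metrics <- two_group_metrics(12)
  groups <- rep(c("saline", "bleo"), each = 12)
  pl <- data.frame(gene = paste0("gene", 1:60),
                   metric = rep(c("alignment", "thickness"), each = 30),
                   slope = NA_real_, noise_sd = 0.1)
  for (m in unique(pl$metric))
    pl$slope[pl$metric == m] <- slope_for_target_r2(0.8, metrics[[m]], 0.1)
  cm <- generate_counts(signature_spec(1000, pl), metrics, groups, seed = 42)
  res <- signature_workflow(cm$counts, metrics, groups, "saline")
  truth <- pl$gene[pl$metric == "alignment"]
  found <- res$signatures$alignment$genes
  sens <- length(intersect(found, truth)) / length(truth)
  spec <- 1 - length(setdiff(found, truth)) / (1000 - length(truth))
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("null matrices produce DEG rates within the alpha budget", {
  metrics <- two_group_metrics(8)
  groups <- rep(c("saline", "bleo"), each = 8)
  cm <- generate_counts(signature_spec(2000), metrics, groups, seed = 55)
  tab <- call_degs(cm$counts, groups, c("saline", "bleo"))
  expect_lte(mean(tab$pass), 0.05)
})
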