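test_that("truth tables are deterministic with exact class counts and signs", {
  t1 <- generate_truth(n_genes = 1000, seed = 1)
  t2 <- generate_truth(n_genes = 1000, seed = 1)
  expect_identical(t1, t2)
  cls <- factor(t1$class, levels = c("direct", "indirect", "orthogonal",
                                     "offtarget", "null"))
  expect_equal(as.vector(table(cls)), c(200L, 150L, 100L, 20L, 530L))

  # construction invariants per class
  d <- t1[t1$class == "direct", ]
  expect_true(all(sign(d$true_crf) == sign(d$true_itps_log2fc)))
  expect_true(all(abs(d$true_crf) > 0.1))
  i <- t1[t1$class == "indirect", ]
  expect_true(all(sign(i$true_crf) == -sign(i$true_itps_log2fc)))
  o <- t1[t1$class == "orthogonal", ]
  expect_true(all(abs(o$true_crf) <= 0.05 & o$true_itps_log2fc != 0))
  expect_true(all(t1$true_itps_log2fc[t1$class == "null"] == 0))
  expect_true(all(abs(t1$true_itps_log2fc[t1$class != "null"]) >= 1))

  expect_error(generate_truth(fractions = c(direct = 0.45, indirect = 0.2,
                                            orthogonal = 0.2, offtarget = 0.05,
                                            null = 0.1)), NA)
  expect_error(generate_truth(fractions = c(direct = 0.5, indirect = 0.2,
                                            orthogonal = 0.2, offtarget = 0.05,
                                            null = 0.2)),
               class = "crfdeconv_input_error")
})

test_that("counts are reproducible under a seed and respect the design", {
  truth <- generate_truth(n_genes = 200, seed = 2)
  c1 <- generate_counts(truth, depth = 2e5, seed = 3)
  c2 <- generate_counts(truth, depth = 2e5, seed = 3)
  expect_identical(c1$counts, c2$counts)
  expect_equal(ncol(c1$counts), 16L)
  expect_true(all(c1$samples$library_size >= colSums(c1$counts)))
  expect_error(generate_counts(truth, theta = -1),
               class = "crfdeconv_input_error")
})

test_that("theta = 0 counts are dispersed like a binomial", {
  # pooled per-gene dispersion statistic sum_i (x_i - n p)^2 / (n p (1 - p))
  # is chi-square with (reps - 1) df per gene under binomial sampling
  set.seed(4)
  truth <- generate_truth(n_genes = 1000,
                          fractions = c(direct = 0, indirect = 0, orthogonal = 0,
                                        offtarget = 0, null = 1))
  cm <- generate_counts(truth, design = default_design(4, "4h"),
                        depth = 2e5, theta = 0)
  idx <- which(cm$samples$genotype == "iTPS" & cm$samples$treatment == "water")
  X <- cm$counts[, idx]
  n <- cm$samples$library_size[idx]
  P <- sweep(X, 2, n, "/")
  phat <- rowSums(X) / sum(n)
  keep <- phat > 0
  disp <- rowSums((P[keep, ] - phat[keep])^2) /
    (phat[keep] * (1 - phat[keep]) * mean(1 / n))
  stat <- sum(disp)
  df <- sum(keep) * (length(idx) - 1)
  p <- 2 * min(stats::pchisq(stat, df), stats::pchisq(stat, df, lower.tail = FALSE))
  expect_gt(p, 0.01)
})

test_that("null genes rarely pass the strict filter", {
  set.seed(5)
  truth <- generate_truth(n_genes = 1500,
                          fractions = c(direct = 0, indirect = 0, orthogonal = 0,
                                        offtarget = 0, null = 1))
  cm <- generate_counts(truth)
  ct <- run_contrast(cm, generate_gene_lengths(truth),
                     list(genotype = "iTPS", treatment = "ethanol"),
                     list(genotype = "iTPS", treatment = "water"))
  expect_lte(mean(ct$passes_strict), 0.07)
})

test_that("doubling depth shrinks proportion standard errors binomially", {
  set.seed(6)
  truth <- generate_truth(n_genes = 400,
                          fractions = c(direct = 0, indirect = 0, orthogonal = 0,
                                        offtarget = 0, null = 1))
  med_se <- function(depth) {
    d <- default_design(30, "4h")
    d <- d[d$genotype == "iTPS" & d$treatment == "water", ]
    cm <- generate_counts(truth, design = d, depth = depth)
    P <- sweep(cm$counts, 2, cm$samples$library_size, "/")
    stats::median(apply(P, 1, stats::sd))
  }
  ratio <- med_se(2e5) / med_se(1e5)
  expect_gte(ratio, 0.6)
  expect_lte(ratio, 0.85)
})

test_that("a clean panel reproduces the planted CRF and missingness is calibrated", {
  truth <- generate_truth(n_genes = 500, seed = 7)
  clean <- generate_panel(truth, noise_sd = 0, missing_rate = 0)
  r <- compute_crf(clean)
  noctx <- !truth$context_dependent
  expect_equal(r$crf[noctx], truth$true_crf[noctx], tolerance = 1e-12)
  # context rows also average back to the planted CRF by construction
  expect_equal(r$crf, truth$true_crf, tolerance = 1e-12)

  miss <- generate_panel(truth, noise_sd = 0.15, missing_rate = 0.3, seed = 8)
  n_obs <- rowSums(!is.na(miss))
  expect_lt(abs(mean(n_obs) - 0.7 * 9), 0.2)

  # context-dependent genes show opposing responses at half the effect scale
  ctx <- truth$context_dependent
  flags <- flag_context_dependent(generate_panel(truth, seed = 9)[ctx, , drop = FALSE],
                                  thr = 0.5)
  expect_gte(mean(flags), 0.95)
  expect_error(generate_panel(truth, missing_rate = 1),
               class = "crfdeconv_input_error")
})

test_that("a noise-free reciprocal signature gives G1 slope exactly -1 on truth groups", {
  truth <- generate_truth(n_genes = 600, seed = 10)
  ext <- generate_external(truth, "reciprocal", noise_sd = 0, seed = 11)
  ct <- truth_contrast(truth)
  groups <- assign_group(ct, data.frame(gene_id = truth$gene_id,
                                        crf = truth$true_crf, n_obs = 9L))
  r <- per_group_comparison(ct, ext, groups)
  g1 <- r[r$set == "G1", ]
  expect_equal(g1$slope, -1)
  expect_equal(g1$r_squared, 1)
  g2 <- r[r$set == "G2", ]
  expect_equal(g2$slope, 1)
  expect_error(generate_external(truth, "sideways"))
})

test_that("mixed-mode concordance proportions track the planted split", {
  truth <- generate_truth(n_genes = 4000, seed = 12)
  ext <- generate_external(truth, "mixed", noise_sd = 0.05,
                           prop_opposite = 0.75, seed = 13)
  resp <- truth$class %in% c("direct", "indirect", "orthogonal")
  sc <- sign_concordance(
    stats::setNames(truth$true_itps_log2fc, truth$gene_id)[resp],
    ext[truth$gene_id[resp]])
  expect_lt(abs(sc$n_opposite / (sc$n_same + sc$n_opposite) - 0.75), 0.03)
})
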