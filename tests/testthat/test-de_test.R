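test_that("RPKM follows the formula with unit scalers and preserves zeros", {
  m <- matrix(c(10, 0, 50), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  m <- cbind(m, s2 = c(10, 0, 50))
  sheet <- data.frame(sample_id = c("s1", "s2"), genotype = "iTPS",
                      treatment = c("ethanol", "water"), timepoint = "4h",
                      replicate = 1, library_size = c(1e6, 2e7))
  cm <- count_matrix(m, sheet)
  lengths <- c(G1 = 1000, G2 = 500, G3 = 2500)
  r <- compute_rpkm(cm, lengths)
  expect_equal(r["G1", "s1"], 10)           # 10 reads, 1 kb, 1e6 library
  expect_equal(r["G2", "s1"], 0)
  expect_equal(r["G3", "s2"], 1.0)          # 50e9 / (2500 * 2e7)
  expect_error(compute_rpkm(cm, c(G1 = 1000, G2 = 0, G3 = 2500)),
               "G2", class = "crfdeconv_input_error")
})

test_that("RPKM is linear in counts, gene by gene", {
  set.seed(41)
  m <- matrix(rpois(40, 50), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  sheet <- data.frame(sample_id = sprintf("s%d", 1:4), genotype = "iTPS",
                      treatment = rep(c("ethanol", "water"), each = 2),
                      timepoint = "4h", replicate = c(1, 2, 1, 2),
                      library_size = 1e6)
  lengths <- stats::setNames(sample(500:3000, 10), toupper(rownames(m)))
  r1 <- compute_rpkm(count_matrix(m, sheet), lengths)
  m2 <- m; m2[3, ] <- m[3, ] * 7
  r2 <- compute_rpkm(count_matrix(m2, sheet), lengths)
  expect_equal(r2[3, ], r1[3, ] * 7)
  expect_equal(r2[-3, ], r1[-3, ])
})

test_that("group proportion fits match hand calculations and clamp at zero", {
  # identical replicates: symmetric weights, p_hat = x/n
  f <- fit_group_proportions(c(30, 30), c(1000, 1000))
  expect_equal(f$weights, c(0.5, 0.5))
  expect_equal(f$p_hat, 0.03)

  # equal proportions leave zero excess variance -> theta clamped to 0
  f2 <- fit_group_proportions(c(30, 60), c(1000, 2000))
  expect_equal(f2$p_hat, 0.03)
  expect_equal(f2$theta_hat, 0)
  # brute-force moments check: var of (0.03, 0.03) is 0 < binomial term
  p_i <- c(30/1000, 60/2000)
  expect_true(stats::var(p_i) <= f2$p_pooled * (1 - f2$p_pooled) *
                mean(1 / c(1000, 2000)))

  # under-dispersed replicates also clamp
  f3 <- fit_group_proportions(c(50, 50, 50, 50), rep(1000, 4))
  expect_equal(f3$theta_hat, 0)

  # overdispersed replicates: theta equals the moments excess
  x <- c(10, 90); n <- c(1000, 1000)
  f4 <- fit_group_proportions(x, n)
  pb <- sum(x) / sum(n)
  expect_equal(f4$theta_hat,
               stats::var(x / n) / (pb * (1 - pb)) - mean(1 / n))
  expect_true(f4$var_hat >= 0)
  expect_equal(sum(f4$weights), 1)
})

test_that("the weighted t-type statistic is antisymmetric and null at equality", {
  a <- list(x = c(30, 45, 38), n = c(1e5, 1.2e5, 9e4))
  b <- list(x = c(60, 50, 40), n = c(1.1e5, 1e5, 9.5e4))
  r1 <- weighted_t_test(a$x, a$n, b$x, b$n)
  r2 <- weighted_t_test(b$x, b$n, a$x, a$n)
  expect_equal(r1$stat, -r2$stat)
  expect_equal(r1$p_value, r2$p_value)

  same <- weighted_t_test(a$x, a$n, a$x, a$n)
  expect_equal(same$stat, 0)
  expect_equal(same$p_value, 1)

  # all-zero gene is untestable
  z <- weighted_t_test(c(0, 0), c(1e5, 1e5), c(0, 0), c(1e5, 1e5))
  expect_equal(z$stat, 0)
  expect_equal(z$p_value, 1)
})

test_that("bh_fdr equals brute-force BH on hand and random inputs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "crfdeconv_input_error")

  set.seed(99)
  for (i in 1:25) {
    p <- stats::runif(sample(5:200, 1))
    expect_lt(max(abs(bh_fdr(p) - brute_bh(p))), 1e-12)
  }
  # order preservation under permutation
  p <- stats::runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("a full contrast flags planted 4-fold genes and controls false calls", {
  set.seed(5)
  truth <- generate_truth(n_genes = 2000,
                          fractions = c(direct = 0.05, indirect = 0, orthogonal = 0,
                                        offtarget = 0, null = 0.95))
  direct <- truth$class == "direct"
  truth$true_itps_log2fc[direct] <- 2 * sign(truth$true_itps_log2fc[direct])
  cm <- generate_counts(truth, design = default_design(4, "4h"))
  lens <- generate_gene_lengths(truth)
  # explicit pseudocount: a fixed RPKM detection floor, so the check probes
  # detection power rather than fold-change compression at the fixture's
  # (narrow) abundance range
  ct <- run_contrast(cm, lens,
                     list(genotype = "iTPS", treatment = "ethanol"),
                     list(genotype = "iTPS", treatment = "water"),
                     pseudocount = 0.5)
  planted <- toupper(truth$gene_id[truth$class == "direct"])
  strict <- ct$gene_id[ct$passes_strict]
  expect_gte(sum(planted %in% strict), 0.90 * length(planted))
  nulls <- toupper(truth$gene_id[truth$class == "null"])
  expect_lte(sum(strict %in% nulls) / max(1, length(strict)), 0.10)
  # strict implies relaxed everywhere
  expect_true(all(ct$passes_relaxed[ct$passes_strict]))
  # fold-change sign matches the mean difference when both means positive
  pos <- ct$mean_treated > 0 & ct$mean_control > 0 & ct$log2_fc != 0
  expect_true(all(sign(ct$log2_fc[pos]) ==
                    sign(ct$mean_treated[pos] - ct$mean_control[pos])))
})

test_that("strict call rate grows with the planted effect size", {
  rates <- vapply(c(0.5, 1, 2), function(es) {
    set.seed(17)
    truth <- generate_truth(n_genes = 600,
                            fractions = c(direct = 0.5, indirect = 0, orthogonal = 0,
                                          offtarget = 0, null = 0.5),
                            effect_scale = es)
    # fix all planted magnitudes at exactly the scale for a clean ordering
    truth$true_itps_log2fc[truth$class == "direct"] <-
      es * sign(truth$true_itps_log2fc[truth$class == "direct"])
    cm <- generate_counts(truth, seed = 23)
    ct <- run_contrast(cm, generate_gene_lengths(truth, seed = 29),
                       list(treatment = "ethanol", genotype = "iTPS"),
                       list(treatment = "water", genotype = "iTPS"))
    mean(ct$passes_strict[ct$gene_id %in% toupper(truth$gene_id[truth$class == "direct"])])
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("identical cells yield a flat contrast and selectors validate", {
  cm <- toy_count_matrix()
  lens <- c(G1 = 1000, G2 = 800, G3 = 1200)
  expect_error(run_contrast(cm, lens,
                            list(genotype = "alcR", treatment = "ethanol"),
                            list(genotype = "iTPS", treatment = "water")),
               "alcR", class = "crfdeconv_input_error")
  # same cell against itself: every gene flat
  ct <- run_contrast(cm, lens,
                     list(treatment = "ethanol"), list(treatment = "ethanol"))
  expect_true(all(ct$log2_fc == 0))
  expect_true(all(ct$p_value == 1))
  expect_false(any(ct$passes_relaxed))
})
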