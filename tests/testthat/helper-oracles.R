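# Independent oracles and small fixture builders used across the suite.

# brute-force Benjamini-Hochberg: sort, scale, cumulative minimum
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force per-BIN mean over an expanded (code, gene) map, ancestors
# included, zeros kept, NA for unpopulated bins
brute_bin_means <- function(display_fc, binmap, subset = NULL) {
  genes <- names(display_fc)
  if (!is.null(subset)) genes <- intersect(genes, subset)
  anc <- function(code) {
    parts <- strsplit(code, ".", fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(i) paste(parts[1:i], collapse = "."), "")
  }
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(binmap)), function(i)
    data.frame(code = anc(binmap$bincode[i]), gene = binmap$gene_id[i],
               stringsAsFactors = FALSE))))
  codes <- unique(pairs$code)
  vals <- vapply(codes, function(cd) {
    members <- intersect(unique(pairs$gene[pairs$code == cd]), genes)
    if (length(members) == 0) NA_real_ else mean(display_fc[members])
  }, numeric(1))
  stats::setNames(vals, codes)
}

# exhaustive sign-concordance counts by direct enumeration
enum_concordance <- function(a, b) {
  n_same <- 0L; n_opp <- 0L; n_zero <- 0L
  for (i in seq_along(a)) {
    sa <- sign(a[i]); sb <- sign(b[i])
    if (sa == 0 || sb == 0) n_zero <- n_zero + 1L
    else if (sa == sb) n_same <- n_same + 1L
    else n_opp <- n_opp + 1L
  }
  list(n_same = n_same, n_opposite = n_opp, n_zero = n_zero)
}

# tiny hand-built count matrix: 3 genes x 4 samples (2 cells x 2 reps)
toy_count_matrix <- function() {
  m <- matrix(c(10, 20, 30, 40,
                0,  5,  5, 10,
                100, 90, 110, 95), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  sheet <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    genotype = "iTPS",
    treatment = c("ethanol", "ethanol", "water", "water"),
    timepoint = "4h",
    replicate = c(1, 2, 1, 2),
    library_size = c(1e6, 1e6, 1e6, 1e6),
    stringsAsFactors = FALSE)
  count_matrix(m, sheet)
}

# contrast_result assembled by hand for unit tests of downstream stages
make_contrast <- function(gene_id, log2_fc, q, fdr = 0.05,
                          lfc_strict = 1, lfc_relaxed = 0.2) {
  res <- data.frame(gene_id = toupper(gene_id),
                    mean_treated = NA_real_, mean_control = NA_real_,
                    log2_fc = log2_fc, stat = 0, p_value = q, q_value = q,
                    testable = TRUE,
                    passes_strict = q < fdr & abs(log2_fc) >= lfc_strict,
                    passes_relaxed = q < fdr & abs(log2_fc) >= lfc_relaxed,
                    stringsAsFactors = FALSE)
  attr(res, "thresholds") <- c(fdr = fdr, lfc_strict = lfc_strict,
                               lfc_relaxed = lfc_relaxed)
  class(res) <- c("contrast_result", "data.frame")
  res
}
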