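# Synthetic data with planted ground truth.  The generator emulates the
# induction experiment: iTPS and alcR (empty-vector) plants sprayed with
# ethanol or water, replicated beta-binomially overdispersed RNA-seq
# counts, a reference sugar-response panel feeding the CRF, a MapMan-style
# BIN mapping with class-enriched categories, and external response
# signatures (e.g. reciprocal SnRK1-like).  Every stage is deterministic
# under a fixed seed.

.CLASSES <- c("direct", "indirect", "orthogonal", "offtarget", "null")

.default_fractions <- c(direct = 0.20, indirect = 0.15, orthogonal = 0.10,
                        offtarget = 0.02, null = 0.53)

#' Generate the planted truth table
#'
#' Plants per-gene classes and effects: \code{direct} genes respond to
#' induction with the same sign as their (sugar-responsive) CRF,
#' \code{indirect} genes with the opposite sign, \code{orthogonal} genes
#' respond to induction but have near-zero CRF, \code{offtarget} genes
#' respond to ethanol in both iTPS and alcR lines, and \code{null} genes do
#' not respond.  Class counts follow \code{round(fraction * n_genes)} for
#' the first four classes, the remainder is null.  Induction effect
#' magnitudes are \code{effect_scale * (1 + Exp(1))} truncated at
#' \code{3.5 * effect_scale} (at least \code{effect_scale}, mean about
#' twice it; the truncation keeps any single gene from dominating a
#' library) with random sign; off-target magnitudes span
#' \code{[3, 4] * effect_scale} so that shared-DEG flagging is
#' power-limited rather than threshold-ambiguous.  CRF
#' magnitudes for sugar-responsive classes are
#' \code{crf_scale * U(0.8, 1.2)}; orthogonal genes get
#' \code{U(-0.05, 0.05)}.  A fraction of the sugar-responsive genes is
#' flagged context-dependent and receives a mixed-sign panel row whose mean
#' still equals the planted CRF.  Each class is enriched in a designated
#' top-level BIN.
#'
#' @param n_genes number of genes.
#' @param fractions named proportions for classes \code{direct},
#'   \code{indirect}, \code{orthogonal}, \code{offtarget}, \code{null};
#'   must sum to 1.
#' @param effect_scale minimum planted |log2 FC| (log2 units, default 1).
#' @param crf_scale typical planted |CRF| for sugar-responsive classes
#'   (default 0.5).
#' @param k_contrasts number of reference panel contrasts (default 9).
#' @param context_fraction fraction of sugar-responsive genes with
#'   context-dependent (mixed-sign) panel rows (default 0.1).
#' @param seed optional RNG seed.
#' @return data frame of class \code{truth_table} with columns
#'   \code{gene_id}, \code{class}, \code{true_itps_log2fc},
#'   \code{true_crf}, \code{context_dependent}, \code{bins}
#'   (comma-separated BIN codes); the noise-free panel rows are stored in
#'   \code{attr(, "true_panel")}.
#' @export
generate_truth <- function(n_genes = 2000L,
                           fractions = .default_fractions,
                           effect_scale = 1, crf_scale = 0.5,
                           k_contrasts = 9L, context_fraction = 0.1,
                           seed = NULL) {
  .set_seed(seed)
  if (is.null(names(fractions))) names(fractions) <- .CLASSES
  if (!setequal(names(fractions), .CLASSES))
    stop_input("fractions must be named with: %s", paste(.CLASSES, collapse = ", "))
  fractions <- fractions[.CLASSES]
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_input("fractions must sum to 1 (got %.12g)", sum(fractions))
  counts <- round(fractions[1:4] * n_genes)
  counts <- c(counts, null = n_genes - sum(counts))
  cls <- rep(.CLASSES, counts)

  gene_id <- sprintf("ATSYN%05d", seq_len(n_genes))
  responsive <- cls %in% c("direct", "indirect", "orthogonal")
  itps <- numeric(n_genes)
  sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
  itps[responsive] <- sgn[responsive] *
    effect_scale * (1 + pmin(stats::rexp(sum(responsive), 1), 2.5))
  off <- cls == "offtarget"
  itps[off] <- sgn[off] * effect_scale * (3 + pmin(stats::rexp(sum(off), 1), 1))

  crf <- numeric(n_genes)
  mag <- crf_scale * stats::runif(n_genes, 0.8, 1.2)
  crf[cls == "direct"] <- sign(itps[cls == "direct"]) * mag[cls == "direct"]
  crf[cls == "indirect"] <- -sign(itps[cls == "indirect"]) * mag[cls == "indirect"]
  crf[cls == "orthogonal"] <- stats::runif(sum(cls == "orthogonal"), -0.05, 0.05)

  sugar <- cls %in% c("direct", "indirect")
  ctx <- rep(FALSE, n_genes)
  n_ctx <- round(context_fraction * sum(sugar))
  if (n_ctx > 0) ctx[sample(which(sugar), n_ctx)] <- TRUE

  # noise-free panel rows: constant at the CRF, except context-dependent
  # genes which mix signs while keeping the row mean equal to the CRF
  K <- as.integer(k_contrasts)
  panel <- matrix(rep(crf, K), ncol = K,
                  dimnames = list(gene_id, sprintf("C%d", seq_len(K))))
  n_opp <- max(1L, K %/% 3L)
  for (g in which(ctx)) {
    opp_val <- -sign(crf[g]) * 2 * abs(crf[g])
    main_val <- (K * crf[g] - n_opp * opp_val) / (K - n_opp)
    row <- rep(main_val, K)
    row[sample(K, n_opp)] <- opp_val
    panel[g, ] <- row
  }

  # BIN assignment: each class has a home top-level category; genes land in
  # a random sub-BIN of their home with prob 0.7, otherwise anywhere; ~20%
  # carry a second mapping (MapMan allows multiple)
  home <- c(direct = 1L, indirect = 2L, orthogonal = 3L, offtarget = 4L,
            null = 5L)[cls]
  top <- ifelse(stats::runif(n_genes) < 0.7, home,
                sample(1:8, n_genes, replace = TRUE))
  bins <- sprintf("%d.%d", top, sample(1:3, n_genes, replace = TRUE))
  second <- stats::runif(n_genes) < 0.2
  bins[second] <- paste(bins[second],
                        sprintf("%d.%d", sample(1:8, sum(second), TRUE),
                                sample(1:3, sum(second), TRUE)), sep = ",")

  out <- data.frame(gene_id = gene_id, class = cls,
                    true_itps_log2fc = itps, true_crf = crf,
                    context_dependent = ctx, bins = bins,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "true_panel") <- panel
  attr(out, "effect_scale") <- effect_scale
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Default experimental design for the simulator
#'
#' iTPS and alcR genotypes, ethanol and water sprays, one timepoint,
#' \code{n_reps} replicates per cell.
#' @param n_reps replicates per cell (default 4).
#' @param timepoints timepoint labels (default "4h").
#' @return design data frame with sample_id, genotype, treatment,
#'   timepoint, replicate.
#' @export
default_design <- function(n_reps = 4L, timepoints = "4h") {
  d <- expand.grid(replicate = seq_len(n_reps), timepoint = timepoints,
                   treatment = c("ethanol", "water"),
                   genotype = c("iTPS", "alcR"),
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$genotype, d$treatment,
                         d$timepoint, d$replicate)
  d[, c("sample_id", "genotype", "treatment", "timepoint", "replicate")]
}

.rbetabinom <- function(m, size, p, theta) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (theta <= 0) return(stats::rbinom(m, size, p))
  ab <- 1 / theta - 1
  stats::rbinom(m, size, stats::rbeta(m, p * ab, (1 - p) * ab))
}

#' Simulate the replicated count matrix from a truth table
#'
#' Baseline relative abundances are log-normal; a gene's planted induction
#' effect shifts its proportion in the ethanol-sprayed iTPS cell (and, for
#' off-target genes, also in the ethanol-sprayed alcR cell).  Replicate
#' counts are beta-binomial: the replicate's proportion is Beta-distributed
#' around the cell proportion with intraclass correlation \code{theta}, and
#' counts are binomial given that proportion and the library size.  Library
#' sizes vary uniformly within 20 percent of \code{depth}.
#'
#' @param truth a \code{truth_table} from [generate_truth()].
#' @param design design data frame (see [default_design()]).
#' @param depth mean library size (default 5e6).
#' @param theta beta-binomial overdispersion, >= 0 (default 1e-6,
#'   i.e. roughly 10 percent between-replicate CV at the median gene).
#' @param sdlog log-normal spread of baseline abundances (default 1).
#' @param seed optional RNG seed.
#' @return a \code{\link{count_matrix}}.
#' @export
generate_counts <- function(truth, design = default_design(),
                            depth = 5e6, theta = 1e-6, sdlog = 1,
                            seed = NULL) {
  .set_seed(seed)
  if (theta < 0) stop_input("theta must be >= 0")
  n <- nrow(truth)
  base <- stats::rlnorm(n, 0, sdlog)
  # off-target (AlcR-regulon) genes are detectably expressed: their baseline
  # abundance is drawn from the upper half of the log-normal
  is_off <- truth$class == "offtarget"
  base[is_off] <- exp(abs(stats::rnorm(sum(is_off), 0, sdlog)))
  p0 <- 0.5 * base / sum(base)   # headroom: induced columns must stay below
                                 # the library size even after planted shifts
  libs <- round(depth * stats::runif(nrow(design), 0.8, 1.2))

  responds <- matrix(0, n, nrow(design))
  for (j in seq_len(nrow(design))) {
    if (design$treatment[j] != "ethanol") next
    if (design$genotype[j] == "iTPS") {
      responds[, j] <- truth$true_itps_log2fc
    } else {
      responds[is_off, j] <- truth$true_itps_log2fc[is_off]
    }
  }
  X <- matrix(0, n, nrow(design),
              dimnames = list(truth$gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    pj <- p0 * 2^responds[, j]
    X[, j] <- .rbetabinom(n, libs[j], pj, theta)
  }
  samples <- design
  samples$library_size <- pmax(libs, colSums(X))
  count_matrix(X, samples)
}

#' Simulate gene lengths (uniform 400-4000 bp)
#' @param truth a \code{truth_table} (or character vector of gene ids).
#' @param seed optional RNG seed.
#' @return named vector of lengths in bp.
#' @export
generate_gene_lengths <- function(truth, seed = NULL) {
  .set_seed(seed)
  ids <- if (is.data.frame(truth)) truth$gene_id else as.character(truth)
  stats::setNames(sample(400:4000, length(ids), replace = TRUE), ids)
}

#' Simulate the reference sugar-response panel
#'
#' Adds Gaussian noise to the truth table's noise-free panel rows and
#' blanks cells at \code{missing_rate} (missing means "not measured", never
#' zero).
#'
#' @param truth a \code{truth_table}.
#' @param noise_sd per-cell log2 noise (default 0.2).
#' @param missing_rate probability a cell is unobserved (default 0.1).
#' @param seed optional RNG seed.
#' @return numeric matrix (genes x contrasts) with \code{NA}s.
#' @export
generate_panel <- function(truth, noise_sd = 0.2, missing_rate = 0.1,
                           seed = NULL) {
  .set_seed(seed)
  if (missing_rate < 0 || missing_rate >= 1)
    stop_input("missing_rate must be in [0, 1)")
  panel <- attr(truth, "true_panel")
  if (is.null(panel)) stop_input("truth lacks the true_panel attribute")
  noisy <- panel + stats::rnorm(length(panel), 0, noise_sd)
  noisy[matrix(stats::runif(length(panel)) < missing_rate,
               nrow(panel), ncol(panel))] <- NA_real_
  noisy
}

#' Simulate an external response signature
#'
#' \code{reciprocal} plants the structure expected of a SnRK1-like
#' signature opposed by the induction: \code{-true_itps_log2fc} for direct
#' genes, \code{+true_itps_log2fc} for indirect genes, pure noise
#' elsewhere.  \code{concordant} flips those signs.  \code{mixed} makes
#' each responsive gene opposite with probability \code{prop_opposite} and
#' concordant otherwise.  Gaussian noise (\code{noise_sd}) is added
#' throughout.
#'
#' @param truth a \code{truth_table}.
#' @param mode \code{"reciprocal"}, \code{"concordant"} or \code{"mixed"}.
#' @param noise_sd log2 noise (default 0.3).
#' @param prop_opposite opposite-response probability in mixed mode
#'   (default 0.75).
#' @param seed optional RNG seed.
#' @return named numeric vector of external log2 fold changes.
#' @export
generate_external <- function(truth,
                              mode = c("reciprocal", "concordant", "mixed"),
                              noise_sd = 0.3, prop_opposite = 0.75,
                              seed = NULL) {
  mode <- match.arg(mode)
  .set_seed(seed)
  n <- nrow(truth)
  base <- numeric(n)
  direct <- truth$class == "direct"
  indirect <- truth$class == "indirect"
  responsive <- truth$class %in% c("direct", "indirect", "orthogonal")
  if (mode == "reciprocal") {
    base[direct] <- -truth$true_itps_log2fc[direct]
    base[indirect] <- truth$true_itps_log2fc[indirect]
  } else if (mode == "concordant") {
    base[direct] <- truth$true_itps_log2fc[direct]
    base[indirect] <- -truth$true_itps_log2fc[indirect]
  } else {
    flip <- ifelse(stats::runif(n) < prop_opposite, -1, 1)
    base[responsive] <- (flip * truth$true_itps_log2fc)[responsive]
  }
  ext <- base + stats::rnorm(n, 0, noise_sd)
  stats::setNames(ext, truth$gene_id)
}

#' Noise-free contrast table built directly from the truth
#'
#' Useful as the idealized limit in structural checks: the log2 FC is the
#' planted effect, responsive genes get q = 0 and null genes q = 1, flags
#' follow the default thresholds.
#'
#' @param truth a \code{truth_table}.
#' @param fdr,lfc_strict,lfc_relaxed thresholds for the flags.
#' @return a \code{contrast_result} data frame.
#' @export
truth_contrast <- function(truth, fdr = 0.05, lfc_strict = 1,
                           lfc_relaxed = 0.2) {
  fc <- truth$true_itps_log2fc
  responds <- fc != 0
  p <- ifelse(responds, 0, 1)
  res <- data.frame(gene_id = truth$gene_id,
                    mean_treated = NA_real_, mean_control = NA_real_,
                    log2_fc = fc, stat = ifelse(responds, Inf * sign(fc), 0),
                    p_value = p, q_value = p, testable = TRUE,
                    passes_strict = responds & abs(fc) >= lfc_strict,
                    passes_relaxed = responds & abs(fc) >= lfc_relaxed,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "thresholds") <- c(fdr = fdr, lfc_strict = lfc_strict,
                               lfc_relaxed = lfc_relaxed)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Extract the BIN mapping planted in a truth table
#' @param truth a \code{truth_table}.
#' @return data frame with columns \code{bincode}, \code{name},
#'   \code{gene_id} (one row per gene-category pair).
#' @export
truth_binmap <- function(truth) {
  codes <- strsplit(truth$bins, ",", fixed = TRUE)
  out <- data.frame(bincode = unlist(codes),
                    gene_id = rep(truth$gene_id, lengths(codes)),
                    stringsAsFactors = FALSE)
  tops <- c("photosynthesis-like", "nutrient-assimilation-like",
            "mixed-regulation", "transgene-offtarget", "housekeeping-a",
            "housekeeping-b", "housekeeping-c", "housekeeping-d")
  out$name <- paste0(tops[as.integer(sub("\\..*$", "", out$bincode))],
                     " / sub", sub("^[0-9]+\\.", "", out$bincode))
  unique(out[, c("bincode", "name", "gene_id")])
}

#' Independent replicate-group draws for null calibration of the test
#'
#' Generates \code{n_genes} independent two-group problems with no
#' treatment effect: each gene gets one proportion shared by both groups
#' and beta-binomial replicate counts at overdispersion \code{theta}.
#' Proportions are drawn log-uniformly so that the Beta shape parameter
#' \code{p / theta} spans \code{shape_range}; with the default range the
#' implied between-replicate CV, \code{sqrt(theta / p)}, spans the 13-32
#' percent band typical of biological replicates.  (At much smaller shapes
#' the replicate distribution is extremely skewed and the t reference is
#' conservative; see the package vignette.)
#'
#' @param n_genes number of independent null genes.
#' @param reps replicates per group, length-2 integer (default c(4, 4)).
#' @param theta beta-binomial overdispersion (default 0.005).
#' @param depth library size per replicate (default 5e4).
#' @param shape_range range of \code{p / theta} (default c(10, 60)).
#' @param seed optional RNG seed.
#' @return list with count matrices \code{XA}, \code{XB}, library sizes
#'   \code{nA}, \code{nB} and the true proportions \code{p}.
#' @export
simulate_null_calibration <- function(n_genes = 10000L, reps = c(4L, 4L),
                                      theta = 0.005, depth = 5e4,
                                      shape_range = c(10, 60), seed = NULL) {
  .set_seed(seed)
  p <- theta * exp(stats::runif(n_genes, log(shape_range[1L]),
                                log(shape_range[2L])))
  nA <- rep(depth, reps[1L]); nB <- rep(depth, reps[2L])
  XA <- vapply(seq_len(reps[1L]),
               function(i) .rbetabinom(n_genes, depth, p, theta),
               numeric(n_genes))
  XB <- vapply(seq_len(reps[2L]),
               function(i) .rbetabinom(n_genes, depth, p, theta),
               numeric(n_genes))
  list(XA = XA, XB = XB, nA = nA, nB = nB, p = p)
}

#' Generate the complete synthetic dataset
#'
#' Chains [generate_truth()], [generate_counts()], [generate_gene_lengths()],
#' [generate_panel()], [truth_binmap()] and [generate_external()] under one
#' seed, optionally writing all tables as TSV (counts.tsv, samples.tsv,
#' lengths.tsv, panel.tsv, binmap.tsv, external.tsv, truth.tsv).
#'
#' @param config configuration list, see [default_config()].
#' @param outdir optional output directory.
#' @return list with elements \code{truth}, \code{counts}, \code{lengths},
#'   \code{panel}, \code{binmap}, \code{external}.
#' @export
simulate_dataset <- function(config = default_config(), outdir = NULL) {
  .set_seed(config$seed)
  truth <- generate_truth(n_genes = config$n_genes,
                          fractions = config$fractions,
                          effect_scale = config$effect_scale,
                          crf_scale = config$crf_scale,
                          k_contrasts = config$k_contrasts,
                          context_fraction = config$context_fraction)
  counts <- generate_counts(truth, design = default_design(config$n_reps,
                                                           config$timepoint),
                            depth = config$depth, theta = config$theta,
                            sdlog = config$sdlog)
  lengths <- generate_gene_lengths(truth)
  panel <- generate_panel(truth, noise_sd = config$panel_noise_sd,
                          missing_rate = config$missing_rate)
  binmap <- truth_binmap(truth)
  external <- generate_external(truth, mode = config$external_mode,
                                noise_sd = config$external_noise_sd,
                                prop_opposite = config$prop_opposite)
  out <- list(truth = truth, counts = counts, lengths = lengths,
              panel = panel, binmap = binmap, external = external)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) write_table(x, file.path(outdir, f))
    w(counts$counts, "counts.tsv")
    w(counts$samples, "samples.tsv")
    w(data.frame(gene_id = names(lengths), length = unname(lengths)),
      "lengths.tsv")
    w(panel, "panel.tsv")
    w(binmap, "binmap.tsv")
    w(data.frame(gene_id = names(external), log2_fc = unname(external)),
      "external.tsv")
    tt <- as.data.frame(truth)
    tt$external_log2fc <- unname(external)
    w(tt, "truth.tsv")
  }
  out
}
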