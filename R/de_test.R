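# RPKM normalization and the weighted proportions t-type differential
# expression test.  The test compares, gene by gene, the proportion of each
# library's mapped reads assigned to the gene between two replicate groups
# (ethanol- vs water-sprayed).  Between-replicate overdispersion of the
# proportions is modelled beta-binomially: var(p_i) = p(1-p)(1/n_i + theta),
# with theta estimated per gene by the method of moments.  Replicates are
# combined with inverse-variance weights and the difference of the weighted
# group proportions is referred to a t distribution with Welch-Satterthwaite
# degrees of freedom.

#' RPKM expression values
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \code{rpkm = count * 1e9 / (length * library_size)}.  Zero counts map to
#' zero RPKM.
#'
#' @param counts a \code{\link{count_matrix}} object.
#' @param lengths named numeric vector of transcript lengths in bp, covering
#'   every gene in \code{counts}.
#' @return numeric matrix (genes x samples) of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "CountMatrix"))
  genes <- rownames(counts$counts)
  miss <- setdiff(genes, names(lengths))
  if (length(miss))
    stop_input("gene length missing for: %s",
               paste(utils::head(miss, 5L), collapse = ", "))
  len <- lengths[genes]
  if (any(!is.finite(len) | len <= 0))
    stop_input("gene length must be positive (offending gene: %s)",
               genes[which(!is.finite(len) | len <= 0)[1L]])
  libs <- counts$samples$library_size
  if (any(libs <= 0)) stop_input("library sizes must be positive")
  counts$counts * 1e9 / outer(len, libs)
}

# Vectorized group fit: X is genes x replicates counts, n replicate library
# sizes.  Returns per-gene pooled proportion, theta, weighted estimate and
# its variance.  The inverse-variance weights 1/(p(1-p)(1/n_i + theta))
# share the p(1-p) factor within a gene, so normalized weights reduce to
# 1/(1/n_i + theta) scaled to sum to one.
.fit_props <- function(X, n) {
  X <- as.matrix(X)
  r <- ncol(X)
  if (r < 2L) stop_input("at least 2 replicates required")
  if (length(n) != r) stop_input("one library size per replicate required")
  if (any(n <= 0)) stop_input("library sizes must be positive")
  P <- sweep(X, 2L, n, "/")
  pbar <- as.vector(X %*% rep(1, r)) / sum(n)
  denom <- pbar * (1 - pbar)
  s2 <- .rowVar(P)
  theta <- ifelse(denom > 0, pmax(0, s2 / denom - mean(1 / n)), 0)
  inv <- 1 / (outer(theta, rep(1, r)) + outer(rep(1, nrow(X)), 1 / n))
  sinv <- rowSums(inv)
  W <- inv / sinv
  list(p_pooled = pbar,
       theta_hat = theta,
       weights = W,
       p_hat = rowSums(W * P),
       var_hat = ifelse(denom > 0, denom / sinv, 0),
       n_rep = r)
}

#' Fit replicate proportions of one group with beta-binomial moments
#'
#' Estimates the group proportion and its variance from replicate counts
#' \code{x} out of library sizes \code{n}.  The overdispersion
#' \code{theta_hat} is the method-of-moments excess of the empirical
#' variance of the replicate proportions over the binomial expectation,
#' clamped at zero; replicates are combined with inverse-variance weights.
#'
#' @param x non-negative integer counts, one per replicate (length >= 2).
#' @param n positive library sizes, one per replicate.
#' @return object of class \code{BetaBinomialFit}: list with \code{p_hat},
#'   \code{theta_hat}, \code{weights} (summing to 1), \code{var_hat} and the
#'   pooled proportion \code{p_pooled}.
#' @examples
#' fit_group_proportions(c(30, 60), c(1000, 2000))
#' @export
fit_group_proportions <- function(x, n) {
  if (any(x < 0)) stop_input("counts must be non-negative")
  f <- .fit_props(matrix(x, nrow = 1L), n)
  structure(list(p_hat = f$p_hat, theta_hat = f$theta_hat,
                 weights = as.vector(f$weights), var_hat = f$var_hat,
                 p_pooled = f$p_pooled, n_rep = f$n_rep),
            class = "BetaBinomialFit")
}

# Vectorized two-group test over genes.
.weighted_t <- function(XA, nA, XB, nB) {
  a <- .fit_props(XA, nA)
  b <- .fit_props(XB, nB)
  v <- a$var_hat + b$var_hat
  diff <- a$p_hat - b$p_hat
  stat <- ifelse(v > 0, diff / sqrt(v), ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(v > 0,
               v^2 / (a$var_hat^2 / (a$n_rep - 1L) + b$var_hat^2 / (b$n_rep - 1L)),
               NA_real_)
  p <- ifelse(v > 0, 2 * stats::pt(-abs(stat), df), ifelse(diff == 0, 1, 0))
  untestable <- rowSums(as.matrix(XA)) + rowSums(as.matrix(XB)) == 0
  stat[untestable] <- 0
  p[untestable] <- 1
  list(stat = stat, p_value = p, df = df, untestable = untestable,
       p_hat_a = a$p_hat, p_hat_b = b$p_hat)
}

#' Weighted t-type test comparing two replicate groups of one gene
#'
#' The statistic is the difference of the weighted group proportions over
#' the square root of the summed variance estimates; the two-sided p-value
#' comes from a t reference with Welch-Satterthwaite degrees of freedom.
#' A gene with zero counts in every replicate of both groups is untestable
#' and reported as \code{stat = 0, p_value = 1}.
#'
#' @param xa,na counts and library sizes for group A replicates.
#' @param xb,nb counts and library sizes for group B replicates.
#' @return list with \code{stat}, \code{p_value} and \code{df}.
#' @export
weighted_t_test <- function(xa, na, xb, nb) {
  r <- .weighted_t(matrix(xa, nrow = 1L), na, matrix(xb, nrow = 1L), nb)
  list(stat = r$stat, p_value = r$p_value, df = r$df)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}; monotone by
#' construction and order-preserving under permutation of the input.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_input("p-values must be finite and in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

.match_cell <- function(samples, selector) {
  if (is.character(selector) && length(selector) == 1L && grepl("=", selector)) {
    kv <- strsplit(strsplit(selector, ",")[[1L]], "=")
    selector <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  selector <- as.list(selector)
  if (is.null(names(selector)) || any(!nzchar(names(selector))))
    stop_input("sample selector must be named, e.g. list(genotype = 'iTPS')")
  keep <- rep(TRUE, nrow(samples))
  for (k in names(selector)) {
    if (is.null(samples[[k]]))
      stop_input("selector field '%s' is not a sample sheet column", k)
    keep <- keep & samples[[k]] == selector[[k]]
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop_input("no samples match cell %s",
               paste(names(selector), unlist(selector), sep = "=", collapse = ","))
  idx
}

#' Run a differential-expression contrast between two sample cells
#'
#' Computes per-gene RPKM means for the treated and control cells, a log2
#' fold change with a pseudocount (by default the 5th percentile of the
#' nonzero cell means, preventing infinite fold changes at zero means
#' without affecting typical genes), the weighted proportions t-type test on
#' the raw counts over library sizes, Benjamini-Hochberg q-values over the
#' testable genes, and DEG flags at the strict (q < fdr and |log2 FC| >=
#' lfc_strict) and relaxed (q < fdr and |log2 FC| >= lfc_relaxed)
#' thresholds.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param lengths named vector of gene lengths in bp.
#' @param treated,control sample-cell selectors: named lists (or
#'   \code{"key=value,key=value"} strings) over sample sheet columns, each
#'   matching at least two replicates.
#' @param fdr q-value cutoff (default 0.05).
#' @param lfc_strict strict |log2 FC| cutoff (default 1, i.e. 2-fold).
#' @param lfc_relaxed relaxed |log2 FC| cutoff (default 0.2).
#' @param pseudocount RPKM pseudocount; \code{NULL} for the default rule.
#' @return \code{contrast_result} data frame with one row per gene:
#'   \code{gene_id}, \code{mean_treated}, \code{mean_control},
#'   \code{log2_fc}, \code{stat}, \code{p_value}, \code{q_value},
#'   \code{testable}, \code{passes_strict}, \code{passes_relaxed}.  The
#'   thresholds are carried in \code{attr(, "thresholds")}.
#' @export
run_contrast <- function(counts, lengths, treated, control,
                         fdr = 0.05, lfc_strict = 1, lfc_relaxed = 0.2,
                         pseudocount = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  it <- .match_cell(counts$samples, treated)
  ic <- .match_cell(counts$samples, control)
  if (length(it) < 2L || length(ic) < 2L)
    stop_input("both cells need at least 2 replicates (got %d and %d)",
               length(it), length(ic))
  rpkm <- compute_rpkm(counts, lengths)
  mt <- rowMeans(rpkm[, it, drop = FALSE])
  mc <- rowMeans(rpkm[, ic, drop = FALSE])
  if (is.null(pseudocount)) {
    nz <- c(mt, mc)[c(mt, mc) > 0]
    pseudocount <- if (length(nz)) unname(stats::quantile(nz, 0.05)) else 1
  }
  lfc <- log2((mt + pseudocount) / (mc + pseudocount))

  libs <- counts$samples$library_size
  tt <- .weighted_t(counts$counts[, it, drop = FALSE], libs[it],
                    counts$counts[, ic, drop = FALSE], libs[ic])
  q <- rep(NA_real_, nrow(counts$counts))
  testable <- !tt$untestable
  q[testable] <- bh_fdr(tt$p_value[testable])
  sig <- testable & !is.na(q) & q < fdr
  res <- data.frame(gene_id = rownames(counts$counts),
                    mean_treated = mt, mean_control = mc,
                    log2_fc = lfc, stat = tt$stat,
                    p_value = tt$p_value, q_value = q,
                    testable = testable,
                    passes_strict = sig & abs(lfc) >= lfc_strict,
                    passes_relaxed = sig & abs(lfc) >= lfc_relaxed,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "thresholds") <- c(fdr = fdr, lfc_strict = lfc_strict,
                               lfc_relaxed = lfc_relaxed)
  attr(res, "pseudocount") <- pseudocount
  class(res) <- c("contrast_result", "data.frame")
  res
}
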