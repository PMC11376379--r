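# Agreement between the iTPS response and external response vectors
# (constitutive TPS overexpression, transient SnRK1a1 overexpression,
# bZIP11 overexpression, TORC inactivation, ...), overall and per CRF
# group: qualitative sign concordance and OLS regression.

#' Sign concordance of two paired log2 FC vectors
#'
#' Counts gene pairs responding in the same direction, in opposite
#' directions, and pairs where either member is exactly zero (genes
#' filtered out or unchanged are neither "similar" nor "opposite").  Named
#' vectors are joined on the intersection of their gene ids.
#'
#' @param vec_a,vec_b numeric vectors (named by gene id, or unnamed and
#'   positionally paired).
#' @return list with \code{n_same}, \code{n_opposite}, \code{n_zero} and
#'   \code{n} (their sum, the paired count).
#' @export
sign_concordance <- function(vec_a, vec_b) {
  p <- .pair_intersect(vec_a, vec_b)
  if (length(p$a) == 0L) stop_input("empty gene intersection")
  sa <- sign(p$a); sb <- sign(p$b)
  zero <- sa == 0 | sb == 0
  list(n_same = sum(!zero & sa == sb),
       n_opposite = sum(!zero & sa == -sb),
       n_zero = sum(zero),
       n = length(p$a))
}

.pair_intersect <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    names(a) <- toupper(names(a)); names(b) <- toupper(names(b))
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) {
    stop_input("unnamed vectors must have equal length (%d vs %d)",
               length(a), length(b))
  }
  keep <- is.finite(a) & is.finite(b)
  list(a = as.numeric(a[keep]), b = as.numeric(b[keep]))
}

#' Regression of one response vector on another
#'
#' OLS of \code{vec_a} (response, e.g. the iTPS log2 FCs) on \code{vec_b}
#' (predictor, e.g. an external signature), with intercept.  r-squared is
#' the squared Pearson correlation; the p-value is the two-sided test of
#' slope = 0.
#'
#' @param vec_a,vec_b paired numeric vectors (named or positional).
#' @return list with \code{r_squared}, \code{slope}, \code{p_value},
#'   \code{n}.
#' @export
response_regression <- function(vec_a, vec_b) {
  p <- .pair_intersect(vec_a, vec_b)
  n <- length(p$a)
  if (n < 3L) stop_input("need at least 3 paired genes (got %d)", n)
  if (stats::var(p$b) == 0) stop_input("predictor vector has zero variance")
  fit <- stats::lm.fit(cbind(1, p$b), p$a)
  slope <- unname(fit$coefficients[2L])
  rss <- sum(fit$residuals^2)
  se <- sqrt(rss / (n - 2L) / sum((p$b - mean(p$b))^2))
  pv <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), n - 2L)
  r2 <- if (stats::var(p$a) == 0) NA_real_ else stats::cor(p$a, p$b)^2
  list(r_squared = r2, slope = slope, p_value = pv, n = n)
}

#' Compare the iTPS response with an external signature, per CRF group
#'
#' For the full filtered gene set and for each CRF group, restricts to
#' genes passing the chosen DEG filter in the iTPS contrast, joins with the
#' external vector on gene id, and reports sign concordance and the
#' regression of the iTPS log2 FCs on the external ones.  Sets with fewer
#' than 3 paired genes (or a degenerate predictor) get \code{NA} regression
#' statistics.
#'
#' @param itps a \code{contrast_result}.
#' @param external named numeric vector of external log2 FCs.
#' @param groups CRF records from [assign_group()].
#' @param filter \code{"relaxed"} (default) or \code{"strict"}.
#' @return data frame with one row per set (\code{all}, \code{G1},
#'   \code{G2}, \code{G0}): \code{n_genes}, \code{n_same},
#'   \code{n_opposite}, \code{n_zero}, \code{slope}, \code{r_squared},
#'   \code{p_value}.
#' @export
per_group_comparison <- function(itps, external, groups,
                                 filter = c("relaxed", "strict")) {
  filter <- match.arg(filter)
  col <- paste0("passes_", filter)
  names(external) <- toupper(names(external))
  gid <- toupper(itps$gene_id)
  pass <- !is.na(itps[[col]]) & itps[[col]]
  itps_fc <- stats::setNames(itps$log2_fc, gid)
  sets <- list(all = gid[pass])
  for (g in c("G1", "G2", "G0"))
    sets[[g]] <- intersect(gid[pass], toupper(groups$gene_id[groups$group == g]))

  rows <- lapply(names(sets), function(s) {
    genes <- intersect(sets[[s]], names(external))
    if (length(genes) == 0L)
      return(data.frame(set = s, n_genes = 0L, n_same = 0L, n_opposite = 0L,
                        n_zero = 0L, slope = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    a <- itps_fc[genes]; b <- external[genes]
    sc <- sign_concordance(a, b)
    reg <- if (length(genes) >= 3L && stats::var(b) > 0)
      response_regression(a, b)
    else list(r_squared = NA_real_, slope = NA_real_, p_value = NA_real_)
    data.frame(set = s, n_genes = length(genes), n_same = sc$n_same,
               n_opposite = sc$n_opposite, n_zero = sc$n_zero,
               slope = reg$slope, r_squared = reg$r_squared,
               p_value = reg$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
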