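# Removal of ethanol/alcR off-target effects from the induced-TPS response.
# Two modes mirror the two experimental arms: residualization against the
# empty-vector (alcR) ethanol response via a per-gene linear model
# (array-era mode), and flagging/omission of DEGs shared between the iTPS
# and alcR contrasts (RNA-seq-era mode).

#' Fit the off-target linear model
#'
#' Ordinary least squares of the iTPS ethanol-minus-water difference on the
#' alcR difference over a shared gene universe.  By default the model has no
#' intercept (both vectors are already centred contrasts); the coefficient
#' is then used by [correct_itps()] to subtract the shared ethanol/alcR
#' background from the iTPS response.
#'
#' @param delta_itps,delta_alcr per-gene difference vectors; if named, names
#'   must cover the same gene universe.
#' @param intercept fit an intercept term (default \code{FALSE}).
#' @return object of class \code{OffTargetModel}: list with \code{beta},
#'   \code{intercept}, \code{r_squared} (squared Pearson correlation) and
#'   \code{n_genes}.
#' @export
fit_offtarget_model <- function(delta_itps, delta_alcr, intercept = FALSE) {
  v <- .pair_vectors(delta_itps, delta_alcr)
  if (length(v$a) < 10L)
    stop_input("need >= 10 paired genes to fit the off-target model (got %d)",
               length(v$a))
  if (stats::var(v$b) == 0)
    stop_input("alcR differences have zero variance; no off-target model can be fit")
  if (intercept) {
    fit <- stats::lm.fit(cbind(1, v$b), v$a)
    beta <- unname(fit$coefficients[2L])
    alpha <- unname(fit$coefficients[1L])
  } else {
    beta <- sum(v$a * v$b) / sum(v$b^2)
    alpha <- 0
  }
  structure(list(beta = beta, intercept = alpha,
                 r_squared = stats::cor(v$a, v$b)^2,
                 n_genes = length(v$a), has_intercept = intercept),
            class = "OffTargetModel")
}

#' @export
print.OffTargetModel <- function(x, ...) {
  cat(sprintf("OffTargetModel: beta = %.4g, r^2 = %.3f (n = %d genes%s)\n",
              x$beta, x$r_squared, x$n_genes,
              if (x$has_intercept) sprintf(", intercept = %.4g", x$intercept) else ""))
  invisible(x)
}

.pair_vectors <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    names(a) <- toupper(names(a)); names(b) <- toupper(names(b))
    miss <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    if (length(miss))
      stop_input("gene universes differ; missing gene(s): %s",
                 paste(utils::head(unique(miss), 5L), collapse = ", "))
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop_input("paired vectors must have equal length (%d vs %d)",
               length(a), length(b))
  }
  keep <- is.finite(a) & is.finite(b)
  list(a = as.numeric(a[keep]), b = as.numeric(b[keep]),
       genes = if (!is.null(names(a))) names(a)[keep] else NULL)
}

#' Subtract the fitted off-target component from the iTPS response
#'
#' \code{corrected = delta_itps - intercept - beta * delta_alcr}.  With the
#' default no-intercept model the corrected vector is exactly orthogonal (in
#' the OLS sense) to the alcR differences.
#'
#' @param delta_itps,delta_alcr per-gene difference vectors over the
#'   universe the model was fitted on.
#' @param model an \code{OffTargetModel} from [fit_offtarget_model()].
#' @return corrected per-gene difference vector (named like the input).
#' @export
correct_itps <- function(delta_itps, delta_alcr, model) {
  stopifnot(inherits(model, "OffTargetModel"))
  v <- .pair_vectors(delta_itps, delta_alcr)
  out <- v$a - model$intercept - model$beta * v$b
  if (!is.null(v$genes)) names(out) <- v$genes
  out
}

#' Flag (and mark for omission) DEGs shared between iTPS and alcR contrasts
#'
#' Lists genes that pass the chosen DEG filter in \emph{both} the iTPS and
#' the alcR ethanol-vs-water contrast, split into same-direction and
#' opposite-direction responders.  Same-direction genes are plausible
#' ethanol/alcR off-target responses and are marked excluded from all
#' downstream analyses; no gene's statistics are altered.
#'
#' @param itps_contrast,alcr_contrast \code{contrast_result} tables computed
#'   at the same thresholds.
#' @param filter which flag to use: \code{"strict"} (default) or
#'   \code{"relaxed"}.
#' @return list with \code{report} (data frame: gene_id, log2_fc_itps,
#'   log2_fc_alcr, same_direction, excluded), \code{excluded} (character
#'   vector of same-direction gene ids), \code{n_shared} and
#'   \code{n_same_direction}.
#' @export
flag_shared_degs <- function(itps_contrast, alcr_contrast,
                             filter = c("strict", "relaxed")) {
  filter <- match.arg(filter)
  ti <- attr(itps_contrast, "thresholds")
  ta <- attr(alcr_contrast, "thresholds")
  if (!is.null(ti) && !is.null(ta) && !isTRUE(all.equal(ti, ta)))
    stop_input("contrasts were called at different thresholds")
  col <- paste0("passes_", filter)
  ii <- itps_contrast[[col]] & !is.na(itps_contrast[[col]])
  shared <- intersect(itps_contrast$gene_id[ii],
                      alcr_contrast$gene_id[alcr_contrast[[col]] &
                                              !is.na(alcr_contrast[[col]])])
  fi <- itps_contrast$log2_fc[match(shared, itps_contrast$gene_id)]
  fa <- alcr_contrast$log2_fc[match(shared, alcr_contrast$gene_id)]
  same <- sign(fi) == sign(fa)
  report <- data.frame(gene_id = shared, log2_fc_itps = fi, log2_fc_alcr = fa,
                       same_direction = same, excluded = same,
                       stringsAsFactors = FALSE)
  report <- report[order(report$gene_id), , drop = FALSE]
  rownames(report) <- NULL
  list(report = report, excluded = report$gene_id[report$excluded],
       n_shared = nrow(report), n_same_direction = sum(report$same_direction))
}
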