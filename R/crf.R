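# Carbon response factor (CRF) construction and deconvolution of the iTPS
# response into groups G1 (responds like increased sugar: inferred direct
# Tre6P effect), G2 (responds opposite to sugar: inferred indirect/low-sugar
# effect) and G0 (no consistent sugar response).

#' Compute the per-gene carbon response factor
#'
#' The CRF is the unweighted arithmetic mean of a gene's log2 fold changes
#' across the available reference sugar-manipulation contrasts (missing
#' cells are skipped, never treated as zero).  Genes observed in fewer than
#' \code{min_obs} contrasts receive no CRF (\code{NA}); such genes can only
#' be assigned to G0.
#'
#' @param panel numeric matrix (genes x contrasts) of log2 fold changes with
#'   possible \code{NA}s, as from [read_response_panel()] or
#'   [generate_panel()].
#' @param min_obs minimum number of observed contrasts (default 3).
#' @return data frame with columns \code{gene_id}, \code{crf}, \code{n_obs}.
#' @export
compute_crf <- function(panel, min_obs = 3L) {
  if (!is.matrix(panel) || ncol(panel) < 1L)
    stop_input("panel must be a matrix with at least one contrast column")
  if (min_obs < 1L) stop_input("min_obs must be >= 1")
  n_obs <- rowSums(!is.na(panel))
  crf <- ifelse(n_obs > 0, rowMeans(panel, na.rm = TRUE), NA_real_)
  crf[n_obs < min_obs] <- NA_real_
  data.frame(gene_id = toupper(rownames(panel)), crf = crf, n_obs = n_obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag context-dependent sugar responders
#'
#' A gene's sugar response is context-dependent when its transcript
#' abundance moves in opposing directions across the reference contrasts:
#' some observed panel value \code{>= +thr} \emph{and} some \code{<= -thr}.
#'
#' @param panel numeric matrix (genes x contrasts) or a single row vector.
#' @param thr positive log2 threshold.
#' @return logical vector, one flag per gene.
#' @export
flag_context_dependent <- function(panel, thr) {
  if (!is.numeric(thr) || length(thr) != 1L || thr <= 0)
    stop_input("thr must be a single positive number")
  if (!is.matrix(panel)) panel <- matrix(panel, nrow = 1L)
  up <- rowSums(panel >= thr, na.rm = TRUE) > 0
  dn <- rowSums(panel <= -thr, na.rm = TRUE) > 0
  unname(up & dn)
}

#' Assign iTPS-responsive genes to CRF groups
#'
#' Genes failing the chosen iTPS responsiveness filter are
#' \code{unassigned}.  Responsive genes with \code{|CRF| > crf_threshold}
#' go to G1 when the CRF sign matches the iTPS log2 FC sign and to G2 when
#' the signs differ; responsive genes with \code{|CRF| <= crf_threshold}
#' (or no CRF) go to G0.  The relaxed threshold on |CRF| maximizes
#' assignment to G1/G2.  Output covers every gene of the iTPS contrast and
#' is a partition over \{G1, G2, G0, unassigned\}.
#'
#' @param itps a \code{contrast_result} for the iTPS ethanol-vs-water cell.
#' @param crf data frame from [compute_crf()] (optionally with a
#'   \code{context_dependent} column to carry through).
#' @param responsiveness which DEG filter defines "responsive":
#'   \code{"relaxed"} (default; q < fdr and |log2 FC| >= 0.2) or
#'   \code{"strict"}.
#' @param crf_threshold |CRF| needed for G1/G2 (default 0.1, strict
#'   inequality).
#' @param absent_panel treatment of responsive genes absent from the panel:
#'   \code{"G0"} (default) or \code{"unassigned"}.
#' @return data frame of CRF records: \code{gene_id}, \code{itps_log2fc},
#'   \code{crf}, \code{n_obs}, \code{in_panel}, \code{responsive},
#'   \code{group}, \code{context_dependent}.
#' @export
assign_group <- function(itps, crf,
                         responsiveness = c("relaxed", "strict"),
                         crf_threshold = 0.1,
                         absent_panel = c("G0", "unassigned")) {
  responsiveness <- match.arg(responsiveness)
  absent_panel <- match.arg(absent_panel)
  if (!all(c("gene_id", "crf") %in% names(crf)))
    stop_input("crf must be a data frame with gene_id and crf columns")
  col <- paste0("passes_", responsiveness)
  m <- match(toupper(itps$gene_id), toupper(crf$gene_id))
  crf_v <- crf$crf[m]
  responsive <- !is.na(itps[[col]]) & itps[[col]]
  in_panel <- !is.na(m)

  group <- rep("unassigned", nrow(itps))
  has_crf <- !is.na(crf_v)
  sugar <- has_crf & abs(crf_v) > crf_threshold
  g1 <- responsive & sugar & sign(crf_v) == sign(itps$log2_fc)
  g2 <- responsive & sugar & sign(crf_v) != sign(itps$log2_fc)
  g0 <- responsive & !sugar & (in_panel | absent_panel == "G0")
  group[g0] <- "G0"
  group[g1] <- "G1"
  group[g2] <- "G2"

  ctx <- if (!is.null(crf$context_dependent)) crf$context_dependent[m] else NA
  out <- data.frame(gene_id = toupper(itps$gene_id),
                    itps_log2fc = itps$log2_fc,
                    crf = crf_v,
                    n_obs = if (!is.null(crf$n_obs)) crf$n_obs[m] else NA_integer_,
                    in_panel = in_panel,
                    responsive = responsive,
                    group = group,
                    context_dependent = ctx,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "crf_threshold") <- crf_threshold
  attr(out, "responsiveness") <- responsiveness
  class(out) <- c("crf_records", "data.frame")
  out
}

#' Summarize CRF group assignment
#'
#' Counts per group plus, for G1/G2/G0, the fraction of assigned
#' (responsive) genes in each group; fractions are \code{NA} when nothing
#' was assigned.
#'
#' @param records data frame from [assign_group()].
#' @return data frame with columns \code{group}, \code{n}, \code{fraction}.
#' @export
group_summary <- function(records) {
  lv <- c("G1", "G2", "G0", "unassigned")
  n <- vapply(lv, function(g) sum(records$group == g), integer(1))
  assigned <- sum(n[c("G1", "G2", "G0")])
  frac <- c(if (assigned > 0) n[c("G1", "G2", "G0")] / assigned
            else rep(NA_real_, 3L), NA_real_)
  data.frame(group = lv, n = unname(n), fraction = unname(frac),
             row.names = NULL, stringsAsFactors = FALSE)
}
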