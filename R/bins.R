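# PageMan-style display over the MapMan BIN hierarchy: set non-significant
# genes to zero, then average the (zeroed) log2 fold changes of every gene
# in a BIN -- per CRF group and per contrast.

#' Per-gene display fold changes after the significance filter
#'
#' Returns each gene's log2 FC if it passes the chosen DEG filter, else
#' exactly zero.  The zeros are kept in the downstream BIN averages, so a
#' category's mean shrinks toward zero as fewer of its members respond.
#'
#' @param contrast a \code{contrast_result}.
#' @param filter \code{"strict"} (default) or \code{"relaxed"}.
#' @return named numeric vector of display fold changes.
#' @export
zero_filtered_fc <- function(contrast, filter = c("strict", "relaxed")) {
  filter <- match.arg(filter)
  col <- paste0("passes_", filter)
  ok <- !is.na(contrast[[col]]) & contrast[[col]]
  stats::setNames(ifelse(ok, contrast$log2_fc, 0), toupper(contrast$gene_id))
}

.bin_ancestors <- function(codes) {
  lapply(strsplit(codes, ".", fixed = TRUE), function(parts)
    vapply(seq_along(parts), function(i)
      paste(parts[seq_len(i)], collapse = "."), ""))
}

# expand a binmap to (bincode, gene_id) pairs, optionally including each
# gene in every ancestor category (PageMan's cumulative display)
.expand_binmap <- function(binmap, include_descendants = TRUE) {
  if (!all(c("bincode", "gene_id") %in% names(binmap)) || nrow(binmap) == 0L)
    stop_input("binmap must be a non-empty data frame with bincode and gene_id")
  code <- as.character(binmap$bincode)
  gene <- toupper(binmap$gene_id)
  if (include_descendants) {
    anc <- .bin_ancestors(code)
    reps <- lengths(anc)
    out <- data.frame(bincode = unlist(anc), gene_id = rep(gene, reps),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(bincode = code, gene_id = gene, stringsAsFactors = FALSE)
  }
  unique(out)  # within one BIN a gene counts once
}

.sort_bincodes <- function(codes) {
  parts <- strsplit(codes, ".", fixed = TRUE)
  depth <- max(lengths(parts))
  keys <- vapply(parts, function(p)
    paste(formatC(c(as.integer(p), rep(0L, depth - length(p))),
                  width = 6, flag = "0"), collapse = "."), "")
  codes[order(keys)]
}

#' Average display fold changes per BIN
#'
#' For every category (including implicit ancestors), the mean of the
#' display fold changes over its member genes, restricted to
#' \code{gene_subset} when given (e.g. one CRF group).  Zeros from the
#' significance filter are included in the mean; a populated BIN whose
#' members all failed the filter averages to exactly 0, while a BIN with no
#' members under the restriction is \code{NA}.
#'
#' @param display_fc named vector from [zero_filtered_fc()]; its names
#'   define the gene universe.
#' @param binmap data frame from [read_bin_map()].
#' @param gene_subset optional character vector restricting the universe.
#' @param include_descendants count genes of descendant BINs in their
#'   ancestors (default TRUE, matching the cumulative PageMan display).
#' @return data frame with columns \code{bincode}, \code{name},
#'   \code{n_genes}, \code{mean_fc}, ordered by BIN code.
#' @export
bin_average <- function(display_fc, binmap, gene_subset = NULL,
                        include_descendants = TRUE) {
  ex <- .expand_binmap(binmap, include_descendants)
  universe <- names(display_fc)
  if (!is.null(gene_subset)) universe <- intersect(universe, toupper(gene_subset))
  codes <- .sort_bincodes(unique(ex$bincode))
  hit <- ex[ex$gene_id %in% universe, , drop = FALSE]
  sums <- tapply(display_fc[hit$gene_id], hit$bincode, sum)
  cnts <- tapply(hit$gene_id, hit$bincode, length)
  n <- ifelse(is.na(cnts[codes]), 0L, cnts[codes])
  mean_fc <- ifelse(n > 0, sums[codes] / n, NA_real_)
  nm <- binmap$name[match(codes, binmap$bincode)]
  data.frame(bincode = codes, name = as.character(nm),
             n_genes = as.integer(n), mean_fc = unname(mean_fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the BIN x (group x contrast) filtered-average heat map matrix
#'
#' One column per (CRF group, contrast) pair, one row per BIN (hierarchy
#' ancestors included), each cell the filtered-average log2 FC of the
#' group's genes in that BIN for that contrast.
#'
#' @param contrasts named list of display-FC vectors from
#'   [zero_filtered_fc()], one per contrast (names become column labels).
#' @param groups CRF records from [assign_group()] (or any data frame with
#'   \code{gene_id} and \code{group}).
#' @param binmap data frame from [read_bin_map()].
#' @param group_order columns are laid out group-major in this order.
#' @param include_descendants see [bin_average()].
#' @return numeric matrix, rownames BIN codes, colnames
#'   \code{"<group>.<contrast>"}.
#' @export
build_heatmap <- function(contrasts, groups, binmap,
                          group_order = c("G1", "G2", "G0"),
                          include_descendants = TRUE) {
  if (!is.list(contrasts) || is.null(names(contrasts)))
    stop_input("contrasts must be a named list of display-FC vectors")
  cols <- list()
  for (g in group_order) {
    members <- toupper(groups$gene_id[groups$group == g])
    for (ct in names(contrasts)) {
      ba <- bin_average(contrasts[[ct]], binmap, gene_subset = members,
                        include_descendants = include_descendants)
      cols[[paste(g, ct, sep = ".")]] <- stats::setNames(ba$mean_fc, ba$bincode)
    }
  }
  codes <- names(cols[[1L]])
  out <- vapply(cols, function(v) v[codes], numeric(length(codes)))
  rownames(out) <- codes
  out
}
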