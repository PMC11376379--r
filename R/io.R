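# Readers/writers for the tabular formats every stage consumes and produces.
# All tables are TSV (UTF-8, Unix newlines); missing values are the literal
# "NA" -- zeros are data, never missingness.  Gene identifiers are matched by
# exact string equality after upper-casing.

.VALID_GENOTYPES  <- c("iTPS", "alcR")
.VALID_TREATMENTS <- c("ethanol", "water")

.norm_level <- function(x, valid, what) {
  idx <- match(tolower(x), tolower(valid))
  if (anyNA(idx))
    stop_format("invalid %s value(s): %s (expected one of %s)",
                what, paste(unique(x[is.na(idx)]), collapse = ", "),
                paste(valid, collapse = ", "))
  valid[idx]
}

#' Construct a validated count matrix with its sample sheet
#'
#' The container used throughout the pipeline: an integer matrix of read
#' counts (genes in rows, samples in columns) plus a per-sample data frame
#' describing genotype (\code{iTPS} or \code{alcR}), treatment
#' (\code{ethanol} or \code{water}), timepoint label, replicate index and
#' library size (total mapped reads; at least the column sum, since the
#' matrix rows may be a subset of all mapped reads).
#'
#' @param counts numeric matrix of non-negative integer counts with unique
#'   rownames (gene identifiers) and colnames (sample identifiers).
#' @param samples data frame with columns \code{sample_id}, \code{genotype},
#'   \code{treatment}, \code{timepoint}, \code{replicate}, and optionally
#'   \code{library_size} (defaults to the column sums of \code{counts}).
#' @return An object of class \code{CountMatrix}: a list with elements
#'   \code{counts} and \code{samples} (rows ordered to match the columns of
#'   \code{counts}).
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_format("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_format("counts must carry gene rownames and sample colnames")
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts)))
    stop_format("duplicate gene_id: %s",
                paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                      collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_format("negative or non-integer count at gene %s, sample %s",
                rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]])
  storage.mode(counts) <- "double"

  if (!is.data.frame(samples)) stop_format("samples must be a data frame")
  need <- c("sample_id", "genotype", "treatment", "timepoint", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_format("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  unmatched <- setdiff(colnames(counts), samples$sample_id)
  if (length(unmatched))
    stop_format("sample(s) in count matrix missing from sheet: %s",
                paste(unmatched, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$genotype  <- .norm_level(samples$genotype,  .VALID_GENOTYPES,  "genotype")
  samples$treatment <- .norm_level(samples$treatment, .VALID_TREATMENTS, "treatment")
  samples$timepoint <- as.character(samples$timepoint)

  if (is.null(samples$library_size)) {
    samples$library_size <- unname(colSums(counts))
  } else {
    samples$library_size <- as.numeric(samples$library_size)
    if (any(!is.finite(samples$library_size) | samples$library_size <= 0))
      stop_format("library_size must be positive")
    short <- samples$library_size < colSums(counts) - 1e-8
    if (any(short))
      stop_format("library_size smaller than column sum for sample(s): %s",
                  paste(samples$sample_id[short], collapse = ", "))
  }
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cells <- table(interaction(x$samples$genotype, x$samples$treatment,
                             x$samples$timepoint, drop = TRUE))
  cat("replicates per cell:\n")
  print(cells)
  invisible(x)
}

#' Read a count matrix and sample sheet from TSV files
#'
#' The count matrix TSV has a header row of sample identifiers and gene
#' identifiers in the first column.  The sample sheet TSV needs columns
#' \code{sample_id}, \code{genotype}, \code{treatment}, \code{timepoint},
#' \code{replicate} and optionally \code{library_size} (column sums are used
#' when absent).  Lines starting with \code{#} are ignored.
#'
#' @param path path to the count matrix TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return A \code{\link{count_matrix}} object.
#' @export
read_count_matrix <- function(path, sample_sheet_path) {
  tab <- .read_tsv(path)
  gene_ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_format("non-numeric count values in %s", path)
  rownames(m) <- gene_ids
  sheet <- .read_tsv(sample_sheet_path)
  if (is.null(sheet$sample_id))
    stop_format("sample sheet %s lacks a sample_id column", sample_sheet_path)
  count_matrix(m, sheet)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "")
}

#' Write a result table as TSV
#'
#' Serializes any stage output (contrast results, CRF records, comparison
#' tables, ...) with a fixed column order (the data frame's own), missing
#' values as the literal \code{NA}, and full double precision so re-reading
#' reproduces values.  Optional comment lines (prefixed \code{# }) are
#' written above the header.
#'
#' @param x data frame (or matrix with rownames, written with an
#'   \code{gene_id} first column).
#' @param path output path.
#' @param comments character vector of header comment lines.
#' @export
write_table <- function(x, path, comments = character()) {
  if (is.matrix(x)) {
    x <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  con <- tryCatch(file(path, open = "wt"), condition = function(e)
    stop_io("cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene lengths (gene_id, length in bp) from TSV
#' @param path TSV with columns \code{gene_id} and \code{length}.
#' @return named numeric vector of lengths in base pairs.
#' @export
read_gene_lengths <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("gene_id", "length") %in% names(tab)))
    stop_format("%s must have columns gene_id and length", path)
  len <- as.numeric(tab$length)
  if (any(!is.finite(len) | len <= 0))
    stop_format("gene lengths must be positive integers")
  names(len) <- toupper(as.character(tab$gene_id))
  len
}

#' Read a reference response panel of per-gene log2 fold changes
#'
#' One row per gene (first column \code{gene_id}), one column per reference
#' sugar-manipulation contrast.  Missing cells (\code{NA}) mean "not
#' measured" and are never treated as zero.
#'
#' @param path TSV path.
#' @return numeric matrix (genes x contrasts) with possible \code{NA}s.
#' @export
read_response_panel <- function(path) {
  tab <- .read_tsv(path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- toupper(as.character(tab[[1L]]))
  if (anyDuplicated(rownames(m)))
    stop_format("duplicate gene_id in panel: %s",
                rownames(m)[duplicated(rownames(m))][1L])
  m
}

#' Read a gene-to-BIN mapping (MapMan dialect or plain)
#'
#' Accepts the MapMan mapping-file dialect (columns \code{BINCODE},
#' \code{NAME}, \code{IDENTIFIER}, \code{DESCRIPTION}, values possibly
#' wrapped in single quotes) or a plain TSV with columns \code{bincode},
#' \code{name}, \code{gene_id}.  One row per (gene, category) pair; a gene
#' may map to several categories.
#'
#' @param path TSV path.
#' @return data frame with columns \code{bincode}, \code{name},
#'   \code{gene_id}.
#' @export
read_bin_map <- function(path) {
  tab <- .read_tsv(path)
  names(tab) <- tolower(names(tab))
  unquote <- function(x) gsub("^'|'$", "", as.character(x))
  if (all(c("bincode", "identifier") %in% names(tab))) {
    out <- data.frame(bincode = unquote(tab$bincode),
                      name = unquote(tab$name %||% rep(NA_character_, nrow(tab))),
                      gene_id = toupper(unquote(tab$identifier)),
                      stringsAsFactors = FALSE)
  } else if (all(c("bincode", "gene_id") %in% names(tab))) {
    out <- data.frame(bincode = unquote(tab$bincode),
                      name = unquote(tab$name %||% rep(NA_character_, nrow(tab))),
                      gene_id = toupper(unquote(tab$gene_id)),
                      stringsAsFactors = FALSE)
  } else {
    stop_format("%s is not a recognizable BIN mapping (need BINCODE/IDENTIFIER or bincode/gene_id columns)", path)
  }
  out <- out[nzchar(out$gene_id) & !is.na(out$gene_id), , drop = FALSE]
  if (!all(grepl("^[0-9]+(\\.[0-9]+)*$", out$bincode)))
    stop_format("malformed BIN code(s): %s",
                paste(utils::head(unique(out$bincode[!grepl("^[0-9]+(\\.[0-9]+)*$", out$bincode)]), 3), collapse = ", "))
  unique(out)
}

#' Read an external response vector (gene_id, log2_fc) from TSV
#' @param path TSV with columns \code{gene_id} and \code{log2_fc}.
#' @return named numeric vector of log2 fold changes.
#' @export
read_external_response <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("gene_id", "log2_fc") %in% names(tab)))
    stop_format("%s must have columns gene_id and log2_fc", path)
  stats::setNames(as.numeric(tab$log2_fc), toupper(as.character(tab$gene_id)))
}

#' Read a differential-expression contrast table written by [write_table()]
#'
#' Restores the threshold attribute from the header comment when present so
#' that downstream threshold-consistency checks still apply.
#'
#' @param path TSV path.
#' @return a \code{contrast_result} data frame.
#' @export
read_contrast_result <- function(path) {
  tab <- .read_tsv(path)
  need <- c("gene_id", "log2_fc", "p_value", "q_value",
            "passes_strict", "passes_relaxed")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_format("%s lacks contrast column(s): %s", path,
                paste(miss, collapse = ", "))
  tab$gene_id <- toupper(as.character(tab$gene_id))
  for (cl in c("passes_strict", "passes_relaxed", "testable"))
    if (!is.null(tab[[cl]])) tab[[cl]] <- as.logical(tab[[cl]])
  hdr <- readLines(path, n = 5L)
  thr <- grep("^# thresholds:", hdr, value = TRUE)
  if (length(thr)) {
    kv <- strsplit(strsplit(sub("^# thresholds: *", "", thr[1L]), ", *")[[1L]], "=")
    attr(tab, "thresholds") <- stats::setNames(
      as.numeric(vapply(kv, `[`, "", 2L)), vapply(kv, `[`, "", 1L))
  }
  class(tab) <- c("contrast_result", "data.frame")
  tab
}
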