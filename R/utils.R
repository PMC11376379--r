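# internal helpers: classed conditions, seeds, small utilities

.stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "crfdeconv_error")))
}

stop_format <- function(fmt, ...) .stop("crfdeconv_format_error", fmt, ...)
stop_input  <- function(fmt, ...) .stop("crfdeconv_input_error", fmt, ...)
stop_io     <- function(fmt, ...) .stop("crfdeconv_io_error", fmt, ...)

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop_input("seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable polynomial hash of a character vector; used to stamp pipeline outputs
.confhash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

.rowVar <- function(m) {
  if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
}
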