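# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
GENE_GROUPS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")

# width of a probe source sequence and the 1-based offset of the interrogated
# CpG within it (the C sits at offset 25, the G at 26)
PROBE_WIDTH <- 50L
CPG_OFFSET <- 25L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_fraction <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) {
    stop_invalid("`%s` must be a single fraction in [0,%s], got %s",
                 name, if (open_upper) "1)" else "1]", format(x))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && (if (positive) x > 0 else x >= 0)
  if (!ok) {
    stop_invalid("`%s` must be a %s integer, got %s",
                 name, if (positive) "positive" else "non-negative", format(x))
  }
  invisible(as.integer(x))
}

# split a ';'-joined annotation field into a character vector ('' -> empty)
split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

collapse_field <- function(x) paste(x, collapse = ";")
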