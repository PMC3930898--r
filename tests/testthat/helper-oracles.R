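# Independent oracles used to validate the package's computations. These are
# deliberately naive re-implementations that share no code with the package.

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# exhaustive Hamming scan of one probe over a named character-vector genome;
# returns all windows (both strands) with <= max_mm substitutions
oracle_scan <- function(probe, chroms, max_mm) {
  p_fwd <- utf8ToInt(probe)
  p_rev <- utf8ToInt(oracle_revcomp(probe))
  w <- length(p_fwd)
  rows <- list()
  for (cn in names(chroms)) {
    g <- utf8ToInt(chroms[[cn]])
    n_win <- length(g) - w + 1L
    if (n_win < 1) next
    for (strand in c("+", "-")) {
      p <- if (strand == "+") p_fwd else p_rev
      mm <- integer(n_win)
      for (k in seq_len(w)) {
        mm <- mm + (g[k:(k + n_win - 1L)] != p[k])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        cpg <- vapply(hit, function(st) {
          substr(chroms[[cn]], st + 24L, st + 25L) == "CG"
        }, logical(1))
        rows[[length(rows) + 1]] <- data.frame(
          chromosome = cn, start = hit - 1L, strand = strand,
          mismatch_count = mm[hit], cpg_preserved = cpg)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(0), start = integer(0),
               strand = character(0), mismatch_count = integer(0),
               cpg_preserved = logical(0))
  out[order(out$mismatch_count, out$chromosome, out$start), , drop = FALSE]
}

# unique-best acceptance on top of the oracle scan (mirrors the stated policy,
# computed independently)
oracle_competent <- function(manifest, chroms, max_mm, require_cpg = TRUE) {
  oracle_competent_both(manifest, chroms, max_mm, require_cpg)$at_max
}

# one exhaustive scan per probe, acceptance derived at both thresholds
# (exact = 0 mismatches, at_max = the given bound)
oracle_competent_both <- function(manifest, chroms, max_mm, require_cpg = TRUE) {
  accept <- function(h, thr) {
    h <- h[h$mismatch_count <= thr, , drop = FALSE]
    if (!nrow(h)) return(FALSE)
    best <- min(h$mismatch_count)
    sum(h$mismatch_count == best) == 1
  }
  exact <- character(0); at_max <- character(0)
  for (i in seq_len(nrow(manifest))) {
    h <- oracle_scan(manifest$source_seq[i], chroms, max_mm)
    if (require_cpg) h <- h[h$cpg_preserved, , drop = FALSE]
    if (!nrow(h)) next
    if (accept(h, 0)) exact <- c(exact, manifest$probe_id[i])
    if (accept(h, max_mm)) at_max <- c(at_max, manifest$probe_id[i])
  }
  list(exact = exact, at_max = at_max)
}

# exact two-sided Fisher p by full enumeration over tables with fixed margins
# (point-probability rule)
oracle_fisher_two_sided <- function(a, b, cc, d) {
  m <- a + cc; n_ <- b + d; k <- a + b
  lo <- max(0L, k - n_); hi <- min(k, m)
  support <- lo:hi
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}

# pooled-variance two-sample t-test p-value, closed form
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(effect = mean(y) - mean(x), t = t,
       p = 2 * pt(-abs(t), nx + ny - 2))
}

# one average-linkage or complete-linkage agglomeration trace on a small
# dissimilarity matrix, by direct recomputation over cluster members
oracle_linkage_heights <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        val <- if (linkage == "average") mean(dd) else max(dd)
        if (val < best_d) { best_d <- val; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
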