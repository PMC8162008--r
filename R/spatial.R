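# Sliding-window chromosome scans. Genes are assigned to windows by their
# midpoint (floor((start + end) / 2)), which keeps counts unambiguous for
# genes straddling window edges and makes tiling counts conserve the number
# of placed genes exactly.

#' Sliding-window specification
#' @param window_bp window width in bp (enrichment default 1.5 Mb; the class
#'   density scan uses 3 Mb).
#' @param step_bp step between window starts in bp (default 100 kb).
#' @return a `window_spec` list.
#' @export
window_spec <- function(window_bp = 1500000L, step_bp = 100000L) {
  if (!(step_bp > 0 && step_bp <= window_bp)) {
    stop("need 0 < step_bp <= window_bp", call. = FALSE)
  }
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp)), class = "window_spec")
}

#' Chromosome lengths from a gene catalog
#'
#' Defaults to the maximum annotated gene end per chromosome; supply an
#' explicit length table when one is available.
#' @param catalog a [gene_catalog()].
#' @return named integer vector of lengths.
#' @export
chromosome_lengths <- function(catalog) {
  tapply(catalog$end, catalog$chrom, max)
}

#' Build sliding windows along chromosomes
#'
#' Windows start at 1, 1 + step, ...; each spans `window_bp`, so a chromosome
#' of length L yields `floor((L - window_bp) / step_bp) + 1` windows. A
#' chromosome shorter than one window yields a single window covering it.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp), e.g. from
#'   [chromosome_lengths()].
#' @param spec a [window_spec()].
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `window_id`.
#' @export
make_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- as.numeric(chrom_lengths[[ch]])
    if (L < spec$window_bp) {
      data.frame(chrom = ch, start = 1, end = L)
    } else {
      n <- floor((L - spec$window_bp) / spec$step_bp) + 1
      start <- 1 + (seq_len(n) - 1) * spec$step_bp
      data.frame(chrom = ch, start = start, end = start + spec$window_bp - 1)
    }
  })
  res <- do.call(rbind, out)
  res$window_id <- seq_len(nrow(res))
  res
}

.gene_midpoints <- function(catalog) {
  floor((catalog$start + catalog$end) / 2)
}

# windows x genes logical incidence by midpoint; windows and genes must share
# chromosome naming. Genes on chromosomes absent from `windows` are dropped
# with a warning.
.window_membership <- function(windows, catalog) {
  mid <- .gene_midpoints(catalog)
  unknown <- !(catalog$chrom %in% unique(windows$chrom))
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) on chromosome(s) without windows; excluded",
            call. = FALSE)
  }
  M <- matrix(FALSE, nrow(windows), nrow(catalog),
              dimnames = list(NULL, catalog$gene_id))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    gi <- which(catalog$chrom == ch)
    if (!length(gi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(windows$start[wi], windows$end[wi]),
      IRanges::IRanges(mid[gi], width = 1L))
    M[cbind(wi[S4Vectors::queryHits(hits)], gi[S4Vectors::subjectHits(hits)])] <- TRUE
  }
  M
}

#' Count labelled genes per sliding window
#'
#' A gene belongs to every window whose span contains its midpoint (sliding
#' windows overlap by design).
#'
#' @param windows a [make_windows()] result.
#' @param catalog a [gene_catalog()].
#' @param labels named character/factor vector: a label per gene id (genes
#'   absent from `labels` are counted only in the per-window total).
#' @return a `window_table`: `windows` with `n_genes_total` plus one `n_<label>`
#'   count column per label level.
#' @export
window_counts <- function(windows, catalog, labels) {
  M <- .window_membership(windows, catalog)
  wt <- windows
  wt$n_genes_total <- as.integer(rowSums(M))
  lab <- labels[catalog$gene_id]
  for (lv in unique(stats::na.omit(as.character(labels)))) {
    sel <- !is.na(lab) & as.character(lab) == lv
    wt[[paste0("n_", lv)]] <- as.integer(rowSums(M[, sel, drop = FALSE]))
  }
  class(wt) <- c("window_table", "data.frame")
  wt
}

#' One-tailed Fisher enrichment p-value per window
#'
#' Tests whether salt-specific heritable genes are over-represented among the
#' heritable genes inside the window, against the genome-wide composition of
#' the heritable set: the exact p is the upper hypergeometric tail of drawing
#' the window's heritable genes from all heritable genes with the
#' salt-specific ones as successes. Windows with no heritable gene get p = 1.
#'
#' @param wt a [window_counts()] result carrying `n_heritable` and
#'   `n_salt_specific` columns (see [heritability_window_counts()]).
#' @param n_salt_total,n_heritable_total genome-wide totals.
#' @return `wt` with a `fisher_p` column.
#' @export
fisher_enrichment <- function(wt, n_salt_total, n_heritable_total) {
  k <- wt$n_salt_specific
  nh <- wt$n_heritable
  if (is.null(k) || is.null(nh)) {
    stop("wt needs n_salt_specific and n_heritable columns", call. = FALSE)
  }
  if (any(k > nh)) stop("n_salt_specific exceeds n_heritable in a window",
                        call. = FALSE)
  p <- phyper(k - 1L, n_salt_total, n_heritable_total - n_salt_total, nh,
              lower.tail = FALSE)
  p[nh == 0L] <- 1.0
  wt$fisher_p <- p
  wt$fisher_flagged <- nh == 0L
  wt
}

#' Window counts for heritability classes
#'
#' Convenience wrapper: counts heritable (`general`, `control_specific`,
#' `salt_specific`) and salt-specific genes per window.
#'
#' @param windows a [make_windows()] result.
#' @param catalog a [gene_catalog()].
#' @param h2_classes a [classify_heritability()] table (or any data.frame with
#'   `gene_id` and `class`).
#' @return a `window_table` with `n_heritable` and `n_salt_specific` columns
#'   and the genome totals as attributes.
#' @export
heritability_window_counts <- function(windows, catalog, h2_classes) {
  cls <- setNames(as.character(h2_classes$class), h2_classes$gene_id)
  heritable <- names(cls)[!is.na(cls) & cls != "not_heritable"]
  salt <- names(cls)[!is.na(cls) & cls == "salt_specific"]
  lab <- setNames(rep(NA_character_, nrow(catalog)), catalog$gene_id)
  lab[intersect(heritable, names(lab))] <- "heritable"
  wt <- window_counts(windows, catalog, lab)
  M <- .window_membership(windows, catalog)
  wt$n_salt_specific <- as.integer(
    rowSums(M[, colnames(M) %in% salt, drop = FALSE]))
  attr(wt, "n_heritable_total") <- sum(catalog$gene_id %in% heritable)
  attr(wt, "n_salt_total") <- sum(catalog$gene_id %in% salt)
  wt
}

#' Bootstrap-adjusted window p-values
#'
#' Builds a window-specific null by repeatedly drawing `n_salt` genes without
#' replacement from the heritable set, recomputing every window's Fisher p,
#' and setting `adjusted_p = (1 + #\{null p <= observed p\}) / (1 + B)`. Windows
#' whose estimate is unstable (zero null exceedances) escalate in further
#' batches of `B` up to `B_max` iterations. Significance is strict:
#' `adjusted_p < alpha`.
#'
#' @param wt a [fisher_enrichment()] result.
#' @param catalog a [gene_catalog()].
#' @param heritable_ids gene ids of all heritable genes (the resampling pool).
#' @param n_salt number of salt-specific heritable genes to draw per iteration.
#' @param B initial number of bootstrap iterations (default 4000).
#' @param B_max escalation cap (default 50000).
#' @param alpha significance level (default 0.001).
#' @param seed integer seed.
#' @param chunk internal batch size for the vectorized resampling.
#' @return `wt` with `adjusted_p`, `n_null_iterations` and `significant`
#'   columns.
#' @export
bootstrap_adjust <- function(wt, catalog, heritable_ids, n_salt,
                             B = 4000L, B_max = 50000L, alpha = 0.001,
                             seed, chunk = 250L) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  pool <- catalog[catalog$gene_id %in% heritable_ids, , drop = FALSE]
  n_pool <- nrow(pool)
  if (n_salt > n_pool) stop("n_salt exceeds the heritable pool", call. = FALSE)
  M <- .window_membership(wt[, c("chrom", "start", "end")], pool) * 1
  nh <- wt$n_heritable
  obs_p <- wt$fisher_p
  n_win <- nrow(wt)

  set.seed(seed)
  run_batch <- function(rows, n_iter) {
    # returns #\{null p <= obs p\} per requested window row
    exceed <- integer(length(rows))
    done <- 0L
    Msub <- M[rows, , drop = FALSE]
    while (done < n_iter) {
      b <- min(chunk, n_iter - done)
      Z <- matrix(0, n_pool, b)
      for (j in seq_len(b)) Z[sample.int(n_pool, n_salt), j] <- 1
      k_null <- Msub %*% Z                      # windows x iterations
      p_null <- matrix(
        phyper(k_null - 1, n_salt, n_pool - n_salt, nh[rows], lower.tail = FALSE),
        nrow = length(rows))
      p_null[nh[rows] == 0L, ] <- 1.0
      exceed <- exceed + rowSums(p_null <= obs_p[rows] + 1e-12)
      done <- done + b
    }
    exceed
  }

  exceed <- run_batch(seq_len(n_win), B)
  iters <- rep(as.integer(B), n_win)
  repeat {
    unstable <- which(exceed == 0L & iters < B_max)
    if (!length(unstable)) break
    extra <- pmin(B, B_max - iters[unstable])
    stopifnot(length(unique(extra)) == 1L)
    exceed[unstable] <- exceed[unstable] + run_batch(unstable, extra[1L])
    iters[unstable] <- iters[unstable] + extra
  }
  wt$adjusted_p <- (1 + exceed) / (1 + iters)
  wt$n_null_iterations <- iters
  wt$significant <- wt$adjusted_p < alpha
  attr(wt, "alpha") <- alpha
  wt
}

#' Merge significant windows into contiguous regions
#'
#' Significant windows on one chromosome are combined when they overlap or
#' abut within one step; each region spans the minimum start to the maximum
#' end of its member windows and carries the ids of the genes whose midpoints
#' fall inside it.
#'
#' @param wt a [bootstrap_adjust()] result (needs `significant`).
#' @param catalog a [gene_catalog()] used to collect member genes.
#' @param step_bp the scan's step size (merging tolerance).
#' @return data.frame with `region_id`, `chrom`, `start`, `end`, `n_windows`,
#'   `n_genes`; member gene ids in the `genes` list-attribute. `wt` rows gain
#'   a `region_id` via the `window_regions` attribute. Empty when no window
#'   is significant.
#' @export
merge_regions <- function(wt, catalog = NULL, step_bp = 100000L) {
  sig <- wt[which(wt$significant), , drop = FALSE]
  if (!nrow(sig)) {
    out <- data.frame(region_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), n_genes = integer())
    attr(out, "genes") <- list()
    return(out)
  }
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  region <- integer(nrow(sig))
  rid <- 0L
  cur_end <- -Inf
  cur_ch <- ""
  for (i in seq_len(nrow(sig))) {
    if (sig$chrom[i] != cur_ch || sig$start[i] > cur_end + step_bp) {
      rid <- rid + 1L
      cur_ch <- sig$chrom[i]
      cur_end <- sig$end[i]
    } else {
      cur_end <- max(cur_end, sig$end[i])
    }
    region[i] <- rid
  }
  genes <- list()
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), region), function(ix) {
    data.frame(region_id = region[ix[1L]], chrom = sig$chrom[ix[1L]],
               start = min(sig$start[ix]), end = max(sig$end[ix]),
               n_windows = length(ix))
  }))
  rownames(out) <- NULL
  if (!is.null(catalog)) {
    mid <- .gene_midpoints(catalog)
    genes <- lapply(seq_len(nrow(out)), function(r) {
      catalog$gene_id[catalog$chrom == out$chrom[r] &
                        mid >= out$start[r] & mid <= out$end[r]]
    })
    out$n_genes <- vapply(genes, length, 1L)
  } else {
    out$n_genes <- NA_integer_
  }
  attr(out, "genes") <- genes
  out
}

#' Correlate expression-class gene density with a compartment eigenvector
#'
#' Per chromosome: gene midpoints of each label are counted in fixed
#' non-overlapping bins of `bin_bp`; the track is re-binned onto the same grid
#' by length-weighted averaging; the per-bin counts are correlated with the
#' per-bin eigenvector values. With the A-compartment-positive sign
#' convention, constitutive-gene density correlates positively and
#' repressed-gene density negatively.
#'
#' @param catalog a [gene_catalog()].
#' @param labels named vector of per-gene labels (e.g. expression classes).
#' @param track a [genomic_track()] (eigenvector values).
#' @param bin_bp fixed bin width in bp (default 500 kb, the Hi-C analysis
#'   bin).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with `chrom`, `label`, `rho`, `n_bins`, `reliable`
#'   (`FALSE` when a chromosome has fewer than 5 bins).
#' @export
compartment_correlation <- function(catalog, labels, track,
                                    bin_bp = 500000L,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mid <- .gene_midpoints(catalog)
  lab <- as.character(labels[catalog$gene_id])
  out <- list()
  for (ch in intersect(unique(catalog$chrom), unique(track$chrom))) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    L <- max(max(tr$end), max(catalog$end[catalog$chrom == ch]))
    n_bins <- ceiling(L / bin_bp)
    breaks <- c(0, seq_len(n_bins) * bin_bp)
    # length-weighted average of track values per bin
    ev <- numeric(n_bins); wsum <- numeric(n_bins)
    for (i in seq_len(nrow(tr))) {
      b0 <- max(1L, ceiling(tr$start[i] / bin_bp))
      b1 <- min(n_bins, ceiling(tr$end[i] / bin_bp))
      for (b in b0:b1) {
        ov <- min(tr$end[i], b * bin_bp) - max(tr$start[i], (b - 1) * bin_bp + 1) + 1
        if (ov > 0) { ev[b] <- ev[b] + ov * tr$value[i]; wsum[b] <- wsum[b] + ov }
      }
    }
    covered <- wsum > 0
    ev[covered] <- ev[covered] / wsum[covered]
    for (lv in unique(stats::na.omit(lab))) {
      gm <- mid[catalog$chrom == ch & !is.na(lab) & lab == lv]
      counts <- tabulate(pmin(n_bins, ceiling(gm / bin_bp)), nbins = n_bins)
      use <- covered
      rho <- if (sum(use) >= 3L && sd(counts[use]) > 0 && sd(ev[use]) > 0) {
        cor(counts[use], ev[use], method = method)
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, label = lv, rho = rho, n_bins = sum(use),
        reliable = sum(use) >= 5L, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
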