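#' @importFrom stats cor lm.fit optimize phyper prcomp qchisq quantile rbeta
#'   rbinom rnorm runif sd setNames uniroot var rlnorm
#' @importFrom utils head
NULL

CONDITIONS <- c("control", "salt")

# ---- sample labels -----------------------------------------------------------

#' Parse canonical sample labels
#'
#' Sample labels follow the dialect `<genotype>__<condition>__rep<k>` with
#' `condition` one of `control` or `salt` and `k` a positive integer.
#'
#' @param labels character vector of sample labels.
#' @return data.frame with columns `sample_id`, `genotype_id`, `condition`,
#'   `replicate`.
#' @export
parse_sample_labels <- function(labels) {
  parts <- strsplit(labels, "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed sample label(s), expected '<genotype>__<condition>__rep<k>': ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  genotype <- vapply(parts, `[[`, "", 1L)
  condition <- vapply(parts, `[[`, "", 2L)
  reptok <- vapply(parts, `[[`, "", 3L)
  bad <- !grepl("^rep[0-9]+$", reptok) | !(condition %in% CONDITIONS) |
    !nzchar(genotype)
  if (any(bad)) {
    stop("malformed sample label(s) in column(s): ",
         paste(labels[bad], collapse = ", "),
         " (need condition in {control, salt} and a 'rep<k>' token)",
         call. = FALSE)
  }
  data.frame(
    sample_id = labels,
    genotype_id = genotype,
    condition = condition,
    replicate = as.integer(sub("^rep", "", reptok)),
    stringsAsFactors = FALSE
  )
}

# ---- expression matrix -------------------------------------------------------

#' Construct an expression matrix from raw TPM values
#'
#' Zero TPM defines the missing mask (no pseudocount is added); all non-zero
#' cells are stored as log2(TPM). The raw TPM matrix is retained so that
#' writing the object back to disk reproduces the input exactly.
#'
#' @param tpm numeric matrix of raw TPM (genes x samples), non-negative.
#' @param samples data.frame as returned by [parse_sample_labels()].
#' @param gene_ids character vector of unique gene identifiers.
#' @return an object of class `expression_matrix` with elements `values`
#'   (log2 TPM, `NA` under the mask), `mask` (logical, `TRUE` where TPM == 0),
#'   `tpm` (raw TPM), `samples`, `gene_ids`.
#' @export
expression_matrix <- function(tpm, samples, gene_ids) {
  tpm <- as.matrix(tpm)
  storage.mode(tpm) <- "double"
  if (anyNA(tpm)) stop("TPM matrix contains NA cells", call. = FALSE)
  if (any(tpm < 0)) stop("negative TPM values are not allowed", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  key <- paste(samples$genotype_id, samples$condition, samples$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, condition, replicate) sample keys", call. = FALSE)
  }
  if (nrow(tpm) != length(gene_ids) || ncol(tpm) != nrow(samples)) {
    stop("dimension mismatch between tpm, gene_ids and samples", call. = FALSE)
  }
  mask <- tpm == 0
  values <- log2(tpm)
  values[mask] <- NA_real_
  dimnames(values) <- dimnames(mask) <- dimnames(tpm) <-
    list(gene_ids, samples$sample_id)
  structure(
    list(values = values, mask = mask, tpm = tpm,
         samples = samples, gene_ids = as.character(gene_ids)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (%d genotypes; %.1f%% cells masked)\n",
    length(x$gene_ids), nrow(x$samples),
    length(unique(x$samples$genotype_id)), 100 * mean(x$mask)))
  invisible(x)
}

#' Read a gene x sample expression TSV
#'
#' The file has a `gene_id` first column and one column per sample labelled
#' `<genotype>__<condition>__rep<k>`; cells are raw TPM. Genotypes that do not
#' carry every observed condition x replicate combination are dropped with a
#' warning, matching the completeness rule applied to the study design.
#'
#' @param path path to the TSV file.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  gene_ids <- as.character(dt[[1L]])
  if (ncol(dt) < 2L) stop("expression file has no sample columns", call. = FALSE)
  samples <- parse_sample_labels(colnames(dt)[-1L])
  tpm <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(tpm) <- "double"

  combos <- unique(samples[, c("condition", "replicate")])
  need <- nrow(combos)
  have <- table(samples$genotype_id)
  complete <- names(have)[have == need]
  dropped <- setdiff(unique(samples$genotype_id), complete)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " genotype(s) without all condition x replicate samples: ",
            paste(head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "", call. = FALSE)
    keep <- samples$genotype_id %in% complete
    samples <- samples[keep, , drop = FALSE]
    tpm <- tpm[, keep, drop = FALSE]
  }
  expression_matrix(tpm, samples, gene_ids)
}

#' Write an expression matrix back to TSV as raw TPM
#'
#' Masked cells are written as 0; other cells reproduce the raw TPM values
#' bit-exactly (17 significant digits).
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  chr <- matrix(sprintf("%.17g", expr$tpm), nrow = nrow(expr$tpm))
  out <- cbind(gene_id = expr$gene_ids, as.data.frame(chr))
  colnames(out) <- c("gene_id", expr$samples$sample_id)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- genotype matrix ---------------------------------------------------------

#' Construct a genotype dosage matrix
#'
#' @param dosages numeric matrix (genotypes x markers) of alternate-allele
#'   dosages in `[0, 2]`; no missing values.
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp).
#' @return an object of class `genotype_matrix`; markers are sorted by
#'   (chrom, pos), with a message if the input order was changed.
#' @export
genotype_matrix <- function(dosages, markers) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (anyNA(dosages)) {
    stop("missing genotype calls: impute genotypes upstream before loading",
         call. = FALSE)
  }
  if (any(dosages < 0 | dosages > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (ncol(dosages) != nrow(markers)) stop("marker count mismatch", call. = FALSE)
  ord <- order(markers$chrom, markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    message("markers were not sorted by (chrom, pos); sorting")
    markers <- markers[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  rownames(markers) <- NULL
  colnames(dosages) <- markers$marker_id
  structure(
    list(dosages = dosages, markers = markers,
         genotype_ids = rownames(dosages)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d genotypes x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$markers$chrom))))
  invisible(x)
}

#' Read genotype dosages from TSV or VCF
#'
#' TSV layout: columns `marker_id`, `chrom`, `pos`, then one dosage column per
#' genotype. VCF: the GT field is converted to the count of alternate alleles
#' (`0/0` -> 0, `0/1` -> 1, `1/1` -> 2); any missing or half-missing call is an
#' error because the pipeline requires imputed input.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    if (ncol(dt) < 4L) stop("genotype TSV needs marker_id, chrom, pos + dosages",
                            call. = FALSE)
    markers <- data.frame(marker_id = as.character(dt[[1L]]),
                          chrom = as.character(dt[[2L]]),
                          pos = as.integer(dt[[3L]]),
                          stringsAsFactors = FALSE)
    dosages <- t(as.matrix(dt[, -(1:3), drop = FALSE]))
    genotype_matrix(dosages, markers)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (anyNA(gt) || any(grepl("\\.", gt))) {
      stop("missing genotype calls in VCF: impute genotypes upstream",
           call. = FALSE)
    }
    alleles <- gsub("[|/]", "", gt)
    if (any(!grepl("^[01]{2}$", alleles))) {
      stop("only biallelic diploid GT fields (alleles 0/1) are supported",
           call. = FALSE)
    }
    dos <- matrix(vapply(strsplit(alleles, ""),
                         function(a) sum(a == "1"), 0),
                  nrow = nrow(gt), dimnames = dimnames(gt))
    markers <- data.frame(marker_id = rownames(dos),
                          chrom = as.character(vcfR::getCHROM(v)),
                          pos = as.integer(vcfR::getPOS(v)),
                          stringsAsFactors = FALSE)
    if (any(!nzchar(markers$marker_id)) || anyNA(markers$marker_id)) {
      markers$marker_id <- paste0(markers$chrom, "_", markers$pos)
    }
    genotype_matrix(t(dos), markers)
  }
}

#' Write genotype dosages as TSV
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  out <- cbind(geno$markers, as.data.frame(t(geno$dosages)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- gene catalog ------------------------------------------------------------

#' Read gene coordinates from GFF3
#'
#' Only `gene` features are retained; coordinates keep the GFF3 1-based
#' inclusive convention, which is the internal convention everywhere in this
#' package. Strand is recorded but ignored by downstream positional logic.
#'
#' @param path path to a GFF3 file.
#' @return data.frame of class `gene_catalog` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_gene_catalog <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    warning("no 'gene' features found; returning an empty catalog",
            call. = FALSE)
    return(gene_catalog(data.frame(gene_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   strand = character())))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("gene feature(s) missing an ID attribute at line(s): ",
         paste(which(is.na(ids) | !nzchar(ids)), collapse = ", "),
         call. = FALSE)
  }
  gene_catalog(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  ))
}

#' Construct a gene catalog
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @return the validated data.frame with class `gene_catalog`.
#' @export
gene_catalog <- function(df) {
  if (is.null(df$strand)) df$strand <- "*"
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) && any(df$start > df$end)) stop("gene start > end", call. = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Write a gene catalog as GFF3
#' @param catalog a [gene_catalog()].
#' @param path output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  gr <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(catalog$start, catalog$end),
    strand = ifelse(catalog$strand %in% c("+", "-"), catalog$strand, "*"),
    type = "gene", ID = catalog$gene_id, source = "exprherit"
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- genomic tracks ----------------------------------------------------------

#' Construct a genomic interval track
#'
#' Internal coordinates are 1-based inclusive. Intervals on one chromosome
#' must not overlap.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param label track label, e.g. `"AB_eigenvector"` or `"pericentromere"`.
#' @return the validated data.frame with class `genomic_track` and a `label`
#'   attribute.
#' @export
genomic_track <- function(df, label = "track") {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
  if (is.null(df$value)) df$value <- 1.0
  if (nrow(df) && any(df$start > df$end)) stop("interval start > end", call. = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("overlapping intervals on chromosome ", ch, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df <- df[, c("chrom", "start", "end", "value")]
  attr(df, "label") <- label
  class(df) <- c("genomic_track", "data.frame")
  df
}

#' Read a BED or bedGraph interval track
#'
#' On-disk BED/bedGraph coordinates (0-based half-open) are converted to the
#' internal 1-based inclusive convention. A BED file without a value column
#' gets value 1.0 per interval.
#'
#' @param path input file; format inferred from the extension (`.bedgraph` /
#'   `.bg` vs `.bed`) unless `format` is given.
#' @param label track label.
#' @param format optional, `"bedGraph"` or `"bed"`.
#' @return a [genomic_track()].
#' @export
read_track <- function(path, label = "track", format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedGraph" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  value <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(1.0, length(gr))
  genomic_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    value = value,
    stringsAsFactors = FALSE
  ), label = label)
}

#' Write a track as bedGraph (value column) in 0-based half-open coordinates
#' @param track a [genomic_track()].
#' @param path output path.
#' @export
write_track <- function(track, path) {
  out <- data.frame(track$chrom,
                    sprintf("%d", as.integer(track$start - 1)),
                    sprintf("%d", as.integer(track$end)),
                    sprintf("%.17g", track$value))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
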