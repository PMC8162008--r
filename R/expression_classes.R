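# Expression classes defined by per-gene missingness. A gene's missing rate in
# a condition is the proportion of that condition's samples (replicates pooled)
# whose raw TPM is zero; the constitutive / mixed / repressed bands use strict
# inequalities at 5% and 95%.

#' Class thresholds for missingness-based expression classes
#'
#' @param constitutive_max_missing genes with missing rate strictly below this
#'   are constitutive (default 0.05).
#' @param repressed_min_missing genes with missing rate strictly above this are
#'   repressed (default 0.95).
#' @return a `class_thresholds` list.
#' @export
class_thresholds <- function(constitutive_max_missing = 0.05,
                             repressed_min_missing = 0.95) {
  if (!(0 < constitutive_max_missing &&
        constitutive_max_missing < repressed_min_missing &&
        repressed_min_missing < 1)) {
    stop("need 0 < constitutive_max_missing < repressed_min_missing < 1",
         call. = FALSE)
  }
  structure(list(constitutive_max_missing = constitutive_max_missing,
                 repressed_min_missing = repressed_min_missing),
            class = "class_thresholds")
}

EXPRESSION_CLASSES <- c("constitutive", "mixed", "repressed")

#' Per-gene missing rate within one condition (or pooled)
#'
#' @param expr an [expression_matrix()].
#' @param condition `"control"`, `"salt"`, or `"pooled"` for all samples.
#' @return named numeric vector, one rate in `[0, 1]` per gene.
#' @export
missing_rate <- function(expr, condition = c("control", "salt", "pooled")) {
  condition <- match.arg(condition)
  if (condition == "pooled") {
    sel <- rep(TRUE, nrow(expr$samples))
  } else {
    sel <- expr$samples$condition == condition
    if (!any(sel)) stop("condition '", condition, "' absent from samples",
                        call. = FALSE)
  }
  rowMeans(expr$mask[, sel, drop = FALSE])
}

#' Classify a missing rate into an expression class
#'
#' Boundary rates exactly at the thresholds classify as mixed (strict
#' inequalities on both sides).
#'
#' @param rate numeric vector of missing rates in `[0, 1]`.
#' @param th a [class_thresholds()].
#' @return factor with levels constitutive, mixed, repressed.
#' @export
classify_gene <- function(rate, th = class_thresholds()) {
  if (any(rate < 0 | rate > 1, na.rm = TRUE)) {
    stop("missing rate outside [0, 1]", call. = FALSE)
  }
  cls <- ifelse(rate < th$constitutive_max_missing, "constitutive",
                ifelse(rate > th$repressed_min_missing, "repressed", "mixed"))
  factor(cls, levels = EXPRESSION_CLASSES)
}

#' Per-gene, per-condition expression class table
#'
#' For each gene and condition: the missing rate, the expression class, and
#' the mean of the unmasked log2 TPM values (NA when every sample is masked).
#'
#' @param expr an [expression_matrix()].
#' @param th a [class_thresholds()].
#' @return data.frame of class `gene_class_table` with columns `gene_id`,
#'   `condition`, `missing_rate`, `class`, `mean_nonzero_log2tpm`.
#' @export
gene_class_table <- function(expr, th = class_thresholds()) {
  out <- do.call(rbind, lapply(CONDITIONS, function(cond) {
    rate <- missing_rate(expr, cond)
    sel <- expr$samples$condition == cond
    mu <- rowMeans(expr$values[, sel, drop = FALSE], na.rm = TRUE)
    mu[rate == 1] <- NA_real_
    data.frame(gene_id = expr$gene_ids, condition = cond,
               missing_rate = unname(rate),
               class = classify_gene(rate, th),
               mean_nonzero_log2tpm = unname(mu),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("gene_class_table", "data.frame")
  out
}

#' Cross-condition 3x3 contingency table of expression classes
#'
#' @param classes either a `gene_class_table` (both conditions present for
#'   every gene) or a data.frame with columns `gene_id`, `control`, `salt`
#'   holding class labels.
#' @return a `contingency_table`: 3x3 integer matrix (control rows x salt
#'   columns) with `row_totals`, `col_totals`, `grand_total` attributes.
#' @export
cross_tabulate <- function(classes) {
  if (inherits(classes, "gene_class_table")) {
    ctl <- classes[classes$condition == "control", c("gene_id", "class")]
    slt <- classes[classes$condition == "salt", c("gene_id", "class")]
    only <- c(setdiff(ctl$gene_id, slt$gene_id), setdiff(slt$gene_id, ctl$gene_id))
    if (length(only)) {
      stop("gene(s) classified in one condition only: ",
           paste(head(only, 10L), collapse = ", "), call. = FALSE)
    }
    wide <- merge(ctl, slt, by = "gene_id", suffixes = c("_control", "_salt"))
    control <- wide$class_control
    salt <- wide$class_salt
  } else {
    control <- classes$control
    salt <- classes$salt
    if (is.null(control) || is.null(salt)) {
      stop("need columns 'control' and 'salt'", call. = FALSE)
    }
  }
  control <- factor(control, levels = EXPRESSION_CLASSES)
  salt <- factor(salt, levels = EXPRESSION_CLASSES)
  if (anyNA(control) || anyNA(salt)) {
    stop("unknown class label(s)", call. = FALSE)
  }
  tab <- table(control = control, salt = salt)
  tab <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(control = EXPRESSION_CLASSES,
                                salt = EXPRESSION_CLASSES))
  structure(tab,
            row_totals = rowSums(tab), col_totals = colSums(tab),
            grand_total = sum(tab),
            class = c("contingency_table", "matrix"))
}

#' Symmetric between-class transition count
#'
#' `transitions(tab, A, B)` is the number of genes that switched class between
#' conditions in either direction: cell(A -> B) + cell(B -> A).
#'
#' @param tab a [cross_tabulate()] result.
#' @param from,to class names.
#' @return integer count.
#' @export
transitions <- function(tab, from, to) {
  stopifnot(inherits(tab, "contingency_table"))
  from <- match.arg(from, EXPRESSION_CLASSES)
  to <- match.arg(to, EXPRESSION_CLASSES)
  if (from == to) return(unclass(tab)[from, to])
  unclass(tab)[from, to] + unclass(tab)[to, from]
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  attr(m, "row_totals") <- attr(m, "col_totals") <- attr(m, "grand_total") <- NULL
  full <- rbind(cbind(m, total = attr(x, "row_totals")),
                total = c(attr(x, "col_totals"), attr(x, "grand_total")))
  print(full)
  invisible(x)
}
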