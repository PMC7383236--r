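#' Pre-filter a gene-count table by detection support
#'
#' Keeps genes with at least `min_count` sequence fragments in at least
#' `min_samples` of the samples (the standard pre-filter applied before
#' differential-expression analysis: >= 5 fragments in >= 2 of the 8
#' samples).
#'
#' @param counts Integer matrix genes x samples (a `count_table` or plain
#'   matrix/data.frame).
#' @param min_count Minimal per-sample count.
#' @param min_samples Minimal number of samples meeting `min_count`.
#' @return The filtered table (same class/attributes where possible).
#' @export
filter_genes <- function(counts, min_count = 5, min_samples = 2) {
  m <- as.matrix(counts)
  if (nrow(m) == 0) return(counts)
  keep <- rowSums(m >= min_count) >= min_samples
  out <- m[keep, , drop = FALSE]
  if (inherits(counts, "count_table"))
    out <- structure(out, class = class(counts),
                     pairing = attr(counts, "pairing"),
                     ground_truth = attr(counts, "ground_truth"))
  out
}

#' Normalize counts to UV-opsin expression
#'
#' Divides every sample (column) by that sample's UV-opsin count, putting
#' all genes on a per-opsin expression scale; the opsin row itself becomes
#' 1 in every sample, and the normalization is invariant to per-sample
#' sequencing depth.
#'
#' @param counts Matrix genes x samples with an opsin row.
#' @param opsin Row name (or index) of the UV-opsin gene.
#' @return Numeric matrix of opsin-normalized expression.
#' @export
normalize_to_opsin <- function(counts, opsin = "opsin") {
  m <- as.matrix(counts)
  if (is.character(opsin) && !opsin %in% rownames(m))
    stop("opsin row '", opsin, "' not found", call. = FALSE)
  op <- m[opsin, ]
  zero <- which(op <= 0)
  if (length(zero))
    stop("zero opsin count in sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  out <- sweep(m, 2L, op, "/")
  attr(out, "pairing") <- attr(counts, "pairing")
  out
}

#' Mean pairwise SZ/non-SZ fold change per gene
#'
#' Computes, for each gene, the fold change within each paired SZ /
#' non-SZ sample (same eye/batch), and reports the arithmetic mean of the
#' per-pair ratios with its standard error. Pairs with a zero denominator
#' are excluded with a warning.
#'
#' @param normalized Matrix genes x samples (typically opsin-normalized).
#' @param pairing Data.frame with columns `sz` and `nonsz` naming the
#'   paired sample columns; defaults to the table's `pairing` attribute.
#' @return Data.frame: `gene`, `mean_fold`, `se`, `n_pairs`.
#' @export
pairwise_fold_change <- function(normalized, pairing = NULL) {
  m <- as.matrix(normalized)
  if (is.null(pairing)) pairing <- attr(normalized, "pairing")
  if (is.null(pairing))
    stop("`pairing` required (columns sz, nonsz)", call. = FALSE)
  ratios <- matrix(NA_real_, nrow(m), nrow(pairing))
  for (p in seq_len(nrow(pairing))) {
    den <- m[, pairing$nonsz[p]]
    r <- m[, pairing$sz[p]] / den
    r[den == 0] <- NA
    ratios[, p] <- r
  }
  if (anyNA(ratios))
    warning("pairs with zero denominator excluded from the mean")
  mf <- rowMeans(ratios, na.rm = TRUE)
  npair <- rowSums(!is.na(ratios))
  se <- apply(ratios, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
  })
  data.frame(gene = rownames(m) %||% seq_len(nrow(m)),
             mean_fold = mf, se = se, n_pairs = npair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SZ/non-SZ expression scaling of cascade components
#'
#' Relative (SZ over non-SZ) expression ratios of the tunable cascade
#' components. The transducin ratio is taken as the lowest ratio among its
#' subunits (gngt2b, gnb3b, gnat2) because all subunits are required for
#' function; the CNG channel follows cnga3.
#'
#' @param transducin_subunits Named or unnamed numeric ratios for the
#'   transducin subunits; the minimum is used.
#' @param gc3 Guanylate-cyclase-3 ratio.
#' @param rec2 Recoverin-2 ratio.
#' @param cnga3 CNG-channel alpha-subunit ratio.
#' @return An `expression_scaling` object: list with elements `transducin`,
#'   `gc3`, `rec2`, `cng`.
#' @export
expression_scaling <- function(transducin_subunits = c(gngt2b = 1, gnb3b = 1,
                                                       gnat2 = 1),
                               gc3 = 1, rec2 = 1, cnga3 = 1) {
  vals <- c(unlist(transducin_subunits), gc3 = gc3, rec2 = rec2,
            cnga3 = cnga3)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("expression ratios must be positive", call. = FALSE)
  structure(list(transducin = min(transducin_subunits), gc3 = gc3,
                 rec2 = rec2, cng = cnga3,
                 transducin_subunits = transducin_subunits),
            class = "expression_scaling")
}

#' Derive an expression scaling from a count table
#'
#' Convenience constructor: opsin-normalizes a paired count table, takes
#' mean pairwise SZ/non-SZ fold changes, and extracts the ratios of the
#' four tunable components by gene name.
#'
#' @param counts A `count_table` (or matrix with `pairing` attribute).
#' @param genes Named list mapping component names to row names:
#'   `transducin` (character vector of subunits), `gc3`, `rec2`, `cnga3`.
#' @param opsin Opsin row name.
#' @return An [expression_scaling()].
#' @export
scaling_from_counts <- function(counts,
                                genes = list(
                                  transducin = c("gngt2b", "gnb3b", "gnat2"),
                                  gc3 = "gc3", rec2 = "rec2",
                                  cnga3 = "cnga3"),
                                opsin = "opsin") {
  norm <- normalize_to_opsin(counts, opsin = opsin)
  fc <- pairwise_fold_change(norm, pairing = attr(counts, "pairing"))
  need <- unlist(genes)
  missing <- setdiff(need, fc$gene)
  if (length(missing))
    stop("count table lacks required gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  get <- function(g) fc$mean_fold[match(g, fc$gene)]
  tr <- get(genes$transducin)
  names(tr) <- genes$transducin
  expression_scaling(transducin_subunits = tr, gc3 = get(genes$gc3),
                     rec2 = get(genes$rec2), cnga3 = get(genes$cnga3))
}

#' Scale cascade parameters by expression ratios
#'
#' Applies an [expression_scaling()] to a [cascade_params()] set: the
#' transducin gain is multiplied by the minimal subunit ratio, the maximal
#' cyclase rate by the GC3 ratio, the recoverin weight by the Rec2 ratio,
#' and the CNG maximal current by the cnga3 ratio. All other parameters
#' are untouched, so scaling with all ratios at 1 is the identity and the
#' composition of two scalings equals scaling by the product.
#'
#' @param base A [cascade_params()] set.
#' @param scaling An [expression_scaling()].
#' @return A new `cascade_params`.
#' @export
scale_params_from_expression <- function(base, scaling) {
  stopifnot(inherits(base, "cascade_params"),
            inherits(scaling, "expression_scaling"))
  p <- unclass(base)
  p$nu_re <- p$nu_re * scaling$transducin
  p$alpha_max <- p$alpha_max * scaling$gc3
  p$w_rec <- p$w_rec * scaling$rec2
  p$j_max <- p$j_max * scaling$cng
  do.call(cascade_params, p[setdiff(names(p), "transducin_subunits")])
}

#' Illustrative strike-zone scaling (synthetic example)
#'
#' A synthetic example scaling in the qualitative direction of the
#' strike-zone phenotype (transducin and CNG down, GC3 up, recoverin
#' down). The true numeric ratios live with the study's deposited data and
#' should be supplied via [expression_scaling()] or
#' [scaling_from_counts()]; these values are for demonstration only.
#'
#' @return An [expression_scaling()].
#' @export
example_sz_scaling <- function() {
  expression_scaling(transducin_subunits = c(gngt2b = 0.5, gnb3b = 0.8,
                                             gnat2 = 0.7),
                     gc3 = 2.0, rec2 = 0.5, cnga3 = 0.6)
}
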