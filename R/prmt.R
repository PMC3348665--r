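# --- enzyme activity counts --------------------------------------------------

#' Turn read counts into enzyme activity counts
#'
#' The default `log2p1` transform, EAC = log2(count + 1), keeps the
#' heavy-tailed functional-gene counts comparable across orders of magnitude
#' and makes downstream differences log-fold-like; `raw` keeps the counts as
#' they are. Every published claim the package tests holds under either
#' transform.
#'
#' @param counts numeric matrix, rows = enzyme functions, columns = samples,
#'   non-negative integer read counts (class `count_table` accepted).
#' @param transform `"log2p1"` or `"raw"`.
#' @return Matrix of class `eac_table` with attribute `transform`.
#' @export
compute_eac <- function(counts, transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  counts <- unclass(counts)
  if (any(counts < 0)) stop("negative read count")
  eac <- if (transform == "log2p1") log2(counts + 1) else counts + 0
  structure(eac, transform = transform, class = c("eac_table", class(eac)))
}

# --- quantile normalization --------------------------------------------------

#' Quantile-normalize enzyme activity counts across samples
#'
#' Makes every sample's value distribution identical: the reference
#' distribution is the element-wise mean of the descending-sorted per-sample
#' vectors (the highest value in each sample becomes the mean of the highest
#' values, the second highest the mean of the second highest, and so on), and
#' each sample's values are replaced by the reference value at their
#' within-sample rank. Tied values receive the mean of the reference values
#' spanning the tied ranks. Idempotent, and invariant to sample order.
#'
#' @param eac an `eac_table` (or numeric matrix), rows = enzyme functions,
#'   columns = samples; at least two samples.
#' @return Matrix of class `neac_table`; the descending reference
#'   distribution is stored in attribute `reference_distribution`.
#' @export
quantile_normalize <- function(eac) {
  transform <- attr(eac, "transform") %||% "raw"
  X <- unclass(eac)
  if (is.null(dim(X)) || ncol(X) < 2L) {
    stop("quantile normalization needs at least two samples; ",
         "with a single sample skip normalization and use the EAC directly")
  }
  sorted <- apply(X, 2L, sort, decreasing = FALSE)   # ascending per sample
  ref <- rowMeans(sorted)                            # ascending reference
  out <- X
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    assigned <- ref[rank(x, ties.method = "first")]
    # ties share the mean of the reference values spanning their ranks
    out[, j] <- stats::ave(assigned, match(x, x), FUN = mean)
  }
  structure(out, transform = transform,
            reference_distribution = rev(ref),
            class = c("neac_table", class(out)))
}

#' Reference profile for PRMT scoring
#'
#' Element-wise arithmetic mean of the normalized enzyme activity profiles
#' over all samples (the original study averaged its January, April and
#' August samples), or over a named subset.
#'
#' @param neac an `neac_table` (or numeric matrix, rows = enzyme functions).
#' @param samples optional character vector of sample (column) names to
#'   average; default all.
#' @return Named numeric vector, one value per enzyme function.
#' @export
reference_neac <- function(neac, samples = NULL) {
  X <- unclass(neac)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(X))
    if (length(missing) > 0L) {
      stop("unknown reference sample(s): ", paste(missing, collapse = ", "))
    }
    X <- X[, samples, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("empty sample set for reference")
  rowMeans(X)
}

# --- PRMT scores -------------------------------------------------------------

#' Compute PRMT scores
#'
#' For each sample x, the score vector is `-(M %*% (nEAC_x - reference))`
#' under the default consumption-positive convention: a relative increase in
#' the abundance of enzymes consuming a metabolite yields a positive score
#' (greater predicted turnover/consumption), an increase in producers a
#' negative score (relative accumulation). `production-positive` drops the
#' negation. Scores are unit-less and relative — they never predict net
#' production or consumption.
#'
#' Enzyme labels of `M` and `neac` are aligned by name; labels present on one
#' side only are reported in a message and contribute nothing (an enzyme
#' absent from the catalog has no reactions; an enzyme absent from the counts
#' has no abundance change).
#'
#' @param M the environmental metabolome matrix ([normalize_emm()]).
#' @param neac an `neac_table` (rows = enzyme functions, cols = samples).
#' @param reference reference profile (named vector from [reference_neac()]);
#'   default: mean over all samples of `neac`.
#' @param sign_convention `"consumption-positive"` (default) or
#'   `"production-positive"`.
#' @return Matrix of class `prmt_table`, rows = metabolites, columns =
#'   samples; attributes `reference` and `sign_convention`.
#' @export
prmt_scores <- function(M, neac, reference = NULL,
                        sign_convention = c("consumption-positive",
                                            "production-positive")) {
  sign_convention <- match.arg(sign_convention)
  X <- unclass(neac)
  if (is.null(rownames(X)) || is.null(colnames(unclass(M)))) {
    stop("both the EMM columns and the nEAC rows must carry enzyme labels")
  }
  if (is.null(reference)) reference <- reference_neac(neac)
  if (is.null(names(reference))) {
    if (length(reference) != nrow(X)) {
      stop("unnamed reference must match the nEAC enzyme dimension")
    }
    names(reference) <- rownames(X)
  }
  Mm <- unclass(M)
  common <- intersect(colnames(Mm), rownames(X))
  if (length(common) == 0L) stop("no enzyme labels shared between EMM and nEAC")
  only_m <- setdiff(colnames(Mm), rownames(X))
  only_x <- setdiff(rownames(X), colnames(Mm))
  if (length(only_m) + length(only_x) > 0L) {
    message(length(only_m), " EMM enzyme(s) without counts and ",
            length(only_x), " counted enzyme(s) without reactions ignored")
  }
  missing_ref <- setdiff(common, names(reference))
  if (length(missing_ref) > 0L) {
    stop("reference lacks enzyme(s): ", paste(missing_ref, collapse = ", "))
  }
  delta <- X[common, , drop = FALSE] - reference[common]
  scores <- Mm[, common, drop = FALSE] %*% delta
  if (sign_convention == "consumption-positive") scores <- -scores
  structure(scores, reference = reference[common],
            sign_convention = sign_convention,
            class = c("prmt_table", class(unclass(scores))))
}

#' @export
print.prmt_table <- function(x, ...) {
  cat(sprintf("prmt_table: %d metabolites x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "sign_convention")))
  invisible(x)
}

#' @export
summary.prmt_table <- function(object, ...) {
  X <- unclass(object)
  data.frame(sample = colnames(X),
             min = apply(X, 2L, min),
             median = apply(X, 2L, stats::median),
             max = apply(X, 2L, max),
             n_positive = colSums(X > 0),
             n_negative = colSums(X < 0),
             row.names = NULL)
}
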