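# --- parameter transforms ----------------------------------------------------

#' Log relative abundance of environmental parameters
#'
#' Each measured series is expressed relative to its own across-sample mean:
#' value <- log2(x / mean(x)). The transformed series is what gets correlated
#' with PRMT scores; because Pearson correlation is invariant to positive
#' affine maps, the log base is immaterial. Non-positive measurements are an
#' error unless a pseudocount policy is enabled, in which case `x + eps` is
#' used with a warning (default eps: half the smallest positive observed
#' value in the series).
#'
#' @param params numeric matrix, rows = parameters, columns = samples (class
#'   `parameter_table` accepted), or a single numeric vector.
#' @param pseudocount `NA` (default: error on non-positive values), a positive
#'   number, or `"auto"`.
#' @return Transformed object of the same shape.
#' @export
log_relative_abundance <- function(params, pseudocount = NA) {
  cls <- attr(params, "parameter_class")
  vec <- is.null(dim(params))
  X <- if (vec) matrix(params, nrow = 1L,
                       dimnames = list("x", names(params))) else unclass(params)
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    if (any(x <= 0)) {
      if (is.na(pseudocount[1L]) || identical(pseudocount, FALSE)) {
        bad <- which(x <= 0)[1L]
        stop(sprintf("non-positive measurement for parameter '%s', sample '%s'",
                     rownames(X)[i],
                     colnames(X)[bad] %||% as.character(bad)))
      }
      eps <- if (identical(pseudocount, "auto")) {
        pos <- x[x > 0]
        if (length(pos) == 0L) 1e-6 else min(pos) * 0.5
      } else as.numeric(pseudocount)
      warning(sprintf("parameter '%s': non-positive value(s); pseudocount %g applied",
                      rownames(X)[i], eps))
      x <- x + eps
    }
    out[i, ] <- log2(x / mean(x))
  }
  if (vec) return(drop(out))
  if (!is.null(cls)) attr(out, "parameter_class") <- cls
  out
}

# --- correlation -------------------------------------------------------------

#' Pearson correlation with explicit degenerate-series handling
#'
#' @param a,b numeric series of equal length >= 3.
#' @return The product-moment correlation, or `NA_real_` when either series
#'   has zero variance (the degenerate case is signalled, not silently 0).
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "pearson")
}

#' All pairwise correlations between two series sets
#'
#' @param setA,setB numeric matrices with rows = series over identical,
#'   aligned sample columns.
#' @return data.frame with columns `id_a`, `id_b`, `pcc` (`NA` for
#'   zero-variance pairs, which are excluded from any network).
#' @export
correlate_sets <- function(setA, setB) {
  setA <- as_series_matrix(setA); setB <- as_series_matrix(setB)
  grid <- expand.grid(a = seq_len(nrow(setA)), b = seq_len(nrow(setB)))
  pcc <- mapply(function(i, j) {
    if (stats::sd(setA[i, ]) == 0 || stats::sd(setB[j, ]) == 0) NA_real_
    else stats::cor(setA[i, ], setB[j, ])
  }, grid$a, grid$b)
  data.frame(id_a = rownames(setA)[grid$a], id_b = rownames(setB)[grid$b],
             pcc = pcc, stringsAsFactors = FALSE)
}

as_series_matrix <- function(x) {
  X <- unclass(x)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list("x", names(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("series", seq_len(nrow(X)))
  X
}

# --- resampling null ---------------------------------------------------------

#' Resampling null distribution of correlation coefficients
#'
#' With only a handful of samples, analytic significance of a Pearson
#' coefficient is unreliable, so an empirical null is built instead: each
#' iteration draws one series from each set uniformly at random, permutes the
#' sample order of the second series uniformly over all permutations, and
#' records the correlation. The scheme preserves each series' marginal
#' distribution while destroying the sample pairing. Degenerate
#' (zero-variance) draws are redrawn up to a bounded number of retries.
#'
#' @param setA,setB series matrices (rows = series, columns = aligned samples).
#' @param iterations number of resamplings (the original analysis used 10000).
#' @param seed integer seed; the distribution is reproducible given the seed.
#' @return Object of class `null_distribution`: list with sorted `values`,
#'   `iterations`, `seed`.
#' @export
build_null <- function(setA, setB, iterations = 10000L, seed = 1L) {
  if (iterations < 1L) stop("iterations must be >= 1")
  setA <- as_series_matrix(setA); setB <- as_series_matrix(setB)
  ns <- ncol(setA)
  if (ncol(setB) != ns) stop("sample dimensions differ between sets")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  values <- numeric(iterations)
  for (k in seq_len(iterations)) {
    r <- NA_real_
    for (try in 1:100) {
      a <- setA[sample.int(nrow(setA), 1L), ]
      b <- setB[sample.int(nrow(setB), 1L), ][sample.int(ns)]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) { r <- stats::cor(a, b); break }
    }
    if (is.na(r)) stop("could not draw a non-degenerate series pair in 100 tries")
    values[k] <- r
  }
  structure(list(values = sort(values), iterations = iterations, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.05, 0.5, 0.95))
  cat(sprintf("null_distribution: %d resamplings (seed %d); 5th/50th/95th pct = %.3f / %.3f / %.3f\n",
              x$iterations, x$seed, q[1L], q[2L], q[3L]))
  invisible(x)
}

#' Flag strong correlations against a resampling null
#'
#' An observed coefficient is called strong when it falls in the top or
#' bottom 5th percentile of the null (boundary inclusive). Percentiles use
#' the linear-interpolation convention of `stats::quantile(type = 7)`.
#'
#' @param observed data.frame with a `pcc` column (as from
#'   [correlate_sets()]); `NA` coefficients are never flagged.
#' @param null a `null_distribution`.
#' @param lower,upper tail probabilities (defaults 0.05 / 0.95).
#' @return `observed` with added columns `percentile` (fraction of null values
#'   <= pcc), `strong` (logical) and `sign` (`"positive"`/`"negative"`/`NA`).
#' @export
classify_strong <- function(observed, null, lower = 0.05, upper = 0.95) {
  stopifnot(inherits(null, "null_distribution"))
  if (length(null$values) == 0L) stop("empty null distribution")
  thresholds <- stats::quantile(null$values, c(lower, upper), type = 7,
                                names = FALSE)
  pcc <- observed$pcc
  ecdf_vals <- vapply(pcc, function(r) {
    if (is.na(r)) NA_real_ else mean(null$values <= r)
  }, numeric(1))
  strong <- !is.na(pcc) & (pcc <= thresholds[1L] | pcc >= thresholds[2L])
  observed$percentile <- ecdf_vals
  observed$strong <- strong
  observed$sign <- ifelse(is.na(pcc), NA_character_,
                          ifelse(pcc >= 0, "positive", "negative"))
  attr(observed, "thresholds") <- thresholds
  observed
}

#' Joint probability of all coefficients lying in a band
#'
#' Fits a normal distribution to the reference (null) coefficient
#' distribution by sample mean and standard deviation, computes the normal
#' probability of one coefficient falling inside `[lo, hi]`, and raises it to
#' the number of observed coefficients — the chance that all of them land in
#' the band if they were independent draws from the fitted normal. Used to
#' argue that a set of individually non-strong coefficients is nevertheless
#' jointly improbable.
#'
#' @param observed_pccs numeric vector (only its length enters the result).
#' @param band numeric length-2, `lo < hi`.
#' @param reference a `null_distribution` or numeric vector of coefficients.
#' @return Single probability.
#' @export
joint_band_probability <- function(observed_pccs, band, reference) {
  if (length(band) != 2L || !(band[1L] < band[2L])) stop("band must be [lo, hi] with lo < hi")
  vals <- if (inherits(reference, "null_distribution")) reference$values else as.numeric(reference)
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma == 0) stop("degenerate reference distribution (sd = 0)")
  k <- length(observed_pccs)
  if (k == 0L) return(1)
  p1 <- stats::pnorm(band[2L], mu, sigma) - stats::pnorm(band[1L], mu, sigma)
  p1^k
}

# --- correlation network & subnetworks ---------------------------------------

#' Build the strong-correlation network
#'
#' Nodes are measurements (environmental metabolites, taxa, SEED subsystems,
#' PRMT metabolites), edges are strong correlations carrying their sign and
#' coefficient; weak or degenerate pairs never become edges, and the (A,B) /
#' (B,A) duplicates collapse to a single undirected edge.
#'
#' @param flagged output of [classify_strong()].
#' @param node_classes named character vector mapping node ids to a type
#'   (e.g. `"taxon-abundance"`); unmapped ids get `"unknown"`.
#' @return An undirected igraph graph with vertex attribute `type` and edge
#'   attributes `sign`, `pcc`, `interaction` (`"pos"`/`"neg"`).
#' @export
build_correlation_network <- function(flagged, node_classes = character(0)) {
  strong <- flagged[!is.na(flagged$pcc) & flagged$strong, , drop = FALSE]
  if (nrow(strong) > 0L) {
    key <- paste(pmin(strong$id_a, strong$id_b),
                 pmax(strong$id_a, strong$id_b), sep = "\r")
    strong <- strong[!duplicated(key), , drop = FALSE]
  }
  nodes <- unique(c(strong$id_a, strong$id_b))
  g <- igraph::graph_from_data_frame(
    strong[, c("id_a", "id_b", "pcc", "sign")],
    directed = FALSE, vertices = if (length(nodes)) data.frame(name = nodes) else NULL)
  if (length(nodes)) {
    igraph::V(g)$type <- unname(
      ifelse(nodes %in% names(node_classes), node_classes[nodes], "unknown"))
  }
  if (igraph::ecount(g) > 0L) {
    igraph::E(g)$interaction <- ifelse(igraph::E(g)$sign == "positive", "pos", "neg")
  }
  g
}

#' Extract taxon-correlated metabolic subnetworks
#'
#' For each taxon (phylum), keeps only the network edges joining two
#' metabolites whose scores both correlate strongly with that taxon's
#' relative abundance, then reports the connected components of the surviving
#' edge set — connected components imply partial or complete pathways rather
#' than isolated metabolites.
#'
#' @param net a `metabolic_network`.
#' @param strong_by_phylum named list: taxon -> character vector of strongly
#'   correlated metabolite ids. Ids absent from the network are reported in a
#'   message and ignored.
#' @return Object of class `subnetwork_set`: named list (per taxon) of
#'   components, each a list with `metabolites` and `n_enzyme_reactions`
#'   (reversible pairs counted once), sorted by size descending.
#' @export
extract_correlated_subnetworks <- function(net, strong_by_phylum) {
  stopifnot(inherits(net, "metabolic_network"))
  unknown <- setdiff(unique(unlist(strong_by_phylum)), net$nodes)
  if (length(unknown) > 0L) {
    message(length(unknown), " flagged metabolite(s) absent from the network ignored")
  }
  out <- lapply(strong_by_phylum, function(flagged) {
    e <- net$edges
    keep <- e$from %in% flagged & e$to %in% flagged
    e <- e[keep, , drop = FALSE]
    if (nrow(e) == 0L) return(list())
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to),
                 e$enzyme_id, e$reaction_id, sep = "\r")
    e <- e[!duplicated(key), , drop = FALSE]
    g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE)
    comp <- igraph::components(g)
    comps <- lapply(seq_len(comp$no), function(ci) {
      mets <- names(comp$membership)[comp$membership == ci]
      n_edges <- sum(comp$membership[e$from] == ci)
      list(metabolites = sort(mets), n_enzyme_reactions = n_edges)
    })
    comps[order(-vapply(comps, function(cc) length(cc$metabolites), integer(1)))]
  })
  structure(out, class = "subnetwork_set")
}

#' @export
print.subnetwork_set <- function(x, ...) {
  for (taxon in names(x)) {
    comps <- x[[taxon]]
    if (length(comps) == 0L) next
    cat(sprintf("%s: %d subnetwork(s); largest %d metabolites / %d enzyme reactions\n",
                taxon, length(comps), length(comps[[1L]]$metabolites),
                comps[[1L]]$n_enzyme_reactions))
  }
  invisible(x)
}
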