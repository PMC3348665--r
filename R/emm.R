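# --- metabolic network -------------------------------------------------------

#' Build the metabolite network
#'
#' One directed edge per (directed reaction, consumed metabolite, produced
#' metabolite) pair, labelled by the catalysing enzyme function. Reversible
#' reactions contribute edges in both directions; the network keeps both even
#' though their contributions cancel in the connectivity matrix, because the
#' topology (components, subnetwork extraction, visual export) needs them.
#'
#' @param directed a `directed_reactions` table from [expand_directions()].
#' @return An object of class `metabolic_network`: list with `nodes`
#'   (sorted metabolite ids) and `edges` (data.frame `from`, `to`,
#'   `enzyme_id`, `direction`, `reaction_id`).
#' @export
build_network <- function(directed) {
  stopifnot(inherits(directed, "directed_reactions"))
  n_pairs <- lengths(directed$consumed) * lengths(directed$produced)
  idx <- rep(seq_len(nrow(directed)), times = n_pairs)
  from <- unlist(lapply(seq_len(nrow(directed)), function(i) {
    rep(directed$consumed[[i]], each = length(directed$produced[[i]]))
  }))
  to <- unlist(lapply(seq_len(nrow(directed)), function(i) {
    rep(directed$produced[[i]], times = length(directed$consumed[[i]]))
  }))
  edges <- data.frame(from = as.character(from %||% character(0)),
                      to = as.character(to %||% character(0)),
                      enzyme_id = directed$enzyme_id[idx],
                      direction = directed$direction[idx],
                      reaction_id = directed$reaction_id[idx],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(unlist(c(directed$consumed, directed$produced))))
  structure(list(nodes = as.character(nodes %||% character(0)), edges = edges),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites, %d directed edges, %d enzyme functions\n",
              length(x$nodes), nrow(x$edges), length(unique(x$edges$enzyme_id))))
  invisible(x)
}

#' Convert a metabolic network to an igraph graph
#'
#' Edge attribute `interaction` is `"enzyme:<EC>"`, suitable for SIF export.
#' @param net a `metabolic_network`.
#' @return An igraph directed graph.
#' @export
as_igraph_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$interaction <- paste0("enzyme:", net$edges$enzyme_id)
  igraph::V(g)$type <- "metabolite"
  g
}

# --- connectivity matrix and EMM ---------------------------------------------

#' Build the raw connectivity matrix
#'
#' Rows are metabolites, columns unique enzyme functions; entry (i, j) is the
#' number of directed reactions of enzyme j that produce metabolite i minus
#' the number that consume it. Forward and reverse copies of a reversible
#' reaction are summed into the same column, so an enzyme whose reactions are
#' all reversible has an identically zero column — this is what makes PRMT
#' scores exactly invariant to abundance changes of such enzymes.
#'
#' @param directed a `directed_reactions` table.
#' @param enzyme_universe optional superset of enzyme ids; enzymes present in
#'   the count data but absent from the catalog get all-zero columns so that
#'   count vectors and the matrix stay dimensionally aligned.
#' @return Numeric matrix of class `connectivity_matrix`, rows and columns in
#'   lexicographic order.
#' @export
build_connectivity <- function(directed, enzyme_universe = NULL) {
  stopifnot(inherits(directed, "directed_reactions"))
  enzymes <- sort(unique(c(directed$enzyme_id, enzyme_universe)))
  mets <- sort(unique(unlist(c(directed$consumed, directed$produced))))
  C <- matrix(0, nrow = length(mets), ncol = length(enzymes),
              dimnames = list(mets, enzymes))
  for (i in seq_len(nrow(directed))) {
    e <- directed$enzyme_id[i]
    for (m in directed$produced[[i]]) C[m, e] <- C[m, e] + 1
    for (m in directed$consumed[[i]]) C[m, e] <- C[m, e] - 1
  }
  class(C) <- c("connectivity_matrix", class(C))
  C
}

#' Normalize a connectivity matrix into the environmental metabolome matrix
#'
#' Per metabolite (row): positive entries are divided by the row's positive
#' sum and negative entries by the absolute value of the row's negative sum,
#' so that inputs to a compound sum to 1 and outputs sum to -1. Rows lacking
#' one side normalize only the side present; all-zero rows stay zero.
#' Idempotent.
#'
#' @param C a `connectivity_matrix` (or any labelled numeric matrix).
#' @return Matrix of class `emm` with the same dimnames.
#' @export
normalize_emm <- function(C) {
  M <- unclass(C)
  pos <- pmax(M, 0)
  neg <- pmin(M, 0)
  pos_sum <- rowSums(pos)
  neg_sum <- rowSums(neg)  # <= 0
  pos_scale <- ifelse(pos_sum > 0, 1 / pos_sum, 0)
  neg_scale <- ifelse(neg_sum < 0, 1 / abs(neg_sum), 0)
  M <- pos * pos_scale + neg * neg_scale
  class(M) <- c("emm", class(unclass(C)))
  M
}

#' @export
print.emm <- function(x, ...) {
  cat(sprintf("emm: %d metabolites x %d enzyme functions (%.1f%% non-zero)\n",
              nrow(x), ncol(x), 100 * mean(unclass(x) != 0)))
  invisible(x)
}

#' Degree of each metabolite in the EMM
#'
#' Number of enzyme functions with a non-zero entry in the metabolite's row;
#' useful for interpreting a score in the context of the wider network.
#' @param M an `emm` or connectivity matrix.
#' @return Named integer vector.
#' @export
emm_degree <- function(M) {
  rowSums(unclass(M) != 0)
}

# --- connected components ----------------------------------------------------

#' Summarize connected components of the metabolite network
#'
#' Components of the undirected projection, sizes sorted descending. Edge
#' counts are per component; with `collapse_reversible = TRUE` (default) the
#' forward/reverse pair of a reversible reaction counts as one enzyme
#' reaction.
#'
#' @param net a `metabolic_network`.
#' @param collapse_reversible count a reversible pair as a single reaction.
#' @return Object of class `component_summary`: list with `sizes`
#'   (data.frame `nodes`, `edges`, descending by nodes), `n_components`,
#'   `n_two_node`.
#' @export
connected_components <- function(net, collapse_reversible = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (length(net$nodes) == 0L) {
    out <- list(sizes = data.frame(nodes = integer(0), edges = integer(0)),
                n_components = 0L, n_two_node = 0L)
    return(structure(out, class = "component_summary"))
  }
  g <- as_igraph_network(net)
  comp <- igraph::components(g, mode = "weak")
  edges <- net$edges
  if (collapse_reversible) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
                 edges$enzyme_id, edges$reaction_id, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edge_comp <- comp$membership[edges$from]
  edge_counts <- tabulate(edge_comp, nbins = comp$no)
  sizes <- data.frame(nodes = as.integer(comp$csize),
                      edges = as.integer(edge_counts))
  sizes <- sizes[order(-sizes$nodes, -sizes$edges), , drop = FALSE]
  rownames(sizes) <- NULL
  structure(list(sizes = sizes,
                 n_components = comp$no,
                 n_two_node = sum(sizes$nodes == 2L)),
            class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf("component_summary: %d components (%d two-node)\n",
              x$n_components, x$n_two_node))
  if (nrow(x$sizes) > 0L) {
    cat(sprintf("largest: %d metabolites, %d enzyme reactions\n",
                x$sizes$nodes[1L], x$sizes$edges[1L]))
  }
  invisible(x)
}

# --- serialization -----------------------------------------------------------

#' Write an EMM or connectivity matrix as TSV
#'
#' `format = "wide"` writes rows = metabolites with a header of enzyme ids;
#' `format = "triplets"` writes the sparse (metabolite, enzyme, value) form.
#'
#' @param M labelled numeric matrix (`emm` or `connectivity_matrix`).
#' @param path output path.
#' @param format `"wide"` or `"triplets"`.
#' @param header optional `#`-prefixed provenance lines.
#' @export
write_emm <- function(M, path, format = c("wide", "triplets"), header = NULL) {
  format <- match.arg(format)
  M <- unclass(M)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (format == "wide") {
    writeLines(paste(c("metabolite", colnames(M)), collapse = "\t"), con)
    body <- apply(M, 1L, function(row) paste(format_num(row), collapse = "\t"))
    writeLines(paste(rownames(M), body, sep = "\t"), con)
  } else {
    writeLines("metabolite\tenzyme_id\tvalue", con)
    nz <- which(M != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
    writeLines(paste(rownames(M)[nz[, 1L]], colnames(M)[nz[, 2L]],
                     format_num(M[nz]), sep = "\t"), con)
  }
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read an EMM written by [write_emm()]
#'
#' Auto-detects wide vs sparse-triplet layout from the header.
#' @param path path to the TSV.
#' @return Matrix of class `emm`.
#' @export
read_emm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (identical(header, c("metabolite", "enzyme_id", "value"))) {
    parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
    met <- vapply(parts, `[`, character(1), 1L)
    enz <- vapply(parts, `[`, character(1), 2L)
    val <- as.numeric(vapply(parts, `[`, character(1), 3L))
    mets <- sort(unique(met)); enzs <- sort(unique(enz))
    M <- matrix(0, length(mets), length(enzs), dimnames = list(mets, enzs))
    M[cbind(match(met, mets), match(enz, enzs))] <- val
  } else {
    parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
    mets <- vapply(parts, `[`, character(1), 1L)
    M <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
    dimnames(M) <- list(mets, header[-1L])
  }
  class(M) <- c("emm", class(unclass(M)))
  M
}
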