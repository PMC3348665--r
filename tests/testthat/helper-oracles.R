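# In-code fixtures and independent brute-force oracles used across the suite.

# numeric payload of a classed matrix, ignoring bookkeeping attributes
vals <- function(x) {
  a <- unclass(x)
  attributes(a) <- attributes(a)[intersect(names(attributes(a)),
                                           c("dim", "dimnames", "names"))]
  a
}

# Build a reaction catalog from a compact row description:
# list("R1", "1.1.1.1", "<=>", c("C1"), c("C2"), c("map00010"))
make_catalog <- function(...) {
  rows <- list(...)
  reactions <- data.frame(
    reaction_id = vapply(rows, `[[`, character(1), 1L),
    enzyme_id = vapply(rows, `[[`, character(1), 2L),
    reversible = vapply(rows, function(r) r[[3L]] == "<=>", logical(1)))
  reactions$substrates <- lapply(rows, `[[`, 4L)
  reactions$products <- lapply(rows, `[[`, 5L)
  reactions$pathways <- lapply(rows, function(r) {
    if (length(r) >= 6L) r[[6L]] else character(0)
  })
  reaction_catalog(reactions)
}

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force connectivity: per (metabolite, enzyme) cell, count matching
# directed reactions one cell at a time — deliberately the naive route.
oracle_connectivity <- function(directed, enzyme_universe = NULL) {
  enzymes <- sort(unique(c(directed$enzyme_id, enzyme_universe)))
  mets <- sort(unique(unlist(c(directed$consumed, directed$produced))))
  C <- matrix(0, length(mets), length(enzymes), dimnames = list(mets, enzymes))
  for (m in mets) {
    for (e in enzymes) {
      rows <- which(directed$enzyme_id == e)
      n_prod <- sum(vapply(rows, function(i) m %in% directed$produced[[i]], logical(1)))
      n_cons <- sum(vapply(rows, function(i) m %in% directed$consumed[[i]], logical(1)))
      C[m, e] <- n_prod - n_cons
    }
  }
  C
}

# naive row normalization, scalar loops only
oracle_normalize <- function(C) {
  M <- C
  for (i in seq_len(nrow(C))) {
    row <- C[i, ]
    ps <- sum(row[row > 0]); ns <- abs(sum(row[row < 0]))
    for (j in seq_along(row)) {
      if (row[j] > 0) M[i, j] <- row[j] / ps
      if (row[j] < 0) M[i, j] <- row[j] / ns
    }
  }
  M
}

# naive consumption-positive scoring: explicit double loop over the EMM
oracle_prmt <- function(catalog, neac, reference) {
  directed <- expand_directions(catalog)
  M <- oracle_normalize(oracle_connectivity(directed))
  X <- unclass(neac)
  enzymes <- intersect(colnames(M), rownames(X))
  scores <- matrix(0, nrow(M), ncol(X), dimnames = list(rownames(M), colnames(X)))
  for (s in colnames(X)) {
    for (m in rownames(M)) {
      acc <- 0
      for (e in enzymes) acc <- acc + M[m, e] * (X[e, s] - reference[e])
      scores[m, s] <- -acc
    }
  }
  scores
}

# a small random catalog for property tests, independent of generate_catalog
random_small_catalog <- function(seed, max_reactions = 50L, n_mets = 12L,
                                 n_enzymes = 8L) {
  set.seed(seed)
  mets <- sprintf("C%02d", seq_len(n_mets))
  enzymes <- sprintf("%d.%d.%d.%d", sample(1:6, n_enzymes, TRUE),
                     sample(1:9, n_enzymes, TRUE), sample(1:9, n_enzymes, TRUE),
                     seq_len(n_enzymes))
  k <- sample.int(max_reactions, 1L)
  rows <- lapply(seq_len(k), function(i) {
    subs <- sample(mets, sample(1:2, 1L))
    prods <- sample(setdiff(mets, subs), sample(1:2, 1L))
    list(sprintf("R%03d", i), sample(enzymes, 1L),
         if (runif(1) < 0.4) "<=>" else "=>", subs, prods,
         sample(c("map00010", "map00020"), 1L))
  })
  do.call(make_catalog, rows)
}

random_neac_like <- function(enzymes, samples, seed) {
  set.seed(seed)
  X <- matrix(stats::rlnorm(length(enzymes) * samples, 1, 1),
              length(enzymes), samples,
              dimnames = list(enzymes, sprintf("S%02d", seq_len(samples))))
  X
}
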