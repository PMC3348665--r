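# --- fixture specification ---------------------------------------------------

#' Specification for synthetic fixtures
#'
#' Describes a synthetic study: a random reaction catalog, per-sample enzyme
#' read counts with a heavy-tailed (rounded log-normal) distribution and
#' Bernoulli dropout, optional planted turnover signals (a fold-change on all
#' consumers or producers of a chosen metabolite in one sample), and
#' environmental parameters constructed to track chosen score series. The
#' defaults (100 metabolites, 200 enzyme functions, 3 samples) mirror a
#' seasonal three-time-point marine design at roughly one tenth of a real
#' EC-annotated enzyme universe.
#'
#' @param n_metabolites,n_enzymes,n_samples problem size.
#' @param reactions_per_enzyme integer range (min, max), sampled uniformly.
#' @param reversible_fraction probability a reaction is reversible.
#' @param count_meanlog,count_sdlog log-normal parameters of the per-enzyme
#'   baseline abundance (the heavy tail lives across enzymes, as in real
#'   functional-gene tables).
#' @param sample_sdlog2 standard deviation, in log2 units, of the
#'   within-enzyme between-sample variation around the baseline.
#' @param sparsity extra Bernoulli dropout probability on top of the Poisson
#'   zeros that low-abundance enzymes produce naturally (default 0).
#' @param planted_signals list of `list(metabolite=, sample=, direction=
#'   "consume"|"produce", fold=)`.
#' @param parameter_links list of `list(parameter_id=, metabolite=, slope=,
#'   noise_sd=, class=)`.
#' @param seed integer seed; every generator below is deterministic given it.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_metabolites = 100L, n_enzymes = 200L,
                         n_samples = 3L, reactions_per_enzyme = c(1L, 3L),
                         reversible_fraction = 0.3,
                         count_meanlog = 2, count_sdlog = 1.5,
                         sample_sdlog2 = 0.5,
                         sparsity = 0,
                         planted_signals = list(),
                         parameter_links = list(),
                         seed = 1L) {
  if (n_metabolites < 2L) stop("need at least 2 metabolites")
  if (n_enzymes < 1L) stop("need at least 1 enzyme function")
  if (n_metabolites < 4L && n_metabolites < sum(c(2L, 2L))) {
    stop("infeasible: reactions draw up to 2 substrates and 2 products, ",
         "which needs at least 4 metabolites")
  }
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_enzymes = as.integer(n_enzymes),
                 n_samples = as.integer(n_samples),
                 reactions_per_enzyme = as.integer(reactions_per_enzyme),
                 reversible_fraction = reversible_fraction,
                 count_meanlog = count_meanlog, count_sdlog = count_sdlog,
                 sample_sdlog2 = sample_sdlog2,
                 sparsity = sparsity,
                 planted_signals = planted_signals,
                 parameter_links = parameter_links,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

# --- catalog generation ------------------------------------------------------

#' Generate a random reaction catalog
#'
#' Each enzyme function catalyses 1 to a few reactions over 1-2 substrates
#' and 1-2 disjoint products drawn from the metabolite pool; a
#' `reversible_fraction` of reactions is reversible. Metabolite ids use a
#' synthetic `M###` scheme (never KEGG compound ids, so fixtures cannot
#' collide with the shipped currency-metabolite blacklist), enzyme ids a
#' synthetic EC-like scheme, and pathway tags a small `mapNNNNN` pool.
#'
#' @param spec a [fixture_spec()].
#' @return A [reaction_catalog()].
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    mets <- sprintf("M%04d", seq_len(spec$n_metabolites))
    enzymes <- sprintf("%d.%d.%d.%d",
                       sample(1:6, spec$n_enzymes, replace = TRUE),
                       sample(1:9, spec$n_enzymes, replace = TRUE),
                       sample(1:9, spec$n_enzymes, replace = TRUE),
                       seq_len(spec$n_enzymes))
    pathway_pool <- sprintf("map%05d", seq(10, 150, by = 10))
    rows <- list()
    for (j in seq_len(spec$n_enzymes)) {
      k <- sample(seq(spec$reactions_per_enzyme[1L],
                      spec$reactions_per_enzyme[2L]), 1L)
      for (r in seq_len(k)) {
        ns <- sample(1:2, 1L); np <- sample(1:2, 1L)
        subs <- sample(mets, ns)
        prods <- sample(setdiff(mets, subs), np)
        rows[[length(rows) + 1L]] <- list(
          reaction_id = sprintf("R%05d", length(rows) + 1L),
          enzyme_id = enzymes[j],
          reversible = stats::runif(1L) < spec$reversible_fraction,
          substrates = subs, products = prods,
          pathways = sample(pathway_pool, sample(1:2, 1L)))
      }
    }
    reactions <- data.frame(
      reaction_id = vapply(rows, `[[`, character(1), "reaction_id"),
      enzyme_id = vapply(rows, `[[`, character(1), "enzyme_id"),
      reversible = vapply(rows, `[[`, logical(1), "reversible"))
    reactions$substrates <- lapply(rows, `[[`, "substrates")
    reactions$products <- lapply(rows, `[[`, "products")
    reactions$pathways <- lapply(rows, `[[`, "pathways")
    reaction_catalog(reactions)
  })
}

#' Metabolites a signal can be planted on
#'
#' A consume signal needs at least one enzyme with net-consuming connectivity
#' for the metabolite (a purely reversible consumer cancels out and carries no
#' signal); likewise for produce signals. When `spec` is supplied the pool is
#' further restricted to metabolites with at least one such enzyme whose
#' baseline abundance reaches `min_baseline` expected reads — a turnover shift
#' is only identifiable when the enzymes carrying it are detectable, so the
#' benchmark plants signals where any power analysis would.
#'
#' @param catalog a `reaction_catalog`.
#' @param direction `"consume"` or `"produce"`.
#' @param spec optional [fixture_spec()]; enables the detectability filter.
#' @param min_baseline minimum baseline expected read count (default 4).
#' @return Character vector of metabolite ids.
#' @export
plantable_metabolites <- function(catalog, direction = c("consume", "produce"),
                                  spec = NULL, min_baseline = 4) {
  direction <- match.arg(direction)
  C <- unclass(build_connectivity(expand_directions(catalog)))
  signed <- if (direction == "consume") C < 0 else C > 0
  if (!is.null(spec)) {
    baseline <- enzyme_baseline(spec, colnames(C))
    signed <- signed & rep(baseline >= min_baseline, each = nrow(C))
  }
  rownames(C)[rowSums(signed) > 0]
}

#' Per-enzyme baseline abundance of a fixture
#'
#' The log-normal baseline that [generate_counts()] draws first; exposed so
#' callers can reason about detectability without re-generating counts.
#'
#' @param spec a [fixture_spec()].
#' @param enzymes enzyme ids in the order of `enzyme_universe(catalog)`.
#' @return Named numeric vector of expected read counts.
#' @export
enzyme_baseline <- function(spec, enzymes) {
  with_seed(spec$seed + 1L, {
    stats::setNames(stats::rlnorm(length(enzymes), spec$count_meanlog,
                                  spec$count_sdlog), enzymes)
  })
}

# --- count generation --------------------------------------------------------

#' Generate per-sample enzyme read counts
#'
#' Each enzyme gets a log-normal baseline abundance (heavy-tailed across
#' enzymes, as in real functional-gene tables); its expected count per sample
#' varies around that baseline by a log2-normal factor, and the observed
#' count is a Poisson draw from that intensity — so zeros arise naturally for
#' low-abundance enzymes, the way sequencing depth produces them. `sparsity`
#' adds optional abundance-independent dropout on top. Each planted signal
#' multiplies, in its target sample, the expected count of every enzyme whose
#' connectivity entry for the target metabolite has the signal's sign
#' (consumers for `"consume"`, producers for `"produce"`); with `fold = 1`
#' the output is identical to the unplanted table.
#'
#' @param catalog catalog from [generate_catalog()].
#' @param spec the same [fixture_spec()].
#' @return Integer matrix of class `count_table` (enzymes x samples).
#' @export
generate_counts <- function(catalog, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  enzymes <- enzyme_universe(catalog)
  with_seed(spec$seed + 1L, {
    E <- length(enzymes); S <- spec$n_samples
    baseline <- stats::rlnorm(E, spec$count_meanlog, spec$count_sdlog)
    lambda <- baseline * matrix(2 ^ stats::rnorm(E * S, 0, spec$sample_sdlog2),
                                E, S)
    dimnames(lambda) <- list(enzymes, sprintf("S%02d", seq_len(S)))
    dropout <- matrix(stats::runif(E * S) < spec$sparsity, E, S)
    if (length(spec$planted_signals) > 0L) {
      C <- build_connectivity(expand_directions(catalog))
      for (sig in spec$planted_signals) {
        met <- sig$metabolite
        if (!met %in% rownames(C)) stop("planted metabolite not in catalog: ", met)
        col <- unclass(C)[met, ]
        target <- if (sig$direction == "consume") names(col)[col < 0]
                  else names(col)[col > 0]
        if (length(target) == 0L) {
          stop("no net ", sig$direction, "rs of ", met, " to plant on")
        }
        lambda[target, sig$sample] <- lambda[target, sig$sample] * sig$fold
      }
    }
    X <- matrix(stats::rpois(E * S, lambda), E, S, dimnames = dimnames(lambda))
    X[dropout] <- 0L
    storage.mode(X) <- "integer"
    structure(X, class = c("count_table", class(X)))
  })
}

# --- parameter generation ----------------------------------------------------

#' Generate environmental parameters linked to score series
#'
#' Each linked parameter is `2 ^ (slope * score_series + noise)` — strictly
#' positive, and by construction its log relative abundance is a positive
#' affine image of `slope * score + noise`, so its Pearson correlation with
#' the score series has known expected sign (exactly +/- 1 at zero noise).
#'
#' @param prmt a `prmt_table`.
#' @param spec the [fixture_spec()] carrying `parameter_links`.
#' @return A `parameter_table` (rows = parameters, columns = samples).
#' @export
generate_parameters <- function(prmt, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  links <- spec$parameter_links
  if (length(links) == 0L) stop("fixture spec has no parameter links")
  X <- unclass(prmt)
  with_seed(spec$seed + 2L, {
    values <- do.call(rbind, lapply(links, function(lk) {
      z <- X[lk$metabolite, ]
      2 ^ (lk$slope * z + stats::rnorm(length(z), 0, lk$noise_sd))
    }))
    ids <- vapply(links, `[[`, character(1), "parameter_id")
    cls <- vapply(links, function(lk) lk$class %||% "environmental-metabolite",
                  character(1))
    dimnames(values) <- list(ids, colnames(X))
    names(cls) <- ids
    structure(values, parameter_class = cls,
              class = c("parameter_table", class(values)))
  })
}
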