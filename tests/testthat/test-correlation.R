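# Log relative abundance, Pearson correlation, the resampling null,
# strong-correlation calls, joint band probability and subnetworks.

test_that("log relative abundance is log2 of the ratio to the series mean", {
  expect_equal(log_relative_abundance(c(a = 5, b = 5, c = 5)),
               c(a = 0, b = 0, c = 0))
  got <- log_relative_abundance(c(1, 2, 4))
  expect_equal(unname(got), log2(c(3 / 7, 6 / 7, 12 / 7)))  # mean is 7/3

  X <- rbind(p1 = c(1, 2, 4), p2 = c(10, 10, 10))
  colnames(X) <- c("s1", "s2", "s3")
  out <- log_relative_abundance(X)
  expect_equal(unname(out["p2", ]), c(0, 0, 0))

  withzero <- rbind(p = c(0, 2, 4)); colnames(withzero) <- c("s1", "s2", "s3")
  expect_error(log_relative_abundance(withzero), "non-positive.*'p'.*'s1'")
  expect_warning(ok <- log_relative_abundance(withzero, pseudocount = "auto"),
                 "pseudocount 1 applied")  # half the smallest positive (2)
  expect_equal(unname(ok["p", ]), log2(c(1, 3, 5) / 3))
})

test_that("pearson handles exact linearity and degenerate series", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(pearson(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson(1:2, 1:2), "at least 3")
  # invariance under positive affine transforms (so the log base is immaterial)
  set.seed(5)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(pearson(a, b), pearson(2.5 * a + 3, b), tolerance = 1e-12)
  expect_equal(pearson(log2(exp(a)), b), pearson(a, b), tolerance = 1e-12)
})

test_that("the resampling null is seed-reproducible and matches exhaustive enumeration", {
  pair_a <- rbind(a = c(1, 2, 3)); pair_b <- rbind(b = c(2, 4, 6))
  n1 <- build_null(pair_a, pair_b, iterations = 6000, seed = 11)
  n2 <- build_null(pair_a, pair_b, iterations = 6000, seed = 11)
  expect_identical(n1$values, n2$values)

  # oracle: all 3! sample-order permutations of the second series
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  enum <- sort(vapply(perms, function(p) cor(c(1, 2, 3), c(2, 4, 6)[p]),
                      numeric(1)))
  expect_equal(sort(unique(round(n1$values, 12))),
               sort(unique(round(enum, 12))))
  # each permutation is equally likely; +-0.5 each arise from two of the six
  freq <- table(round(n1$values, 12)) / n1$iterations
  expected <- c(1, 2, 2, 1) / 6  # at r = -1, -0.5, 0.5, 1
  tol <- 4 * sqrt(max(expected) * (1 - max(expected)) / 6000)
  expect_true(all(abs(as.numeric(freq) - expected) < tol))
  # symmetry: reversing a permutation negates r, so mirrored values match
  expect_lt(abs(freq[["1"]] - freq[["-1"]]), tol)
  expect_lt(abs(freq[["0.5"]] - freq[["-0.5"]]), tol)

  expect_error(build_null(pair_a, pair_b, iterations = 0), ">= 1")
  const <- rbind(a = c(1, 1, 1))
  expect_error(build_null(const, const, iterations = 5, seed = 1),
               "non-degenerate")
})

test_that("strong calls use inclusive 5th/95th null percentiles", {
  null <- structure(list(values = sort(seq(-1, 1, length.out = 101)),
                         iterations = 101L, seed = 1L),
                    class = "null_distribution")
  thr <- stats::quantile(null$values, c(0.05, 0.95), type = 7, names = FALSE)
  obs <- data.frame(id_a = c("m1", "m2", "m3", "m4"),
                    id_b = rep("t", 4),
                    pcc = c(thr[2L] + 0.01, thr[2L], 0, NA_real_))
  flagged <- classify_strong(obs, null)
  expect_equal(flagged$strong, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(flagged$sign[1:3], c("positive", "positive", "positive"))
  low <- classify_strong(data.frame(id_a = "x", id_b = "y", pcc = thr[1L]), null)
  expect_true(low$strong)
  expect_equal(low$sign, "negative")
})

test_that("a self-null flags about 10 percent of observations", {
  set.seed(21)
  A <- matrix(rnorm(60 * 5), 60, 5)
  rownames(A) <- sprintf("a%02d", 1:60)
  B <- matrix(rnorm(60 * 5), 60, 5)
  rownames(B) <- sprintf("b%02d", 1:60)
  obs <- correlate_sets(A, B)
  null <- structure(list(values = sort(obs$pcc),
                         iterations = length(obs$pcc), seed = 0L),
                    class = "null_distribution")
  flagged <- classify_strong(obs, null)
  rate <- mean(flagged$strong)
  n <- nrow(obs)
  band <- 2.576 * sqrt(0.1 * 0.9 / n)  # 99% binomial interval around 0.10
  expect_lt(abs(rate - 0.10), band + 2 / n)  # +2/n: inclusive boundaries
})

test_that("joint band probability matches the closed-form normal oracle", {
  # reference scaled to sample mean 0, sd 1 exactly
  set.seed(3)
  ref <- as.numeric(scale(rnorm(500)))
  p <- joint_band_probability(rep(-0.9, 6), c(-1, -0.8), ref)
  oracle <- (pnorm(-0.8) - pnorm(-1))^6
  expect_equal(p, oracle, tolerance = 1e-10)
  expect_equal(joint_band_probability(numeric(0), c(-1, 1), ref), 1)
  wide <- joint_band_probability(rep(0, 3), c(-100, 100), ref)
  expect_equal(wide, 1, tolerance = 1e-12)
  expect_error(joint_band_probability(1, c(1, -1), ref), "lo < hi")
  expect_error(joint_band_probability(1, c(-1, 1), rep(0.5, 10)), "degenerate")
})

test_that("zero-noise linked parameters are flagged strong and recovered at low noise", {
  spec <- fixture_spec(n_metabolites = 60L, n_enzymes = 120L, seed = 77)
  cat_ <- generate_catalog(spec)
  counts <- generate_counts(cat_, spec)
  M <- normalize_emm(build_connectivity(expand_directions(cat_),
                                        enzyme_universe(cat_)))
  prmt <- prmt_scores(M, quantile_normalize(compute_eac(counts)))
  met <- plantable_metabolites(cat_, "consume", spec)[1L]
  spec$parameter_links <- list(
    list(parameter_id = "linked_pos", metabolite = met, slope = 1, noise_sd = 0),
    list(parameter_id = "linked_neg", metabolite = met, slope = -2, noise_sd = 0))
  params <- generate_parameters(prmt, spec)
  logrel <- log_relative_abundance(params)
  expect_equal(pearson(logrel["linked_pos", ], unclass(prmt)[met, ]), 1,
               tolerance = 1e-9)
  expect_equal(pearson(logrel["linked_neg", ], unclass(prmt)[met, ]), -1,
               tolerance = 1e-9)
  obs <- correlate_sets(unclass(prmt)[met, , drop = FALSE], logrel)
  null <- build_null(unclass(prmt), logrel, iterations = 2000, seed = 5)
  flagged <- classify_strong(obs, null)
  expect_true(all(flagged$strong))
})

test_that("taxon subnetworks require both endpoints flagged", {
  cat_ <- make_catalog(
    list("R1", "a", "=>", "A", "B"),
    list("R2", "b", "=>", "B", "C"),
    list("R3", "c", "=>", "D", "E"),
    list("R4", "d", "=>", "F", "G"))
  net <- build_network(expand_directions(cat_))
  subnets <- extract_correlated_subnetworks(
    net, list(P1 = c("A", "B"), P2 = c("A", "C"),
              P3 = c("D", "E", "F", "G")))
  expect_equal(length(subnets$P1), 1L)
  expect_equal(subnets$P1[[1L]]$metabolites, c("A", "B"))
  expect_equal(subnets$P1[[1L]]$n_enzyme_reactions, 1L)
  expect_equal(length(subnets$P2), 0L)  # A-B edge has only A flagged; no A-C edge
  expect_equal(length(subnets$P3), 2L)  # two disjoint flagged pairs
  expect_message(
    extract_correlated_subnetworks(net, list(P = c("A", "nope"))),
    "absent from the network")
})

test_that("the strong-correlation network dedupes pairs and types its nodes", {
  flagged <- data.frame(
    id_a = c("m1", "t1", "m1"), id_b = c("t1", "m1", "t2"),
    pcc = c(0.99, 0.99, -0.97),
    percentile = c(0.99, 0.99, 0.01),
    strong = c(TRUE, TRUE, TRUE),
    sign = c("positive", "positive", "negative"))
  g <- build_correlation_network(flagged,
                                 node_classes = c(t1 = "taxon-abundance",
                                                  t2 = "taxon-abundance"))
  expect_equal(igraph::ecount(g), 2L)  # (m1,t1) and (t1,m1) collapse
  expect_equal(igraph::vcount(g), 3L)
  expect_setequal(igraph::E(g)$interaction, c("pos", "neg"))
  expect_equal(sort(unique(igraph::V(g)$type)),
               c("taxon-abundance", "unknown"))
  empty <- build_correlation_network(flagged[flagged$pcc > 1, , drop = FALSE])
  expect_equal(igraph::vcount(empty), 0L)
})
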