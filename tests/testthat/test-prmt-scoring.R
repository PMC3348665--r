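# Enzyme activity counts, quantile normalization and PRMT scoring.

test_that("EAC transforms behave as documented", {
  X <- matrix(c(0L, 7L, 3L, 1L), 2, 2,
              dimnames = list(c("e1", "e2"), c("s1", "s2")))
  eac <- compute_eac(X, "log2p1")
  expect_equal(unclass(eac)["e1", "s1"], 0)
  expect_equal(unclass(eac)["e2", "s1"], 3)  # log2(7 + 1)
  expect_equal(vals(compute_eac(X, "raw")), unclass(X) + 0)
  expect_error(compute_eac(matrix(-1, 1, 2)), "negative")
})

test_that("quantile normalization reproduces the worked two-sample example", {
  X <- cbind(s1 = c(1, 2, 3), s2 = c(6, 5, 4))
  rownames(X) <- paste0("e", 1:3)
  q <- quantile_normalize(X)
  expect_equal(attr(q, "reference_distribution"), c(4.5, 3.5, 2.5))
  expect_equal(unname(unclass(q)[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(q)[, "s2"]), c(4.5, 3.5, 2.5))

  # identical samples are unchanged
  same <- cbind(a = c(2, 7, 5), b = c(2, 7, 5))
  rownames(same) <- paste0("e", 1:3)
  expect_equal(vals(quantile_normalize(same)), same)

  # tied values share the mean of the reference values spanning their ranks
  tied <- cbind(s1 = c(1, 1, 2), s2 = c(3, 4, 5))
  rownames(tied) <- paste0("e", 1:3)
  qt <- unclass(quantile_normalize(tied))
  # ascending reference: (1+3)/2, (1+4)/2, (2+5)/2 = 2, 2.5, 3.5
  expect_equal(unname(qt[, "s1"]), c(2.25, 2.25, 3.5))
  expect_equal(unname(qt[, "s2"]), c(2, 2.5, 3.5))

  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "single sample|at least two")
})

test_that("quantile normalization equalizes distributions, is idempotent and order-invariant", {
  X <- random_neac_like(sprintf("e%03d", 1:40), 4, seed = 7)
  q <- quantile_normalize(X)
  sorted <- apply(unclass(q), 2L, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1L])
  expect_equal(vals(quantile_normalize(q)), vals(q), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  q_perm <- quantile_normalize(X[, perm])
  expect_equal(vals(q_perm), vals(q)[, perm], tolerance = 1e-12)
})

test_that("quantile normalization matches the limma reference on tie-free data", {
  X <- random_neac_like(sprintf("e%03d", 1:60), 3, seed = 9)
  expect_equal(unname(vals(quantile_normalize(X))),
               unname(limma::normalizeQuantiles(X)), tolerance = 1e-12)
})

test_that("reference profiles are element-wise means over chosen samples", {
  X <- cbind(a = c(0, 2), b = c(2, 0))
  rownames(X) <- c("e1", "e2")
  expect_equal(unname(reference_neac(X)), c(1, 1))
  expect_equal(unname(reference_neac(X, "a")), c(0, 2))
  same <- cbind(a = c(3, 4), b = c(3, 4)); rownames(same) <- c("e1", "e2")
  expect_equal(unname(reference_neac(same)), c(3, 4))
  expect_error(reference_neac(X, "nope"), "unknown reference sample")
})

test_that("scores are zero at the reference, consumption-positive, and antisymmetric", {
  M <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "e"))
  class(M) <- c("emm", class(M))
  neac <- cbind(x = 2, y = 1)
  rownames(neac) <- "e"

  # nEAC equal to the reference gives the zero vector
  z <- prmt_scores(M, neac, reference = c(e = 2))
  expect_equal(unclass(z)[, "x"], c(A = 0, B = 0))

  # y is BELOW the reference: less consumption capacity, negative score for A
  expect_equal(unclass(z)[, "y"], c(A = -1, B = 1))
  # enzyme e consumes A; its abundance up by 1 => PRMT(A) = +1
  up <- prmt_scores(M, cbind(x = 3) |> `rownames<-`("e"), reference = c(e = 2))
  expect_equal(unclass(up)["A", "x"], 1)

  # production-positive flips the convention
  up_prod <- prmt_scores(M, cbind(x = 3) |> `rownames<-`("e"),
                         reference = c(e = 2),
                         sign_convention = "production-positive")
  expect_equal(unclass(up_prod)["A", "x"], -1)

  # swapping sample and reference negates every score
  sw <- prmt_scores(M, cbind(x = 2) |> `rownames<-`("e"), reference = c(e = 3))
  expect_equal(unclass(sw)["A", "x"], -unclass(up)["A", "x"])
})

test_that("abundance changes of all-reversible enzymes never move a score", {
  cat_ <- make_catalog(
    list("R1", "irr", "=>", "C1", "C2"),
    list("R2", "rev", "<=>", "C2", "C3"),
    list("R3", "rev", "<=>", "C1", "C3"))
  M <- normalize_emm(build_connectivity(expand_directions(cat_)))
  neac <- random_neac_like(c("irr", "rev"), 3, seed = 4)
  ref <- reference_neac(neac)
  base <- unclass(prmt_scores(M, neac, ref))
  bumped <- neac
  bumped["rev", ] <- bumped["rev", ] + c(5, -2, 100)
  expect_identical(unclass(prmt_scores(M, bumped, ref)), base)

  # with the raw transform and no quantile step, even count-level bumps are exact
  counts <- matrix(c(3L, 9L, 5L, 1L, 2L, 8L), 2, 3, byrow = TRUE,
                   dimnames = list(c("irr", "rev"), c("s1", "s2", "s3")))
  eac <- compute_eac(counts, "raw")
  ref2 <- reference_neac(eac)
  base2 <- unclass(prmt_scores(M, eac, ref2))
  counts2 <- counts; counts2["rev", "s2"] <- 1000L
  expect_identical(unclass(prmt_scores(M, compute_eac(counts2, "raw"), ref2)),
                   base2)
})

test_that("matrix scoring agrees with the brute-force per-reaction oracle", {
  for (seed in 1:20) {
    cat_ <- random_small_catalog(seed, max_reactions = 30L, n_mets = 10L,
                                 n_enzymes = 6L)
    neac <- random_neac_like(enzyme_universe(cat_), 3, seed = seed + 100)
    ref <- reference_neac(neac)
    M <- normalize_emm(build_connectivity(expand_directions(cat_)))
    got <- unclass(prmt_scores(M, neac, ref))
    want <- oracle_prmt(cat_, neac, ref)
    expect_lt(max(abs(got - want[rownames(got), colnames(got)])), 1e-9)
  }
})

test_that("mean-referenced scores sum to zero across samples", {
  cat_ <- random_small_catalog(42)
  neac <- random_neac_like(enzyme_universe(cat_), 4, seed = 43)
  M <- normalize_emm(build_connectivity(expand_directions(cat_)))
  pr <- unclass(prmt_scores(M, neac))  # default reference: mean of samples
  expect_true(all(abs(rowSums(pr)) <= 1e-9))
})

test_that("enzymes missing on either side are aligned away with a message", {
  M <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "e"))
  class(M) <- c("emm", class(M))
  neac <- cbind(x = c(3, 5)); rownames(neac) <- c("e", "extra")
  expect_message(pr <- prmt_scores(M, neac, reference = c(e = 2, extra = 1)),
                 "ignored")
  expect_equal(unclass(pr)["A", "x"], 1)
  bad <- cbind(x = 1); rownames(bad) <- "other"
  expect_error(suppressMessages(prmt_scores(M, bad, reference = c(other = 0))),
               "no enzyme labels shared")
})
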