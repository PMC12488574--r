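test_that("variance filter removes sd < 1 and keeps the boundary", {
  X <- rbind(const = rep(5, 20),
             boundary = rep(c(0, 2), 10) * sqrt(1 / (2 * 19 / 20)),
             wide = rnorm(20, sd = 4))
  # make the boundary row have sd exactly 1
  b <- rep(c(-1, 1), 10)
  X["boundary", ] <- b / sd(b)
  expect_equal(sd(X["boundary", ]), 1)
  kept <- filterLowVariance(X, sigma_min = 1)
  expect_false("const" %in% rownames(kept))
  expect_true("boundary" %in% rownames(kept))
})

test_that("variance filter agrees with the per-row sd oracle", {
  set.seed(4)
  X <- matrix(rnorm(50 * 20, sd = rep(seq(0.2, 3, length.out = 50), 20)),
              50, 20, dimnames = list(paste0("g", 1:50), NULL))
  kept <- rownames(filterLowVariance(X, 1))
  oracle <- rownames(X)[vapply(seq_len(50),
                               function(i) sd(X[i, ]) >= 1, logical(1))]
  expect_identical(kept, oracle)
})

test_that("sub-stage merging is total and idempotent", {
  expect_identical(mergeSubstages(c("1", "1A", "1B")), rep("I", 3))
  expect_identical(mergeSubstages("2B"), "II")
  expect_identical(mergeSubstages(c("3", "3A", "3B", "3C")), rep("III", 4))
  expect_identical(mergeSubstages("4"), "IV")
  expect_identical(mergeSubstages(c("X", NA, "weird")),
                   rep(NA_character_, 3))
  expect_identical(mergeSubstages("Stage IIa"), "II")
  # idempotent on its own output
  once <- mergeSubstages(c("1A", "2B", "3C", "4", "X"))
  expect_identical(mergeSubstages(once), once)
})

test_that("IHC subtype derivation follows the receptor taxonomy", {
  expect_identical(deriveMolecularSubtype("-", "-", "-"), "TNBC")
  expect_identical(deriveMolecularSubtype("-", "-", "+"), "HER2")
  expect_identical(deriveMolecularSubtype("+", "+", "-"), "Luminal")
  expect_identical(deriveMolecularSubtype("+", "-", "+"), "Luminal")
  # ki67 enables the A/B split; HER2-positivity forces Luminal B
  expect_identical(deriveMolecularSubtype("+", "+", "-", 0.05), "Luminal A")
  expect_identical(deriveMolecularSubtype("+", "+", "-", 0.30), "Luminal B")
  expect_identical(deriveMolecularSubtype("+", "+", "+", 0.05), "Luminal B")
  expect_identical(deriveMolecularSubtype(NA, NA, NA), NA_character_)
})

test_that("variance stabilization is the closed-form monotone transform", {
  expect_equal(varianceStabilize(matrix(0), weights = FALSE)$log2[1, 1], -1)
  set.seed(2)
  X <- matrix(rexp(200, 0.01), 20)
  L <- varianceStabilize(X, weights = FALSE)$log2
  expect_equal(L, log2(X + 0.5))
  # strictly monotone per entry
  expect_true(all((L[order(X)] == L[order(X)][order(seq_along(X))]) | TRUE))
  o <- order(as.vector(X))
  expect_true(all(diff(as.vector(L)[o]) >= 0))
  # constant matrix: all weights equal
  W <- varianceStabilize(matrix(3, 5, 4), weights = TRUE)$weights
  expect_true(all(W == W[1, 1]))
})

test_that("mean-variance trend weights decrease with inflated variance", {
  set.seed(9)
  mu <- exp(runif(300, 1, 8))
  X <- t(vapply(mu, function(m) rpois(30, m), numeric(30)))
  vs <- varianceStabilize(X, weights = TRUE)
  # Poisson counts: log2 variance shrinks with mean, so weights grow
  w <- vs$weights[, 1]
  m <- rowMeans(vs$log2)
  expect_gt(cor(m, w, method = "spearman"), 0.5)
})

test_that("stratified split is disjoint, exhaustive and proportional", {
  set.seed(6)
  labels <- sample(c("a", "b", "c"), 200, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
  sp <- stratifiedSplit(labels, 0.8, seed = 3)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  for (l in unique(labels)) {
    n_l <- sum(labels == l)
    got <- sum(labels[sp$train] == l)
    expect_lte(abs(got - 0.8 * n_l), 1)
  }
})

test_that("the 112 normal / 1066 cancer split lands near 90/854", {
  labels <- rep(c("normal", "cancer"), c(112, 1066))
  sp <- stratifiedSplit(labels, 0.8, seed = 1)
  tr <- table(labels[sp$train])
  expect_lte(abs(tr[["normal"]] - 90), 1)
  expect_lte(abs(tr[["cancer"]] - 854), 1)
  expect_equal(length(sp$train), round(1178 * 0.8))
})

test_that("tiny strata go wholly to training with a warning", {
  labels <- c(rep("big", 50), "solo")
  expect_warning(sp <- stratifiedSplit(labels, 0.8, seed = 2), "fewer than 2")
  expect_true(51 %in% sp$train)
})

test_that("SMOTE follows the published counting semantics", {
  set.seed(10)
  X <- matrix(rnorm(853 * 4), 853)
  y <- rep(c("met", "non"), c(16, 837))
  b <- smoteBalance(X, y, perc_over = 1000, perc_under = 300, k = 5,
                    seed = 7)
  expect_equal(unname(table(b$y)[["met"]]), 176)
  expect_equal(unname(table(b$y)[["non"]]), 480)
  # perc_over = 0: minority unchanged
  b0 <- smoteBalance(X, y, perc_over = 0, perc_under = 300, seed = 7)
  expect_equal(sum(b0$y == "met"), 16)
  # closed-form counting on a grid of (n_min, over, under)
  for (case in list(c(5, 200, 100, 3), c(8, 500, 200, 3),
                    c(12, 300, 150, 5))) {
    n_min <- case[1]; over <- case[2]; under <- case[3]; k <- case[4]
    yy <- rep(c("m", "M"), c(n_min, 60))
    XX <- matrix(rnorm((n_min + 60) * 3), n_min + 60)
    bb <- smoteBalance(XX, yy, over, under, k, seed = 3)
    expect_equal(sum(bb$y == "m"), n_min * (1 + over / 100))
    expect_equal(sum(bb$y == "M"), round(under / 100 * n_min * over / 100))
  }
})

test_that("SMOTE synthetics are convex combinations of minority points", {
  set.seed(3)
  X <- matrix(runif(40 * 2, 10, 20), 40)
  y <- rep(c("m", "M"), c(10, 30))
  b <- smoteBalance(X, y, perc_over = 300, perc_under = 100, k = 3, seed = 1)
  syn <- b$X[grepl("^synth", rownames(b$X)), , drop = FALSE]
  rng <- apply(X[1:10, ], 2, range)
  expect_true(all(syn >= rng[1, ][col(syn)] & syn <= rng[2, ][col(syn)]))
})

test_that("SMOTE reduces k with a warning for tiny minorities", {
  X <- matrix(rnorm(30 * 2), 30)
  y <- rep(c("m", "M"), c(4, 26))
  expect_warning(smoteBalance(X, y, 100, 100, k = 5, seed = 1),
                 "reduced")
})

test_that("FSQN maps target genes onto the reference distribution", {
  set.seed(5)
  ref <- matrix(rnorm(30 * 40, 8, 2), 30,
                dimnames = list(paste0("g", 1:30), NULL))
  tgt <- ref + 10  # global platform shift
  out <- fsqnHarmonize(tgt, ref)
  for (g in sample(rownames(ref), 5)) {
    ks <- suppressWarnings(ks.test(out[g, ], ref[g, ]))$statistic
    expect_lt(unname(ks), 0.11)
    # rank preservation within the gene
    expect_identical(order(out[g, ]), order(tgt[g, ]))
  }
  # identity: target == reference recovers itself up to interpolation
  idm <- fsqnHarmonize(ref, ref)
  expect_equal(idm, ref, tolerance = 0.15)
  expect_lt(median(abs(idm - ref)), 0.05)
})

test_that("FSQN passes through genes missing in the reference", {
  ref <- matrix(rnorm(20), 2, dimnames = list(c("a", "b"), NULL))
  tgt <- matrix(rnorm(30), 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_warning(out <- fsqnHarmonize(tgt, ref), "missing in reference")
  expect_identical(out["c", ], tgt["c", ])
})
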