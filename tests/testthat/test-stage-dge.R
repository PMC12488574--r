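test_that("reference and cell-means codings are numerically equivalent", {
  co <- smallCohort()
  ref <- fitStageModel(co, coding = "reference")
  cm <- fitStageModel(co, coding = "cell_means")
  dev_cm <- cm$coefficients[, paste0("beta_", 1:4)] -
    cm$coefficients[, "beta_0"]
  expect_equal(unname(ref$coefficients[, paste0("beta_", c("I","II","III","IV"))]),
               unname(dev_cm), tolerance = 1e-10)
  # reference beta_k is exactly the stage-vs-control lfc
  expect_equal(unname(ref$coefficients[, -1]), unname(ref$lfc),
               tolerance = 1e-12)
})

test_that("unmoderated coefficients equal group-mean differences", {
  set.seed(21)
  groups <- rep(c("control", "I", "II", "III", "IV"), c(10, 8, 12, 9, 7))
  X <- matrix(rnorm(200 * length(groups)), 200,
              dimnames = list(paste0("g", 1:200), NULL))
  fit <- fitStageModel(X, coding = "cell_means", groups = groups,
                       moderate = FALSE)
  for (s in c("I", "II", "III", "IV")) {
    oracle <- rowMeans(X[, groups == s]) - rowMeans(X[, groups == "control"])
    expect_equal(unname(fit$lfc[, s]), unname(oracle), tolerance = 1e-10)
  }
})

test_that("identical groups give zero coefficients and flat p-values", {
  set.seed(22)
  groups <- rep(c("control", "I", "II", "III", "IV"), each = 30)
  X <- matrix(rnorm(50 * 150), 50)
  fit <- fitStageModel(X, groups = groups)
  expect_lt(max(abs(fit$lfc)), 1)
  expect_gt(min(fit$padj), 0.2)
})

test_that("BH adjustment matches a direct step-up implementation", {
  set.seed(23)
  p <- runif(500)^2
  bh <- function(p) {  # independent step-up oracle
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(p.adjust(p, "BH"), bh(p), tolerance = 1e-12)
  # adjusted p never below raw p, and within [0,1] (result invariant)
  co <- smallCohort()
  fit <- fitStageModel(co)
  expect_true(all(fit$padj >= fit$p - 1e-12))
  expect_true(all(fit$padj >= 0 & fit$padj <= 1))
})

test_that("level-I filters are strict and recover planted membership", {
  lfc <- cbind(I = c(2.0, 2.1, -2.5, 0.5),
               II = c(0, 3, 0, 0), III = c(0, 0, 0, 0),
               IV = c(0, 0, 0, -4))
  rownames(lfc) <- paste0("g", 1:4)
  padj <- matrix(1e-6, 4, 4, dimnames = dimnames(lfc))
  padj["g3", "I"] <- 0.001  # boundary p: excluded (strict <)
  sets <- levelIStageSpecific(fakeStageFit(lfc, padj))
  expect_false("g1" %in% sets$I)   # lfc exactly 2: strict >
  expect_true("g2" %in% sets$I)
  expect_false("g3" %in% sets$I)   # adjusted p exactly at the cutoff
  expect_identical(sets$IV, "g4")
  # empty results give empty sets
  empty <- fakeStageFit(lfc[0, , drop = FALSE], padj[0, , drop = FALSE])
  expect_true(all(lengths(levelIStageSpecific(empty)) == 0))
})

test_that("disjointly planted per-stage sets sum to the total", {
  set.seed(24)
  sizes <- c(I = 74, II = 238, III = 90, IV = 525)
  n <- 1000
  lfc <- matrix(0, n, 4, dimnames = list(paste0("g", 1:n), names(sizes)))
  padj <- matrix(1, n, 4, dimnames = dimnames(lfc))
  start <- 0
  for (s in names(sizes)) {
    idx <- start + seq_len(sizes[[s]])
    lfc[idx, s] <- 3 * sample(c(-1, 1), sizes[[s]], replace = TRUE)
    padj[idx, s] <- 1e-8
    start <- start + sizes[[s]]
  }
  sets <- levelIStageSpecific(fakeStageFit(lfc, padj))
  expect_equal(unname(lengths(sets)), unname(sizes), ignore_attr = TRUE)
  expect_equal(sum(lengths(sets)), 927)
})

test_that("the salience rule reproduces the reference table labels", {
  tab <- referenceSalientTable()
  dev <- as.matrix(tab[, paste0("beta_", 1:4)])
  colnames(dev) <- c("I", "II", "III", "IV")
  rownames(dev) <- tab$gene
  asg <- assignSalientStage(dev)
  expect_identical(asg$salient_stage, tab$stage)
  expect_identical(asg$direction, tab$status)
})

test_that("regulation status reproduces the linear-model table labels", {
  lt <- referenceLinearTopTable()
  dev <- as.matrix(lt[, paste0("beta_", 1:4)])
  rownames(dev) <- lt$gene
  expect_identical(regulationStatus(dev), lt$status)
})

test_that("tied deviations yield no salience call", {
  expect_true(is.na(assignSalientStage(c(I = 2, II = 2, III = 1,
                                         IV = 0))$salient_stage))
  expect_identical(assignSalientStage(c(I = 1, II = 1, III = 1,
                                        IV = 1))$salient_stage,
                   NA_character_)
})

test_that("planted stage-salient genes are recovered by the two-level call", {
  co <- smallCohort()
  fit <- fitStageModel(co, coding = "cell_means")
  sal <- callStageSalient(fit)
  planted <- plantedOfClass(co, "stage_salient")
  recovered <- 0
  for (p in planted) {
    row <- sal[sal$gene == p$gene_id, ]
    if (nrow(row) == 1) {
      recovered <- recovered + 1
      expect_identical(row$salient_stage, p$stage)
      expect_identical(tolower(row$direction), p$direction)
    }
  }
  # the small fixture has limited power for weak effects against the
  # 16-sample stage-IV group; most planted genes must still surface
  expect_gte(recovered / length(planted), 0.8)
  # null genes never called
  expect_false(any(grepl("^NULL", sal$gene)))
  # reported contrast p is the worst pairwise p, hence in (0, 0.05)
  expect_true(all(sal$adj_p_contrast < 0.05))
})

test_that("monotonic detection is strict on group means", {
  groups <- rep(c("I", "II", "III", "IV"), each = 25)
  mk <- function(means) {
    set.seed(25)
    x <- rep(means, each = 25) + rnorm(100, 0, 0.01)
    matrix(x, 1, dimnames = list("g", NULL))
  }
  down <- detectMonotonic(mk(c(5, 4, 3, 2)), groups)
  expect_equal(nrow(down), 1)
  expect_identical(down$status, "Down")
  expect_lt(down$slope, 0)
  # non-strict profile is not flagged
  flat <- detectMonotonic(mk(c(5, 4, 4, 2)), groups)
  expect_equal(nrow(flat), 0)
})

test_that("planted monotonic genes are recovered with calibrated slope", {
  set.seed(26)
  n_rep <- 20
  cfg <- cohortConfig(
    n_control = 50, n_per_stage = c(100, 100, 100, 100), n_genes = 120,
    planted_profiles = lapply(seq_len(n_rep), function(i) {
      plantedGene(sprintf("M%02d", i), "monotonic",
                  effect_lfc = 0.6 * sample(c(-1, 1), 1))
    }), seed = 27)
  co <- generateCohort(cfg)
  mono <- detectMonotonic(co)
  hits <- sum(sprintf("M%02d", seq_len(n_rep)) %in% mono$gene)
  expect_gte(hits / n_rep, 0.9)
  # slope recovered within 3 standard errors (per-sample ordinal fit)
  got <- mono[mono$gene == "M01", ]
  if (nrow(got) == 1) {
    se <- 1 / sqrt(400) / sd(rep(1:4, each = 100)) / sqrt(400) * 20
    expect_lt(abs(abs(got$slope) - 0.6), 0.1)
  }
  # false discovery among null genes is controlled
  null_called <- sum(grepl("^NULL", mono$gene[mono$adj_p < 0.05]))
  expect_lte(null_called / (120 - n_rep), 0.05)
})

test_that("contra-regulation templates classify paradoxical profiles", {
  # monotone trajectories are never contra
  expect_null(classifyContraRegulation(c(1, 2, 3, 4)))
  expect_null(classifyContraRegulation(c(-1, -2, -3, -4)))
  # up at stage I, below control by stage IV: pattern 1
  cc <- classifyContraRegulation(c(3, 1, -0.5, -1), anchor_stage = "I")
  expect_equal(cc$pattern_id, 1)
  expect_identical(cc$anchor_stage, "I")
  # interior peak position sets the pattern id
  expect_equal(classifyContraRegulation(c(0.5, 3, 1, -1))$pattern_id, 2)
  expect_equal(classifyContraRegulation(c(0.5, 1, 3, -1))$pattern_id, 3)
  # mirrored down-anchored cases: patterns 4..6
  expect_equal(classifyContraRegulation(c(-3, -1, 0.5, 1))$pattern_id, 4)
  expect_equal(classifyContraRegulation(c(-0.5, -3, -1, 1))$pattern_id, 5)
  # an up-early decaying profile (stage-I salient, all above control)
  chrna6_like <- c(3.35, 2.85, 2.93, 2.21)
  cc2 <- classifyContraRegulation(chrna6_like, anchor_stage = "I")
  expect_equal(cc2$pattern_id, 1)
  # with crossing required, the same profile is not contra
  expect_null(classifyContraRegulation(chrna6_like, require_crossing = TRUE))
})

test_that("group contrasts cover all pairs and recover planted markers", {
  co <- smallCohort()
  X <- exprMatrix(co)
  sub <- molecularSubtype(co)
  gc <- groupContrast(X, sub)
  expect_setequal(names(gc$contrasts),
                  c("HER2 vs Luminal", "HER2 vs TNBC", "Luminal vs TNBC"))
  # planted subtype markers pass the |lfc| > 2 binarization in their pair
  lum <- gc$contrasts[["Luminal vs TNBC"]]
  expect_gt(abs(lum$lfc[lum$gene == "SUBL1"]), 2)
  # histology marker planted at 2.6 exceeds the threshold
  hist <- groupContrast(X, histologyClass(co))
  tb <- hist$contrasts[[1]]
  expect_gt(abs(tb$lfc[tb$gene == "HIST1"]), 2)
  # identical distributions: near-zero lfc
  set.seed(28)
  Xn <- matrix(rnorm(40 * 60), 40)
  gc0 <- groupContrast(Xn, rep(c("x", "y"), 30))
  expect_lt(max(abs(gc0$contrasts[[1]]$lfc)), 1.5)
  expect_error(groupContrast(Xn, rep("x", 60)), "two levels")
})
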