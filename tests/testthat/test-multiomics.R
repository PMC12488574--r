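test_that("expression concordance is exactly the opposite-direction rule", {
  expect_true(expressionConcordance("Up", "Down"))
  expect_true(expressionConcordance("Down", "Up"))
  expect_false(expressionConcordance("Up", "Up"))
  expect_false(expressionConcordance("Down", "Down"))
  # full 2x2 enumeration against the rule truth table
  grid <- expand.grid(g = c("Up", "Down"), m = c("Up", "Down"),
                      stringsAsFactors = FALSE)
  expect_identical(expressionConcordance(grid$g, grid$m),
                   grid$g != grid$m)
})

test_that("temporal concordance is the stage-order comparison", {
  expect_true(temporalConcordance("II", "III"))
  expect_false(temporalConcordance("IV", "I"))
  st <- c("I", "II", "III", "IV")
  grid <- expand.grid(m = st, g = st, stringsAsFactors = FALSE)
  expect_identical(temporalConcordance(grid$m, grid$g),
                   match(grid$m, st) <= match(grid$g, st))
})

test_that("target join flags both concordances and lists orphans", {
  gene_sal <- data.frame(gene = c("G1", "G2", "G3"),
                         salient_stage = c("II", "III", "IV"),
                         direction = c("Up", "Down", "Up"))
  mir_sal <- data.frame(gene = c("m1", "m2", "m3"),
                        salient_stage = c("I", "IV", "II"),
                        direction = c("Down", "Up", "Up"))
  map <- data.frame(mirna = c("m1", "m2", "m3"),
                    gene = c("G1", "G2", "G1"))
  jt <- joinTargets(mir_sal, map, gene_sal)
  r <- jt$records
  # m1 (Down, I) vs G1 (Up, II): concordant both ways
  expect_true(r$expression_concordant[r$mirna == "m1"])
  expect_true(r$temporal_concordant[r$mirna == "m1"])
  # m2 (Up, IV) vs G2 (Down, III): direction yes, temporal no
  expect_true(r$expression_concordant[r$mirna == "m2"])
  expect_false(r$temporal_concordant[r$mirna == "m2"])
  # m3 (Up) vs G1 (Up): discordant, temporal not evaluated (NA)
  expect_false(r$expression_concordant[r$mirna == "m3"])
  expect_true(is.na(r$temporal_concordant[r$mirna == "m3"]))
  expect_setequal(jt$unregulated_genes, "G3")
  expect_length(jt$targetless_mirnas, 0)
  # empty map: no records, everything orphaned
  jt0 <- joinTargets(mir_sal, map[0, ], gene_sal)
  expect_equal(nrow(jt0$records), 0)
  expect_setequal(jt0$unregulated_genes, gene_sal$gene)
  expect_setequal(jt0$targetless_mirnas, mir_sal$gene)
  expect_error(joinTargets(mir_sal, data.frame(x = 1), gene_sal),
               "malformed")
})

test_that("planted regulator couplings come out doubly concordant", {
  co <- smallCohort()
  truth <- defaultMultiOmicTruth()
  M <- generateMirnaLayer(truth, co)
  grp <- cohortGroups(co)
  mir_sal <- mirnaStageSalience(M, grp, lfc_min = 1.5)
  fit <- fitStageModel(co, coding = "cell_means")
  gene_sal <- callStageSalient(fit)
  map <- data.frame(mirna = truth$mirna_target_map$mirna,
                    gene = truth$mirna_target_map$target_gene)
  jt <- joinTargets(mir_sal, map, gene_sal)
  conc <- truth$mirna_target_map[truth$mirna_target_map$temporal_concordant,
                                 c("mirna", "target_gene")]
  found <- merge(jt$records, conc,
                 by.x = c("mirna", "gene"),
                 by.y = c("mirna", "target_gene"))
  expect_gt(nrow(found), 0)
  expect_true(all(found$expression_concordant))
  expect_true(all(found$temporal_concordant))
})

test_that("null miRNA layers produce no salience calls", {
  co <- smallCohort()
  M <- generateMirnaLayer(multiOmicTruth(), co, n_null = 40)
  sal <- mirnaStageSalience(M, cohortGroups(co))
  expect_lte(nrow(sal) / 40, 0.05)
})

test_that("methylation-expression drivers follow the correlation gate", {
  set.seed(51)
  n <- 500
  e <- rnorm(n)
  b_driver <- clip01(0.5 - 0.08 * e + rnorm(n, 0, 0.05))
  b_null <- clip01(0.5 + rnorm(n, 0, 0.1))
  res <- methylationExpressionCorrelation(rbind(b_driver, b_null),
                                          rbind(e, e))
  expect_true(res$driver[1])
  expect_false(res$driver[2])
  expect_lt(res$r[1], -0.3)
  # planted correlation recovered closely at n = 500
  rho <- -0.6
  b2 <- clip01(0.5 + 0.1 * (rho * e + sqrt(1 - rho^2) * rnorm(n)))
  r2 <- methylationExpressionCorrelation(b2, e)
  expect_lt(abs(r2$r - rho), 0.08)
  # zero variance: NA, not a driver
  r0 <- methylationExpressionCorrelation(rep(0.5, n), e)
  expect_true(is.na(r0$r))
  expect_false(r0$driver)
})

test_that("differential methylation calls respect both filters", {
  set.seed(52)
  n1 <- 40; n2 <- 40
  groups <- rep(c("normal", "cancer"), c(n1, n2))
  hyper <- c(rnorm(n1, 0.3, 0.05), rnorm(n2, 0.673, 0.05))
  same <- rep(0.4, n1 + n2)
  small <- c(rnorm(n1, 0.4, 0.02), rnorm(n2, 0.45, 0.02))
  beta <- rbind(hyper = clip01(hyper), same = same, small = clip01(small))
  dm <- differentialMethylation(beta, factor(groups,
                                             levels = c("normal", "cancer")))
  expect_true(dm["hyper", "called"])
  expect_identical(dm["hyper", "dm_type"], "Hyper")
  expect_gt(dm["hyper", "effect"], 0.1)
  expect_false(dm["same", "called"])     # identical groups, p = 1
  expect_false(dm["small", "called"])    # significant but tiny effect
  # null simulation: BH-controlled type-I rate
  null_beta <- matrix(clip01(rnorm(200 * 60, 0.5, 0.1)), 200)
  dm0 <- differentialMethylation(null_beta, rep(c("a", "b"), 30))
  expect_lte(mean(dm0$called), 0.05)
})

test_that("beta mixtures are recovered with the right component count", {
  set.seed(53)
  two <- c(rnorm(150, qlogis(0.2) / log(2), 0.6),
           rnorm(150, qlogis(0.7) / log(2), 0.6))
  fit2 <- fitBetaMixture(mToBeta(two))
  expect_equal(fit2$n_components, 2)
  expect_true(all(abs(sort(fit2$means) - c(0.2, 0.7)) < 0.05))
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-6)
  # one tight component
  one <- clip01(rnorm(200, 0.5, 0.01))
  expect_equal(fitBetaMixture(one)$n_components, 1)
  expect_error(fitBetaMixture(runif(5)), ">= 20")
})

test_that("probe clustering respects the pairwise correlation floor", {
  co <- smallCohort()
  # single probe: one cluster
  b1 <- matrix(runif(30), 1, dimnames = list("cg1", NULL))
  expect_equal(unname(clusterProbes(b1)), 1L)
  # two correlated probes + one anti-correlated: clusters {2, 1}
  set.seed(54)
  base <- rnorm(60)
  B <- rbind(p1 = base + rnorm(60, 0, 0.1),
             p2 = base + rnorm(60, 0, 0.1),
             p3 = -base + rnorm(60, 0, 0.1))
  cl <- clusterProbes(B)
  expect_equal(cl[["p1"]], cl[["p2"]])
  expect_false(cl[["p3"]] == cl[["p1"]])
  # planted two-block structure over many probes
  blockA <- rnorm(80); blockB <- rnorm(80)
  BB <- rbind(
    t(sapply(1:10, function(i) blockA + rnorm(80, 0, 0.2))),
    t(sapply(1:8, function(i) blockB + rnorm(80, 0, 0.2))))
  rownames(BB) <- paste0("cg", 1:18)
  cl2 <- clusterProbes(BB)
  expect_equal(length(unique(cl2)), 2)
  expect_equal(length(unique(cl2[1:10])), 1)
  expect_equal(length(unique(cl2[11:18])), 1)
})

test_that("the three stage-informed methylation routes reach consensus", {
  co <- smallCohort()
  truth <- defaultMultiOmicTruth()
  ml <- generateMethylationLayer(truth, co)
  grp <- cohortGroups(co)
  av <- methylationStageSalience(ml$beta, ml$probe_map, grp, "averep")
  mv <- methylationStageSalience(ml$beta, ml$probe_map, grp, "mvalue")
  mm <- methylationStageSalience(ml$beta, ml$probe_map, grp, "methylmix")
  cons <- methylationSalienceConsensus(av, mv, mm)
  # coupled genes inherit their target's stage structure through the
  # expression ranks, so strong couplings surface in all three routes
  expect_gt(nrow(cons), 0)
  expect_true(all(cons$gene %in% vapply(truth$methylation_couplings,
                                        `[[`, character(1), "gene")))
  # consensus identities: identical call sets pass through
  expect_identical(methylationSalienceConsensus(av, av, av)$gene, av$gene)
  # one dissenting stage removes the gene
  av2 <- av
  if (nrow(av2)) {
    av2$salient_stage[1] <- setdiff(c("I", "II", "III", "IV"),
                                    av2$salient_stage[1])[1]
    expect_false(av$gene[1] %in%
                   methylationSalienceConsensus(av2, mv, mm)$gene)
  }
  # monotone: an extra agreeing set never removes a consensus gene
  cons4 <- methylationSalienceConsensus(av, mv, mm, av)
  expect_true(all(cons$gene %in% cons4$gene))
})

test_that("methylation temporal concordance reproduces the worked cases", {
  # hypermethylation at stage II ahead of a stage-IV expression minimum
  expect_true(methylationTemporalConcordance("II", "IV", "Hyper", "Down"))
  # stage-IV hypermethylation against stage-IV overexpression: discordant
  expect_false(methylationTemporalConcordance("IV", "IV", "Hyper", "Up"))
  # hypermethylation with upregulated expression: never concordant
  expect_false(methylationTemporalConcordance("III", "III", "Hyper", "Up"))
  # hypomethylation with upregulation, earlier or same stage: concordant
  expect_true(methylationTemporalConcordance("III", "III", "Hypo", "Up"))
  # strict tie handling is available
  expect_false(methylationTemporalConcordance("III", "III", "Hypo", "Up",
                                              ties = "discordant"))
})
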