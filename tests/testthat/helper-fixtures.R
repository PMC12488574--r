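# Shared fixtures, built once per test run.

# small but fully structured cohort (all planted classes, all labels)
.fixture_env <- new.env()

smallCohort <- function(seed = 11) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- cohortConfig(n_control = 60,
                        n_per_stage = c(I = 40, II = 80, III = 50, IV = 16),
                        n_genes = 120, seed = seed)
    .fixture_env[[key]] <- generateCohort(cfg)
  }
  .fixture_env[[key]]
}

cohortGroups <- function(cohort) {
  ifelse(tissueStatus(cohort) == "normal", "control", stageMacro(cohort))
}

# a hand-built stageFit carrying exactly the fields the level-I filter needs
fakeStageFit <- function(lfc, padj) {
  structure(list(lfc = lfc, padj = padj, stages = colnames(lfc)),
            class = "stageFit")
}

# a fake tuned 1-NN model that predicts a prescribed label per training row
memorizingModel <- function(X, labels, levels) {
  structure(list(family = "knn",
                 fit = list(train = as.matrix(X),
                            cl = factor(labels, levels = levels), k = 1),
                 best_params = data.frame(k = 1), cv_score = NA_real_,
                 levels = levels, center = NULL, scale = NULL,
                 feature_names = colnames(X), seed = 1L),
            class = "tunedModel")
}

clip01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

# planted-gene records of a given class from a cohort's truth metadata
plantedOfClass <- function(cohort, cls) {
  Filter(function(p) inherits(p, "plantedGene") && p$class == cls,
         plantedTruth(cohort))
}

# separable two-class toy matrix for model-zoo tests
separableData <- function(n = 100, p = 5, shift = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n,
              dimnames = list(sprintf("s%04d", seq_len(n)),
                              paste0("g", seq_len(p))))
  y <- factor(rep(c("a", "b"), length.out = n))
  X[y == "b", 1:2] <- X[y == "b", 1:2] + shift
  list(X = X, y = y)
}
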