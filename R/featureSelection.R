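#' @importFrom ranger ranger
NULL

#' Build the problem-specific base feature pool
#'
#' Pooling rules per learning problem:
#' \itemize{
#'   \item screen: stage-salient genes plus the top-n linear-model genes;
#'   \item metastasis: rank-consensus genes from the metastatic contrast
#'     plus the stage-salient genes;
#'   \item molsubtype: top-n genes per pairwise subtype contrast;
#'   \item histology: all genes passing |lfc| > `lfc_min` in the
#'     ductal-vs-lobular contrast.
#' }
#' Duplicates are removed (first provenance wins).
#'
#' @param problem one of "screen", "metastasis", "molsubtype", "histology".
#' @param salient_genes character vector of stage-salient genes.
#' @param linear_top character vector of top linear-model genes (screen).
#' @param contrast_genes character vector from the problem contrast
#'   (metastasis: rank-consensus output).
#' @param contrast_tables for molsubtype: named list of contrast
#'   data.frames (gene/lfc/p/padj) from [groupContrast]; for histology: a
#'   single such data.frame.
#' @param n_top per-contrast cap for molsubtype (default 10).
#' @param lfc_min histology binarization threshold (default 2, strict).
#' @return a `FeaturePanel` data.frame with columns gene and provenance.
#' @export
poolBaseFeatures <- function(problem = c("screen", "metastasis",
                                         "molsubtype", "histology"),
                             salient_genes = NULL, linear_top = NULL,
                             contrast_genes = NULL, contrast_tables = NULL,
                             n_top = 10, lfc_min = 2) {
  problem <- match.arg(problem)
  panel <- switch(problem,
    screen = {
      if (is.null(salient_genes) || is.null(linear_top)) {
        stop("screen pool needs salient_genes and linear_top")
      }
      rbind(data.frame(gene = salient_genes, provenance = "stage_salient"),
            data.frame(gene = linear_top, provenance = "linear_top"))
    },
    metastasis = {
      if (is.null(contrast_genes) || is.null(salient_genes)) {
        stop("metastasis pool needs contrast_genes and salient_genes")
      }
      rbind(data.frame(gene = contrast_genes,
                       provenance = "problem_contrast"),
            data.frame(gene = salient_genes, provenance = "stage_salient"))
    },
    molsubtype = {
      if (is.null(contrast_tables)) stop("molsubtype pool needs contrast_tables")
      tops <- lapply(contrast_tables, function(tb) {
        tb$gene[order(tb$padj)][seq_len(min(n_top, nrow(tb)))]
      })
      data.frame(gene = unlist(tops, use.names = FALSE),
                 provenance = "problem_contrast")
    },
    histology = {
      if (is.null(contrast_tables)) stop("histology pool needs contrast_tables")
      tb <- if (is.data.frame(contrast_tables)) contrast_tables else
        contrast_tables[[1]]
      data.frame(gene = tb$gene[abs(tb$lfc) > lfc_min],
                 provenance = "problem_contrast")
    })
  panel <- panel[!duplicated(panel$gene), , drop = FALSE]
  if (!nrow(panel)) stop("empty base feature pool for problem '", problem, "'")
  rownames(panel) <- NULL
  panel$problem <- problem
  class(panel) <- c("FeaturePanel", "data.frame")
  panel
}

#' Consensus of two rankings with significance backfill
#'
#' Intersects the top `k` genes of a fold-change-ranked list and a
#' significance-ranked list, then appends the top `backfill` genes by
#' significance that the consensus missed. Output order: consensus genes
#' (by significance rank), then backfilled genes.
#'
#' @param by_lfc character vector of genes ranked by |lfc| (best first).
#' @param by_p character vector of genes ranked by significance.
#' @param k depth of each list to intersect (clipped to list length).
#' @param backfill number of top-significance genes appended.
#' @return character vector of selected genes.
#' @export
rankConsensus <- function(by_lfc, by_p, k = 50, backfill = 6) {
  k1 <- min(k, length(by_lfc)); k2 <- min(k, length(by_p))
  consensus <- intersect(by_p[seq_len(k2)], by_lfc[seq_len(k1)])
  extra <- setdiff(by_p, consensus)[seq_len(min(backfill,
                                                length(by_p) - length(consensus)))]
  c(consensus, extra)
}

# one shadow-importance iteration: TRUE where real importance beats the
# best shadow importance
.shadowHits <- function(X, y, num_trees, mtry = NULL) {
  Xs <- apply(X, 2, sample)
  colnames(Xs) <- paste0("shadow_", colnames(X))
  dat <- data.frame(cbind(X, Xs), check.names = FALSE)
  dat$.y <- y
  rf <- ranger(dependent.variable.name = ".y", data = dat,
               num.trees = num_trees, importance = "impurity",
               mtry = mtry, seed = sample.int(1e8, 1))
  imp <- rf$variable.importance
  shadow_max <- max(imp[colnames(Xs)])
  imp[colnames(X)] > shadow_max
}

#' Boruta-style shadow-feature selection
#'
#' Each iteration appends a permuted (shadow) copy of every feature,
#' trains a random forest, and scores a real feature a "hit" when its
#' impurity importance exceeds the best shadow importance. After the
#' iterations, features are confirmed (hits significantly above chance by
#' a two-sided binomial test at `alpha`) or rejected (significantly
#' below); rejected features are removed as decided. Undecided features
#' are "tentative" and excluded unless `include_tentative`.
#'
#' @param X sample x feature matrix (column names = genes).
#' @param y class labels (factor, >= 2 classes).
#' @param alpha binomial test level, default 0.01.
#' @param max_iter number of shadow iterations, default 100 (must be > 0).
#' @param num_trees forest size per iteration, default 500.
#' @param include_tentative logical, default FALSE.
#' @param seed integer RNG seed.
#' @return character vector of selected genes (column-order preserved);
#'   attributes `decision` (named factor confirmed/tentative/rejected) and
#'   `hits`.
#' @export
borutaSelect <- function(X, y, alpha = 0.01, max_iter = 100,
                         num_trees = 500, include_tentative = FALSE,
                         seed = 1L) {
  if (max_iter <= 0) stop("max_iter must be positive")
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) >= 2)
  X <- as.matrix(X)
  constant <- apply(X, 2, function(v) length(unique(v)) == 1)
  decision <- setNames(rep("tentative", ncol(X)), colnames(X))
  decision[constant] <- "rejected"
  set.seed(as.integer(seed))
  active <- colnames(X)[!constant]
  hits <- setNames(integer(length(active)), active)
  iters <- setNames(integer(length(active)), active)
  for (it in seq_len(max_iter)) {
    if (length(active) < 2) break
    h <- .shadowHits(X[, active, drop = FALSE], y, num_trees)
    hits[active] <- hits[active] + h
    iters[active] <- iters[active] + 1L
    # two-sided binomial decisions on the features still in play, with a
    # Bonferroni correction across the features under test
    done <- it >= 5  # allow a burn-in before deciding
    if (done) {
      n_adj <- length(active)
      for (g in active) {
        p_hi <- pbinom(hits[g] - 1, iters[g], 0.5, lower.tail = FALSE)
        p_lo <- pbinom(hits[g], iters[g], 0.5)
        if (p_hi * n_adj < alpha / 2) decision[g] <- "confirmed"
        if (p_lo * n_adj < alpha / 2) decision[g] <- "rejected"
      }
      active <- names(decision)[decision == "tentative"]
    }
  }
  wanted <- c("confirmed", if (include_tentative) "tentative")
  out <- colnames(X)[decision[colnames(X)] %in% wanted]
  attr(out, "decision") <- factor(decision,
                                  c("confirmed", "tentative", "rejected"))
  attr(out, "hits") <- hits
  out
}

.balancedAccuracy <- function(y_true, y_pred) {
  y_true <- factor(y_true)
  y_pred <- factor(y_pred, levels = levels(y_true))
  rec <- vapply(levels(y_true), function(l) {
    denom <- sum(y_true == l)
    if (denom == 0) NA_real_ else sum(y_pred == l & y_true == l) / denom
  }, numeric(1))
  mean(rec, na.rm = TRUE)
}

#' Cross-validated recursive feature elimination
#'
#' Backward elimination driven by random-forest impurity importance:
#' within each CV fold, features are ranked on the training portion and
#' nested subsets of the candidate sizes are refit and scored (balanced
#' accuracy) on the held-out fold. The selected size is the smallest whose
#' mean CV score is within one standard error of the best; the returned
#' features are the top-ranked of that size on the full data. Importance
#' ties break by column order.
#'
#' @param X sample x feature matrix.
#' @param y class labels.
#' @param subset_sizes candidate sizes (clipped to the feature count);
#'   default 1..p.
#' @param folds CV folds, default 5.
#' @param num_trees forest size, default 500.
#' @param seed integer RNG seed.
#' @return character vector of selected genes; attribute `cv` holds the
#'   size/score table.
#' @export
rfeSelect <- function(X, y, subset_sizes = NULL, folds = 5,
                      num_trees = 500, seed = 1L) {
  y <- droplevels(as.factor(y))
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(subset_sizes)) subset_sizes <- seq_len(p)
  subset_sizes <- sort(unique(pmin(subset_sizes, p)))
  set.seed(as.integer(seed))
  fold <- stratifiedFolds(y, folds)
  scores <- matrix(NA_real_, folds, length(subset_sizes))
  rankFeatures <- function(Xtr, ytr) {
    dat <- data.frame(Xtr, check.names = FALSE); dat$.y <- ytr
    rf <- ranger(dependent.variable.name = ".y", data = dat,
                 num.trees = num_trees, importance = "impurity",
                 seed = sample.int(1e8, 1))
    imp <- rf$variable.importance
    # ties break by column order: order() is stable on the original order
    colnames(Xtr)[order(-imp)]
  }
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    ranked <- rankFeatures(X[tr, , drop = FALSE], y[tr])
    for (s in seq_along(subset_sizes)) {
      feats <- ranked[seq_len(subset_sizes[s])]
      dat <- data.frame(X[tr, feats, drop = FALSE], check.names = FALSE)
      dat$.y <- y[tr]
      rf <- ranger(dependent.variable.name = ".y", data = dat,
                   num.trees = num_trees, seed = sample.int(1e8, 1))
      pred <- predict(rf, data.frame(X[te, feats, drop = FALSE],
                                     check.names = FALSE))$predictions
      scores[f, s] <- .balancedAccuracy(y[te], pred)
    }
  }
  mu <- colMeans(scores)
  se <- apply(scores, 2, sd) / sqrt(folds)
  best <- which.max(mu)
  ok <- which(mu >= mu[best] - se[best])
  size <- subset_sizes[min(ok)]
  ranked_full <- rankFeatures(X, y)
  out <- ranked_full[seq_len(size)]
  attr(out, "cv") <- data.frame(size = subset_sizes, mean = mu, se = se)
  out
}

#' Consensus of the two selectors
#'
#' Set intersection of the Boruta-confirmed and RFE-selected genes; when
#' the intersection is empty the RFE set is returned with a warning (the
#' usual case is nesting, which leaves the intersection equal to the RFE
#' set).
#'
#' @param boruta_genes,rfe_genes character vectors.
#' @return character vector of consensus genes.
#' @export
consensusFeatures <- function(boruta_genes, rfe_genes) {
  if (!length(boruta_genes) && !length(rfe_genes)) {
    stop("both selector outputs are empty")
  }
  out <- intersect(rfe_genes, boruta_genes)
  if (!length(out)) {
    warning("empty selector consensus; falling back to the RFE set")
    out <- rfe_genes
  }
  out
}

#' Normalized Gini importance report
#'
#' Mean-decrease-in-impurity scores of a fitted random forest, scaled so
#' the top feature scores exactly 1, sorted descending.
#'
#' @param fit a fitted ranger forest grown with impurity importance, or a
#'   [tuneModel] result of family "random_forest".
#' @param panel optional gene subset to report.
#' @return named numeric vector of normalized importances.
#' @export
giniImportanceReport <- function(fit, panel = NULL) {
  if (inherits(fit, "tunedModel")) fit <- fit$fit
  if (!inherits(fit, "ranger") || is.null(fit$variable.importance)) {
    stop("need a ranger fit with impurity importance")
  }
  imp <- fit$variable.importance
  if (!is.null(panel)) imp <- imp[intersect(names(imp), panel)]
  imp <- sort(imp, decreasing = TRUE)
  imp / imp[1]
}
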