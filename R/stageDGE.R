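#' @importFrom limma lmFit contrasts.fit eBayes makeContrasts
NULL

.ordinaryPT <- function(fit) {
  # unmoderated gene-wise t statistics from an lmFit/contrasts.fit object
  se <- fit$stdev.unscaled * fit$sigma
  tstat <- fit$coefficients / se
  p <- 2 * pt(-abs(tstat), df = fit$df.residual)
  list(t = tstat, p = p)
}

#' Fit the stage-encoded linear model
#'
#' Per-gene least squares of log2 expression on the sample's stage group
#' (control, I..IV), in either of two equivalent codings: reference coding
#' (intercept = control baseline, stage coefficients = stage-wise log
#' fold-change vs control) or cell-means coding (one coefficient per group
#' mean, contrasts taken explicitly). Gene-wise variances are moderated by
#' empirical-Bayes shrinkage toward a pooled prior before t-statistics;
#' p-values are BH-adjusted across genes within each contrast.
#'
#' @param cohort a log2-scale [StageCohort-class], or a gene x sample
#'   matrix if `groups` is given.
#' @param coding "reference" or "cell_means".
#' @param groups factor over control/I/II/III/IV (required for matrix
#'   input; derived from the cohort annotation otherwise, with NA-stage
#'   cancer samples dropped).
#' @param weights optional observation weight matrix (e.g. from
#'   [varianceStabilize]).
#' @param moderate logical; FALSE gives ordinary (unmoderated) t-tests.
#' @return a `stageFit` list: `coefficients` (gene x group), `lfc`, `p`,
#'   `padj` (gene x stage, stage-vs-control contrasts), the coding, group
#'   sizes and the underlying limma fits.
#' @export
fitStageModel <- function(cohort, coding = c("reference", "cell_means"),
                          groups = NULL, weights = NULL, moderate = TRUE) {
  coding <- match.arg(coding)
  if (is(cohort, "StageCohort")) {
    X <- exprMatrix(cohort)
    stopifnot(identical(exprScale(cohort), "log2"))
    stage <- stageMacro(cohort)
    tissue <- tissueStatus(cohort)
    keep <- tissue == "normal" | !is.na(stage)
    X <- X[, keep, drop = FALSE]
    groups <- ifelse(tissue[keep] == "normal", "control", stage[keep])
    if (!is.null(weights)) weights <- weights[, keep, drop = FALSE]
  } else {
    X <- as.matrix(cohort)
    if (is.null(groups)) stop("matrix input requires 'groups'")
  }
  groups <- factor(as.character(groups), levels = c("control", STAGE_LEVELS))
  groups <- droplevels(groups)
  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2]
  skipped <- setdiff(levels(groups), usable)
  if (length(skipped)) {
    warning("contrasts skipped for groups with < 2 samples: ",
            paste(skipped, collapse = ", "))
  }
  if (!"control" %in% usable) stop("need >= 2 control samples")
  stages_in <- intersect(STAGE_LEVELS, usable)

  # cell-means fit drives both codings; reference coefficients follow
  design_cm <- model.matrix(~ 0 + groups)
  colnames(design_cm) <- levels(groups)
  fit_cm <- lmFit(X, design_cm, weights = weights)
  cm <- makeContrasts(
    contrasts = paste0(stages_in, " - control"), levels = design_cm)
  fit_ct <- contrasts.fit(fit_cm, cm)
  if (moderate) {
    fit_ct <- eBayes(fit_ct)
    p <- fit_ct$p.value
  } else {
    p <- .ordinaryPT(fit_ct)$p
  }
  lfc <- fit_ct$coefficients
  colnames(lfc) <- colnames(p) <- stages_in
  padj <- apply(p, 2, p.adjust, method = "BH")
  if (is.null(dim(padj))) padj <- matrix(padj, ncol = length(stages_in),
                                         dimnames = dimnames(p))

  coefs <- fit_cm$coefficients
  if (coding == "reference") {
    ref <- cbind(alpha = coefs[, "control"], lfc)
    colnames(ref) <- c("alpha", paste0("beta_", stages_in))
    coefs_out <- ref
  } else {
    colnames(coefs) <- paste0("beta_",
                              c("0", as.character(stageIndex(stages_in)))[
                                match(colnames(coefs),
                                      c("control", stages_in))])
    coefs_out <- coefs
  }
  structure(list(coding = coding, coefficients = coefs_out,
                 cell_means = fit_cm$coefficients, lfc = lfc, p = p,
                 padj = padj, group_sizes = sizes, stages = stages_in,
                 moderate = moderate, fit_cm = fit_cm, design = design_cm),
            class = "stageFit")
}

#' All pairwise inter-stage contrasts (level II)
#'
#' Moderated (or ordinary) contrasts between every pair of cancer stages
#' from a [fitStageModel] fit, BH-adjusted across genes within each pair.
#'
#' @param fit a `stageFit`.
#' @return list with `lfc`, `p`, `padj` matrices (gene x stage pair, pairs
#'   named "II-I" etc.).
#' @export
interStageContrasts <- function(fit) {
  stopifnot(inherits(fit, "stageFit"))
  st <- fit$stages
  if (length(st) < 2) stop("need >= 2 stages for inter-stage contrasts")
  pairs <- utils::combn(st, 2)
  labels <- apply(pairs, 2, function(pr) paste0(pr[2], "-", pr[1]))
  cm <- makeContrasts(
    contrasts = apply(pairs, 2, function(pr) paste0(pr[2], " - ", pr[1])),
    levels = fit$design)
  fc <- contrasts.fit(fit$fit_cm, cm)
  if (fit$moderate) {
    fc <- eBayes(fc); p <- fc$p.value
  } else {
    p <- .ordinaryPT(fc)$p
  }
  lfc <- fc$coefficients
  colnames(lfc) <- colnames(p) <- labels
  padj <- apply(p, 2, p.adjust, method = "BH")
  list(lfc = lfc, p = p, padj = padj, pairs = pairs)
}

#' Level-I stage-specific gene sets
#'
#' A gene is stage-k specific when its stage-vs-control contrast passes
#' both filters: |lfc| strictly greater than `lfc_min` and BH-adjusted
#' p strictly below `p_max`. Sets may overlap across stages.
#'
#' @param fit a `stageFit` (stage-vs-control contrasts).
#' @param lfc_min log2 fold-change threshold (strict), default 2.
#' @param p_max adjusted-p threshold (strict), default 0.001.
#' @return named list of character vectors, one per stage.
#' @export
levelIStageSpecific <- function(fit, lfc_min = 2, p_max = 0.001) {
  stopifnot(inherits(fit, "stageFit"))
  out <- lapply(fit$stages, function(s) {
    rownames(fit$lfc)[abs(fit$lfc[, s]) > lfc_min & fit$padj[, s] < p_max]
  })
  names(out) <- fit$stages
  out
}

#' Assign the salient stage from deviations vs control
#'
#' The core salience rule: the salient stage is the one with the largest
#' absolute deviation of the stage mean from the control mean, and the
#' direction is the sign of that deviation. Ties yield no call (NA).
#'
#' @param deviations numeric matrix (genes x stages) of stage-vs-control
#'   log fold-changes, or a single gene's numeric vector.
#' @return data.frame with `salient_stage` and `direction` ("Up"/"Down"),
#'   NA on ties.
#' @export
assignSalientStage <- function(deviations) {
  if (is.null(dim(deviations))) deviations <- rbind(deviations)
  stages <- colnames(deviations)
  if (is.null(stages)) stages <- STAGE_LEVELS[seq_len(ncol(deviations))]
  res <- data.frame(salient_stage = rep(NA_character_, nrow(deviations)),
                    direction = rep(NA_character_, nrow(deviations)),
                    row.names = rownames(deviations))
  for (i in seq_len(nrow(deviations))) {
    a <- abs(deviations[i, ])
    mx <- max(a)
    if (sum(a == mx) != 1) next  # ambiguous: tie
    k <- which.max(a)
    res$salient_stage[i] <- stages[k]
    res$direction[i] <- if (deviations[i, k] > 0) "Up" else "Down"
  }
  res
}

#' Regulation status from stage-wise fold changes
#'
#' Up/Down label from the sign of the deviation at the stage of largest
#' absolute deviation from control.
#'
#' @param deviations genes x stages lfc matrix (or vector for one gene).
#' @return character vector of "Up"/"Down" (NA on ties).
#' @export
regulationStatus <- function(deviations) {
  assignSalientStage(deviations)$direction
}

#' Call stage-salient genes (two-level contrast protocol)
#'
#' Level I restricts candidates to genes stage-specific in at least one
#' stage; the salient stage is then assigned by [assignSalientStage] on
#' the stage-vs-control deviations, and the call is confirmed only when
#' every level-II pairwise contrast of the salient stage against the other
#' stages is significant at `contrast_p_max` (BH-adjusted) with deviation
#' differences of consistent sign. The reported contrast p is the worst
#' (largest) of the pairwise adjusted p-values; per-stage lists are
#' truncated to the `n_top_per_stage` most significant calls.
#'
#' @param fit a `stageFit` covering all four stages.
#' @param level1 optional precomputed [levelIStageSpecific] sets.
#' @param lfc_min,p_max level-I thresholds (used when `level1` is NULL).
#' @param contrast_p_max level-II adjusted-p gate, default 0.05.
#' @param n_top_per_stage per-stage cap by contrast significance,
#'   default 10.
#' @return data.frame with gene, salient_stage, direction, the five group
#'   means (beta_0..beta_4), adj_p_contrast and adj_p_control.
#' @export
callStageSalient <- function(fit, level1 = NULL, lfc_min = 2, p_max = 0.001,
                             contrast_p_max = 0.05, n_top_per_stage = 10) {
  stopifnot(inherits(fit, "stageFit"))
  if (length(fit$stages) < length(STAGE_LEVELS)) {
    warning("not all four stages present; salience restricted to: ",
            paste(fit$stages, collapse = ", "))
  }
  if (is.null(level1)) level1 <- levelIStageSpecific(fit, lfc_min, p_max)
  candidates <- unique(unlist(level1))
  if (!length(candidates)) return(.emptySalienceFrame())
  inter <- interStageContrasts(fit)
  assign <- assignSalientStage(fit$lfc[candidates, , drop = FALSE])
  rows <- list()
  for (g in candidates) {
    k <- assign[g, "salient_stage"]
    if (is.na(k)) next
    dir_sign <- if (assign[g, "direction"] == "Up") 1 else -1
    others <- setdiff(fit$stages, k)
    pr_p <- numeric(0); ok <- TRUE
    for (j in others) {
      lab <- if (paste0(k, "-", j) %in% colnames(inter$lfc)) {
        paste0(k, "-", j)
      } else paste0(j, "-", k)
      d <- inter$lfc[g, lab]
      # orient so positive means salient stage exceeds the other stage
      if (strsplit(lab, "-")[[1]][1] != k) d <- -d
      if (sign(d) != dir_sign) { ok <- FALSE; break }
      if (inter$padj[g, lab] >= contrast_p_max) { ok <- FALSE; break }
      pr_p <- c(pr_p, inter$padj[g, lab])
    }
    if (!ok) next
    cmeans <- fit$cell_means[g, c("control", fit$stages)]
    rows[[g]] <- data.frame(
      gene = g, salient_stage = k, direction = assign[g, "direction"],
      beta_0 = cmeans[1], beta_1 = cmeans[2], beta_2 = cmeans[3],
      beta_3 = cmeans[4], beta_4 = cmeans[5],
      adj_p_contrast = max(pr_p), adj_p_control = fit$padj[g, k],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.emptySalienceFrame())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  # per-stage truncation by contrast significance
  keep <- unlist(lapply(split(seq_len(nrow(res)), res$salient_stage),
                        function(idx) {
    idx[order(res$adj_p_contrast[idx])][seq_len(min(n_top_per_stage,
                                                    length(idx)))]
  }))
  res <- res[sort(keep), , drop = FALSE]
  res[order(stageIndex(res$salient_stage), res$adj_p_contrast), ]
}

.emptySalienceFrame <- function() {
  data.frame(gene = character(), salient_stage = character(),
             direction = character(), beta_0 = numeric(), beta_1 = numeric(),
             beta_2 = numeric(), beta_3 = numeric(), beta_4 = numeric(),
             adj_p_contrast = numeric(), adj_p_control = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect monotonically expressed genes
#'
#' Flags genes whose stage-group mean expression is strictly increasing or
#' strictly decreasing from stage I to IV (controls excluded), then fits a
#' stage-ordinal regression (stages coded 1..4) per flagged gene and
#' reports the intercept, slope, BH-adjusted slope p-value and adjusted
#' R-squared; status follows the slope sign.
#'
#' @param cohort log2-scale [StageCohort-class], or matrix with `stages`.
#' @param stages per-sample stage labels for matrix input.
#' @return data.frame gene / intercept / slope / adj_p / adj_r2 / status.
#' @export
detectMonotonic <- function(cohort, stages = NULL) {
  if (is(cohort, "StageCohort")) {
    X <- exprMatrix(cohort)
    stages <- stageMacro(cohort)
  } else X <- as.matrix(cohort)
  keep <- !is.na(stages) & stages %in% STAGE_LEVELS
  X <- X[, keep, drop = FALSE]
  ord <- stageIndex(stages[keep])
  if (length(unique(ord)) < 4) stop("all four stages must be present")
  gm <- vapply(1:4, function(k) rowMeans(X[, ord == k, drop = FALSE]),
               numeric(nrow(X)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(rownames(X), NULL))
  d <- gm[, -1, drop = FALSE] - gm[, -4, drop = FALSE]
  flag <- apply(d, 1, function(z) all(z > 0) || all(z < 0))
  genes <- rownames(X)[flag]
  if (!length(genes)) {
    return(data.frame(gene = character(), intercept = numeric(),
                      slope = numeric(), adj_p = numeric(),
                      adj_r2 = numeric(), status = character()))
  }
  res <- t(vapply(genes, function(g) {
    sm <- summary(lm(X[g, ] ~ ord))
    c(sm$coefficients[1, 1], sm$coefficients[2, 1],
      sm$coefficients[2, 4], sm$adj.r.squared)
  }, numeric(4)))
  out <- data.frame(gene = genes, intercept = res[, 1], slope = res[, 2],
                    adj_p = p.adjust(res[, 3], "BH"), adj_r2 = res[, 4],
                    status = ifelse(res[, 2] > 0, "Up", "Down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$adj_p), ]
}

#' Classify contra-regulation of a stage-specific gene
#'
#' A stage-specific gene is contra-regulated when its mean-expression
#' trajectory is paradoxical with progression: an up-anchored gene whose
#' deviation peaks at an interior stage and decays afterwards (patterns
#' 1-3 by peak position at stage I/II/III), or the mirrored down-anchored
#' case (patterns 4-6 by trough position). Trajectories whose deviation
#' keeps building toward stage IV yield no call. With
#' `require_crossing = TRUE` the decay must additionally cross the control
#' baseline (deviation changing sign) before a call is made.
#'
#' @param deviations numeric length-4 vector of stage-vs-control lfc
#'   (stages I..IV) for one gene, or a genes x 4 matrix.
#' @param anchor_stage the gene's specific/salient stage (bookkeeping,
#'   returned in the call).
#' @param require_crossing logical; see above.
#' @return for vector input, a list (gene-free `ContraCall`: anchor_stage,
#'   pattern_id) or NULL; for matrix input a data.frame of calls.
#' @export
classifyContraRegulation <- function(deviations, anchor_stage = NA,
                                     require_crossing = FALSE) {
  if (!is.null(dim(deviations))) {
    calls <- lapply(seq_len(nrow(deviations)), function(i) {
      cc <- classifyContraRegulation(deviations[i, ],
                                     anchor_stage = anchor_stage,
                                     require_crossing = require_crossing)
      if (is.null(cc)) NULL else
        data.frame(gene = rownames(deviations)[i],
                   anchor_stage = cc$anchor_stage,
                   pattern_id = cc$pattern_id, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, calls))
  }
  d <- as.numeric(deviations)
  stopifnot(length(d) == 4)
  up <- d[which.max(abs(d))] > 0
  if (up) {
    e <- which.max(d)
    decays <- e < 4 && d[4] < d[e]
    crosses <- any(d[seq(e, 4)] < 0)
  } else {
    e <- which.min(d)
    decays <- e < 4 && d[4] > d[e]
    crosses <- any(d[seq(e, 4)] > 0)
  }
  if (!decays || (require_crossing && !crosses)) return(NULL)
  list(anchor_stage = anchor_stage,
       pattern_id = if (up) e else 3L + e)
}

#' Binary / ternary group contrast
#'
#' Cell-means fit of log2 expression on a categorical label (metastasis,
#' molecular subtype, histology), with every pairwise contrast reported:
#' lfc, moderated p and BH-adjusted p across genes per contrast.
#'
#' @param X gene x sample log2 matrix.
#' @param labels per-sample labels (2 or more levels; NAs dropped).
#' @param moderate logical empirical-Bayes moderation.
#' @param weights optional observation weights.
#' @return list with `means` (gene x level) and `contrasts`, a named list
#'   of data.frames (gene, lfc, p, padj) per level pair.
#' @export
groupContrast <- function(X, labels, moderate = TRUE, weights = NULL) {
  keep <- !is.na(labels)
  X <- as.matrix(X)[, keep, drop = FALSE]
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  if (!is.null(weights)) weights <- weights[, keep, drop = FALSE]
  f <- droplevels(factor(labels[keep]))
  if (nlevels(f) < 2) stop("labels must have at least two levels")
  if (any(table(f) < 2)) stop("each level needs >= 2 samples")
  design <- model.matrix(~ 0 + f)
  lev <- make.names(levels(f))
  colnames(design) <- lev
  fit <- lmFit(X, design, weights = weights)
  pairs <- utils::combn(levels(f), 2)
  pairs_safe <- utils::combn(lev, 2)
  cm <- makeContrasts(
    contrasts = apply(pairs_safe, 2,
                      function(pr) paste0(pr[1], " - ", pr[2])),
    levels = design)
  fc <- contrasts.fit(fit, cm)
  if (moderate) { fc <- eBayes(fc); p <- fc$p.value } else {
    p <- .ordinaryPT(fc)$p
  }
  contrasts <- lapply(seq_len(ncol(pairs)), function(j) {
    data.frame(gene = rownames(X), lfc = fc$coefficients[, j],
               p = p[, j], padj = p.adjust(p[, j], "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(contrasts) <- apply(pairs, 2, paste, collapse = " vs ")
  means <- fit$coefficients
  colnames(means) <- levels(f)
  list(means = means, contrasts = contrasts)
}
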