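#' Assemble a cascade bundle
#'
#' @param screen,metastasis,subtype tuned models (see [tuneModel]).
#' @param histology a tuned model or list of tuned models; two or more
#'   members form an agreement ensemble that can abstain.
#' @param panels optional named list of gene panels; defaults to each
#'   model's feature names.
#' @param thresholds named confidence thresholds in (0.5, 1]; a prediction
#'   probability at or above the threshold is flagged "strong". Defaults
#'   reflect the probability bands observed for correct predictions:
#'   0.9 screen, 0.75 metastasis, 0.7 subtype and histology.
#' @return a [CascadeBundle-class].
#' @export
cascadeBundle <- function(screen, metastasis, subtype, histology,
                          panels = NULL,
                          thresholds = c(screen = 0.9, metastasis = 0.75,
                                         subtype = 0.7, histology = 0.7)) {
  if (inherits(histology, "tunedModel")) histology <- list(histology)
  if (is.null(panels)) {
    panels <- list(
      screen = screen$feature_names,
      metastasis = metastasis$feature_names,
      subtype = subtype$feature_names,
      histology = unique(unlist(lapply(histology,
                                       function(m) m$feature_names))))
  }
  new("CascadeBundle", screen = screen, metastasis = metastasis,
      subtype = subtype, histology = histology, panels = panels,
      thresholds = thresholds)
}

.subtypeAdjective <- function(lab) {
  switch(lab, TNBC = "triple-negative", HER2 = "HER2-positive",
         Luminal = "luminal", lab)
}

.histologyNoun <- function(lab) {
  switch(lab, IDC = "ductal", ILC = "lobular", lab)
}

# run one model on a 1 x p matrix, returning label + probability
.levelCall <- function(model, xrow) {
  pr <- predictModel(model, xrow)
  lab <- as.character(pr$class)
  list(label = lab, prob = unname(pr$prob[1, lab]))
}

#' Route one sample through the cascade
#'
#' Level 1 is the cancer/normal screen; only samples called "cancer"
#' proceed to the three second-level models (metastasis, molecular
#' subtype, histology). Each prediction carries its probability and a
#' confidence flag ("strong" when the probability reaches the model's
#' threshold, else "weak"). A histology-ensemble disagreement propagates
#' as an "ambiguous" histology while the other fields stay intact. The
#' composed readout follows the grammar
#' "<Metastatic|Non-metastatic> <subtype> <histology> cancer".
#'
#' @param bundle a [CascadeBundle-class].
#' @param expression_vector named numeric vector of log2 expression
#'   covering every panel gene (an error names any missing gene); values
#'   above 30 trigger a non-log-scale warning.
#' @return a `CascadeReadout` list: per-level label/probability/flag,
#'   the composed phrase, and abstention bookkeeping.
#' @export
predictSample <- function(bundle, expression_vector) {
  stopifnot(is(bundle, "CascadeBundle"))
  need <- unique(unlist(bundle@panels))
  missing <- setdiff(need, names(expression_vector))
  if (length(missing)) {
    stop("missing panel gene(s): ", paste(missing, collapse = ", "))
  }
  if (max(expression_vector, na.rm = TRUE) > 30) {
    warning("input values exceed 30; expression may not be log2-scaled")
  }
  xrow <- matrix(expression_vector[need], nrow = 1,
                 dimnames = list("sample", need))
  th <- bundle@thresholds
  flag <- function(p, nm) if (p >= th[[nm]]) "strong" else "weak"

  scr <- .levelCall(bundle@screen, xrow)
  out <- list(screen = c(scr, list(flag = flag(scr$prob, "screen"))),
              metastasis = NULL, subtype = NULL, histology = NULL,
              abstained = character(0))
  if (scr$label != "cancer") {
    out$phrase <- "normal"
    class(out) <- "CascadeReadout"
    return(out)
  }
  met <- .levelCall(bundle@metastasis, xrow)
  sub <- .levelCall(bundle@subtype, xrow)
  out$metastasis <- c(met, list(flag = flag(met$prob, "metastasis")))
  out$subtype <- c(sub, list(flag = flag(sub$prob, "subtype")))
  ev <- ensembleVote(bundle@histology, xrow)
  hlab <- ev$decisions$prediction[1]
  if (hlab == "ABSTAIN") {
    out$histology <- list(label = "ambiguous", prob = NA_real_,
                          flag = "weak")
    out$abstained <- "histology"
    hist_word <- "ambiguous"
  } else {
    hp <- ev$decisions$probability[1]
    out$histology <- list(label = hlab, prob = hp,
                          flag = flag(hp, "histology"))
    hist_word <- .histologyNoun(hlab)
  }
  met_word <- if (met$label == "metastatic") "Metastatic" else
    "Non-metastatic"
  out$phrase <- paste(met_word, .subtypeAdjective(sub$label), hist_word,
                      "cancer")
  class(out) <- "CascadeReadout"
  out
}

#' @export
print.CascadeReadout <- function(x, ...) {
  cat("Cascade readout:", x$phrase, "\n")
  for (lv in c("screen", "metastasis", "subtype", "histology")) {
    r <- x[[lv]]
    if (is.null(r)) next
    cat(sprintf("  %-10s %-14s p=%s (%s)\n", lv, r$label,
                ifelse(is.na(r$prob), "NA", sprintf("%.3f", r$prob)),
                r$flag))
  }
  invisible(x)
}

#' Batch cascade prediction
#'
#' Row-wise [predictSample] over a cohort, with per-class summary counts.
#' Per-sample errors (e.g. missing genes) are reported, not fatal.
#'
#' @param bundle a [CascadeBundle-class].
#' @param X gene x sample log2 matrix (or [StageCohort-class]).
#' @return data.frame of readouts (one row per sample) with attribute
#'   `summary`, the table of composed predictions.
#' @export
batchPredict <- function(bundle, X) {
  if (is(X, "StageCohort")) X <- exprMatrix(X)
  X <- as.matrix(X)
  rows <- lapply(colnames(X), function(s) {
    r <- tryCatch(predictSample(bundle, X[, s]), error = function(e) e)
    if (inherits(r, "error")) {
      return(data.frame(sample = s, phrase = NA_character_,
                        screen = NA, screen_prob = NA,
                        metastasis = NA, subtype = NA, histology = NA,
                        error = conditionMessage(r),
                        stringsAsFactors = FALSE))
    }
    data.frame(sample = s, phrase = r$phrase,
               screen = r$screen$label, screen_prob = r$screen$prob,
               metastasis = if (is.null(r$metastasis)) NA_character_ else
                 r$metastasis$label,
               subtype = if (is.null(r$subtype)) NA_character_ else
                 r$subtype$label,
               histology = if (is.null(r$histology)) NA_character_ else
                 r$histology$label,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(), phrase = character(),
                      screen = character(), screen_prob = numeric(),
                      metastasis = character(), subtype = character(),
                      histology = character(), error = character())
  }
  attr(out, "summary") <- table(out$phrase, useNA = "no")
  out
}

#' Train the full cascade from an annotated cohort
#'
#' Convenience wrapper fitting one model per learning problem on the given
#' gene panels, with a stratified split per problem, optional SMOTE
#' balancing of the metastasis training data, and a two-member histology
#' ensemble.
#'
#' @param cohort a log2-scale [StageCohort-class].
#' @param panels named list of gene panels (screen, metastasis, subtype,
#'   histology).
#' @param families named list of family names per problem; histology takes
#'   two. Defaults to random forests plus an xgboost/nn histology pair.
#' @param folds inner CV folds.
#' @param smote logical; apply [smoteBalance] to metastasis training data.
#' @param seed integer.
#' @return a [CascadeBundle-class].
#' @export
trainCascade <- function(cohort, panels,
                         families = list(screen = "random_forest",
                                         metastasis = "random_forest",
                                         subtype = "random_forest",
                                         histology = c("xgboost",
                                                       "nn_1layer")),
                         folds = 5, smote = TRUE, seed = 1L) {
  X <- t(exprMatrix(cohort))
  tissue <- tissueStatus(cohort)
  fitProblem <- function(genes, labels, family, balance = FALSE) {
    keep <- !is.na(labels)
    Xp <- X[keep, genes, drop = FALSE]
    yp <- factor(labels[keep])
    if (balance) {
      b <- smoteBalance(Xp, yp, seed = seed)
      Xp <- b$X; yp <- b$y
    }
    tuneModel(modelSpec(family, seed = seed), Xp, yp, folds = folds)
  }
  cancer <- tissue == "cancer"
  screen <- fitProblem(panels$screen, tissue, families$screen)
  met_lab <- ifelse(cancer, metastasisClass(cohort), NA)
  metastasis <- fitProblem(panels$metastasis, met_lab,
                           families$metastasis, balance = smote)
  sub_lab <- ifelse(cancer, molecularSubtype(cohort), NA)
  subtype <- fitProblem(panels$subtype, sub_lab, families$subtype)
  hist_lab <- ifelse(cancer, histologyClass(cohort), NA)
  histology <- lapply(families$histology, function(f) {
    fitProblem(panels$histology, hist_lab, f)
  })
  cascadeBundle(screen, metastasis, subtype, histology, panels = panels)
}
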