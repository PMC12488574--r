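#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' StageCohort: a stage-annotated expression cohort
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' gene x sample expression matrix together with the per-sample clinical
#' labels used throughout the pipeline: tissue status, AJCC macro stage,
#' metastasis class, IHC-derived molecular subtype and histology. The
#' expression scale ("raw" or "log2") is tracked in the metadata, as is the
#' planted ground truth when the cohort is synthetic.
#'
#' Validity enforces the labelling rules of the cohort design: tissue is
#' normal/cancer, normals carry no stage, and a staged cancer sample is
#' metastatic exactly when its macro stage is IV.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("StageCohort", contains = "SummarizedExperiment")

.validStageCohort <- function(object) {
  msgs <- character()
  cd <- colData(object)
  need <- c("tissue", "stage_macro", "metastasis",
            "molecular_subtype", "histology")
  missing_cols <- setdiff(need, colnames(cd))
  if (length(missing_cols)) {
    return(paste("colData lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  tissue <- as.character(cd$tissue)
  stage <- as.character(cd$stage_macro)
  met <- as.character(cd$metastasis)
  if (!all(tissue %in% c("normal", "cancer"))) {
    msgs <- c(msgs, "tissue must be 'normal' or 'cancer'")
  }
  if (!all(is.na(stage) | stage %in% STAGE_LEVELS)) {
    msgs <- c(msgs, "stage_macro must be I/II/III/IV or NA")
  }
  if (any(tissue == "normal" & !is.na(stage))) {
    msgs <- c(msgs, "normal samples must have stage_macro = NA")
  }
  staged <- tissue == "cancer" & !is.na(stage) & !is.na(met)
  if (any(staged & ((stage == "IV") != (met == "metastatic")))) {
    msgs <- c(msgs, "staged cancer samples must satisfy stage IV <=> metastatic")
  }
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "log2")) {
    msgs <- c(msgs, "metadata()$scale must be 'raw' or 'log2'")
  }
  if (!is.null(sc) && identical(sc, "raw") &&
      any(assay(object) < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "raw-scale expression must be non-negative")
  }
  if (anyDuplicated(rownames(object))) msgs <- c(msgs, "duplicate gene IDs")
  if (anyDuplicated(colnames(object))) msgs <- c(msgs, "duplicate sample IDs")
  if (length(msgs)) msgs else TRUE
}

setValidity("StageCohort", .validStageCohort)

#' Construct a StageCohort
#'
#' @param expr numeric gene x sample matrix with row and column names.
#' @param annotation data.frame (or DataFrame) of per-sample labels with at
#'   least tissue, stage_macro, metastasis, molecular_subtype, histology;
#'   rows matched to the columns of `expr` by the `sample_id` column or by
#'   row names.
#' @param scale expression scale, "raw" or "log2".
#' @param truth optional planted ground truth (list of planted-gene records)
#'   stored in the metadata for recovery testing.
#' @return a [StageCohort-class] object.
#' @examples
#' cfg <- cohortConfig(n_control = 10, n_per_stage = c(5, 5, 5, 5),
#'                     n_genes = 20, seed = 1)
#' cohort <- generateCohort(cfg)
#' cohort
#' @export
StageCohort <- function(expr, annotation, scale = c("log2", "raw"),
                        truth = NULL) {
  scale <- match.arg(scale)
  annotation <- as.data.frame(annotation)
  if ("sample_id" %in% colnames(annotation)) {
    rownames(annotation) <- annotation$sample_id
  }
  if (!all(colnames(expr) %in% rownames(annotation))) {
    stop("annotation does not cover all samples in the expression matrix")
  }
  annotation <- annotation[colnames(expr), , drop = FALSE]
  md <- list(scale = scale)
  if (!is.null(truth)) md$truth <- truth
  se <- SummarizedExperiment(
    assays = list(expr = as.matrix(expr)),
    colData = DataFrame(annotation),
    metadata = md
  )
  obj <- new("StageCohort", se)
  validObject(obj)
  obj
}

#' Accessors for StageCohort labels
#'
#' @param x a [StageCohort-class].
#' @return the corresponding per-sample label vector (or scalar for
#'   `exprScale`, list for `plantedTruth`).
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
exprMatrix <- function(x) assay(x, "expr")

#' @rdname cohort-accessors
#' @export
tissueStatus <- function(x) as.character(colData(x)$tissue)

#' @rdname cohort-accessors
#' @export
stageMacro <- function(x) as.character(colData(x)$stage_macro)

#' @rdname cohort-accessors
#' @export
metastasisClass <- function(x) as.character(colData(x)$metastasis)

#' @rdname cohort-accessors
#' @export
molecularSubtype <- function(x) as.character(colData(x)$molecular_subtype)

#' @rdname cohort-accessors
#' @export
histologyClass <- function(x) as.character(colData(x)$histology)

#' @rdname cohort-accessors
#' @export
exprScale <- function(x) metadata(x)$scale

#' @rdname cohort-accessors
#' @export
plantedTruth <- function(x) metadata(x)$truth

setMethod("show", "StageCohort", function(object) {
  cat("StageCohort:", nrow(object), "genes x", ncol(object), "samples",
      sprintf("(scale: %s)\n", exprScale(object)))
  tissue <- tissueStatus(object)
  cat("  tissue: ", sum(tissue == "normal"), " normal / ",
      sum(tissue == "cancer"), " cancer\n", sep = "")
  st <- table(factor(stageMacro(object), levels = STAGE_LEVELS))
  cat("  stages:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  planted <- Filter(function(x) inherits(x, "plantedGene"),
                    plantedTruth(object))
  if (length(planted)) {
    cls <- vapply(planted, function(p) p$class, character(1))
    cat("  planted truth:", length(cls), "genes (",
        paste(sprintf("%s:%d", names(table(cls)), table(cls)), collapse = ", "),
        ")\n")
  }
  invisible(NULL)
})

#' CascadeBundle: trained models for the staged inference engine
#'
#' Holds the four trained decision points of the cascade: the cancer/normal
#' screen, the metastasis model, the molecular-subtype model and the
#' histology ensemble (a list of one or more member models whose
#' disagreement triggers abstention), together with their gene panels and
#' per-model confidence thresholds.
#'
#' @slot screen,metastasis,subtype tuned model objects (see [tuneModel]).
#' @slot histology list of tuned member models voted at prediction time.
#' @slot panels named list of character gene panels per problem.
#' @slot thresholds named numeric confidence thresholds in (0.5, 1].
#' @export
setClass("CascadeBundle",
  representation(screen = "ANY", metastasis = "ANY", subtype = "ANY",
                 histology = "list", panels = "list",
                 thresholds = "numeric"))

.validCascadeBundle <- function(object) {
  msgs <- character()
  need <- c("screen", "metastasis", "subtype", "histology")
  if (!all(need %in% names(object@panels))) {
    msgs <- c(msgs, "panels must be named screen/metastasis/subtype/histology")
  }
  if (!all(need %in% names(object@thresholds))) {
    msgs <- c(msgs, "thresholds must be named screen/metastasis/subtype/histology")
  }
  th <- object@thresholds
  if (any(th <= 0.5 | th > 1)) msgs <- c(msgs, "thresholds must lie in (0.5, 1]")
  if (!length(object@histology)) msgs <- c(msgs, "histology ensemble is empty")
  if (length(msgs)) msgs else TRUE
}

setValidity("CascadeBundle", .validCascadeBundle)

setMethod("show", "CascadeBundle", function(object) {
  cat("CascadeBundle\n")
  for (p in c("screen", "metastasis", "subtype", "histology")) {
    n_mod <- if (p == "histology") length(object@histology) else 1L
    cat(sprintf("  %-10s panel: %3d genes | threshold %.2f | %d model(s)\n",
                p, length(object@panels[[p]]), object@thresholds[[p]], n_mod))
  }
  invisible(NULL)
})
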