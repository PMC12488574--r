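#' Reference coefficient tables from a TCGA breast-cancer cohort analysis
#'
#' Two small plain-text tables ship with the package as worked-example
#' inputs for the salience rules: `referenceSalientTable()` returns the 24
#' stage-salient genes with their control baseline (beta_0), the four
#' stage-vs-control log fold-change coefficients (beta_1..beta_4), the
#' reported stage label, contrast/control adjusted p-values and regulation
#' status; `referenceLinearTopTable()` returns the ten top-ranked genes of
#' the stage-encoded linear model with their stage-wise log fold-changes
#' and regulation status.
#'
#' These tables are fixed inputs (transcribed published coefficients from
#' the reference TCGA BRCA analysis), used to check that the package's
#' salience and regulation-status rules reproduce the reported labels.
#'
#' @return a data.frame.
#' @export
referenceSalientTable <- function() {
  read.delim(system.file("extdata", "stage_salient_coefficients.tsv",
                         package = "stageSalience"),
             stringsAsFactors = FALSE)
}

#' @rdname referenceSalientTable
#' @export
referenceLinearTopTable <- function() {
  read.delim(system.file("extdata", "linear_model_top_genes.tsv",
                         package = "stageSalience"),
             stringsAsFactors = FALSE)
}
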