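#' Planted-gene record for the synthetic cohort
#'
#' Describes the ground-truth expression behaviour of one simulated gene.
#' Classes mirror the feature classes the pipeline mines: genes dysregulated
#' across all stages (`cancer_wide`), genes extremal in exactly one stage
#' (`stage_salient`), strictly trending genes (`monotonic`), genes with a
#' paradoxical reversing trajectory (`contra`), and markers tied to
#' molecular subtype, histology or metastasis.
#'
#' @param gene_id character gene identifier.
#' @param class one of "null", "cancer_wide", "stage_salient", "monotonic",
#'   "contra", "subtype_marker", "histology_marker", "metastasis_marker".
#' @param effect_lfc log2 fold change of the planted effect vs control
#'   (for "monotonic" the per-stage slope); sign sets the direction unless
#'   `direction` is given.
#' @param stage salient stage "I".."IV" (stage_salient only).
#' @param direction "up" or "down"; defaults to the sign of `effect_lfc`.
#' @param pattern_id contra pattern 1..6 (contra only).
#' @param subtype target subtype (subtype_marker only): "Luminal", "HER2"
#'   or "TNBC".
#' @return a `plantedGene` list record.
#' @export
plantedGene <- function(gene_id, class = "null", effect_lfc = 0,
                        stage = NULL, direction = NULL, pattern_id = NULL,
                        subtype = NULL) {
  classes <- c("null", "cancer_wide", "stage_salient", "monotonic", "contra",
               "subtype_marker", "histology_marker", "metastasis_marker")
  class <- match.arg(class, classes)
  if (class != "null" && abs(effect_lfc) <= 0 && class != "contra") {
    stop("planted class '", class, "' requires a non-zero |effect_lfc|",
         call. = FALSE)
  }
  if (is.null(direction)) direction <- if (effect_lfc < 0) "down" else "up"
  direction <- match.arg(direction, c("up", "down"))
  if (class == "stage_salient") {
    if (is.null(stage) || !stage %in% STAGE_LEVELS) {
      stop("stage_salient gene needs stage in I..IV")
    }
  }
  if (class == "contra") {
    if (is.null(pattern_id) || !pattern_id %in% 1:6) {
      stop("contra gene needs pattern_id in 1..6")
    }
  }
  if (class == "subtype_marker") {
    subtype <- match.arg(subtype, c("Luminal", "HER2", "TNBC"))
  }
  structure(list(gene_id = gene_id, class = class,
                 effect_lfc = abs(effect_lfc), stage = stage,
                 direction = direction, pattern_id = pattern_id,
                 subtype = subtype),
            class = "plantedGene")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the class structure of the TCGA BRCA cohort the
#' pipeline was designed around: 112 controls and 181/616/249/20 staged
#' cancers (so metastatic disease is rare, roughly 16:837 within an 80%
#' training split), IHC subtype fractions from the 567/37/115
#' Luminal/HER2/TNBC breakdown and histology fractions from the 780/202
#' IDC/ILC breakdown. Expression is simulated as Gaussian noise on the log2
#' scale around per-group means; planted genes shift those group means.
#'
#' @param n_control number of normal samples.
#' @param n_per_stage integer counts for stages I..IV.
#' @param n_genes total number of genes (planted genes occupy the first
#'   rows; the remainder are null).
#' @param baseline_mean baseline log2 expression.
#' @param noise_sd within-group standard deviation (log2 units), > 0.
#' @param planted_profiles list of [plantedGene] records; defaults to
#'   [defaultPlantedProfiles()].
#' @param subtype_fractions named proportions over Luminal/HER2/TNBC,
#'   summing to 1.
#' @param histology_fractions named proportions over IDC/ILC, summing to 1.
#' @param seed integer seed; one seed fans out to independent per-layer
#'   substreams (expression, labels, miRNA, methylation).
#' @return a validated `cohortConfig` list.
#' @export
cohortConfig <- function(n_control = 112,
                         n_per_stage = c(I = 181, II = 616, III = 249, IV = 20),
                         n_genes = 600,
                         baseline_mean = 6,
                         noise_sd = 1,
                         planted_profiles = NULL,
                         subtype_fractions = c(Luminal = 567, HER2 = 37,
                                               TNBC = 115) / 719,
                         histology_fractions = c(IDC = 780, ILC = 202) / 982,
                         seed = 1L) {
  n_per_stage <- setNames(as.integer(n_per_stage), STAGE_LEVELS)
  if (any(c(n_control, n_per_stage, n_genes) < 0)) {
    stop("configuration error: counts must be >= 0")
  }
  if (noise_sd <= 0) stop("configuration error: noise_sd must be > 0")
  for (fr in list(subtype_fractions, histology_fractions)) {
    if (abs(sum(fr) - 1) > 1e-9 || any(fr < 0)) {
      stop("configuration error: fractions must be non-negative and sum to 1")
    }
  }
  if (is.null(planted_profiles)) planted_profiles <- defaultPlantedProfiles()
  stopifnot(all(vapply(planted_profiles, inherits, logical(1), "plantedGene")))
  ids <- vapply(planted_profiles, function(p) p$gene_id, character(1))
  if (anyDuplicated(ids)) stop("configuration error: duplicate planted gene IDs")
  if (length(planted_profiles) > n_genes) {
    stop("configuration error: more planted genes than n_genes")
  }
  structure(list(n_control = as.integer(n_control), n_per_stage = n_per_stage,
                 n_genes = as.integer(n_genes), baseline_mean = baseline_mean,
                 noise_sd = noise_sd, planted_profiles = planted_profiles,
                 subtype_fractions = subtype_fractions,
                 histology_fractions = histology_fractions,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Default planted ground truth
#'
#' A compact panel covering every planted class at effect sizes on the
#' scale of the reference cohort analysis (stage-salient deviations 2-4.2
#' log2 units, monotonic slopes ~0.6-0.9 per stage, subtype and histology
#' markers at |lfc| 2.5-3.5).
#'
#' @return list of [plantedGene] records.
#' @export
defaultPlantedProfiles <- function() {
  p <- list(
    plantedGene("CW01", "cancer_wide", 4.3),
    plantedGene("CW02", "cancer_wide", -3.6),
    plantedGene("CW03", "cancer_wide", 5.9),
    plantedGene("SSI1", "stage_salient", 3.4, stage = "I"),
    plantedGene("SSII1", "stage_salient", 3.3, stage = "II"),
    plantedGene("SSII2", "stage_salient", -2.6, stage = "II"),
    plantedGene("SSIII1", "stage_salient", 4.22, stage = "III"),
    plantedGene("SSIII2", "stage_salient", -2.9, stage = "III"),
    plantedGene("SSIV1", "stage_salient", -4.0, stage = "IV"),
    plantedGene("SSIV2", "stage_salient", -5.7, stage = "IV"),
    plantedGene("MONO1", "monotonic", 0.62),
    plantedGene("MONO2", "monotonic", -0.89),
    plantedGene("MONO3", "monotonic", 0.74),
    plantedGene("CONTRA1", "contra", 3.0, pattern_id = 1),
    plantedGene("CONTRA2", "contra", 3.0, pattern_id = 5),
    plantedGene("SUBL1", "subtype_marker", 3.5, subtype = "Luminal"),
    plantedGene("SUBH1", "subtype_marker", 3.0, subtype = "HER2"),
    plantedGene("SUBT1", "subtype_marker", 3.0, subtype = "TNBC"),
    plantedGene("HIST1", "histology_marker", 2.6),
    plantedGene("HIST2", "histology_marker", -2.8),
    plantedGene("MET1", "metastasis_marker", 3.2),
    plantedGene("MET2", "metastasis_marker", -3.0)
  )
  p
}

# per-group mean offsets (control, I..IV) for one planted gene, log2 units
.plantedOffsets <- function(p) {
  sgn <- if (p$direction == "down") -1 else 1
  e <- p$effect_lfc
  off <- switch(p$class,
    null = rep(0, 5),
    cancer_wide = c(0, rep(sgn * e, 4)),
    stage_salient = {
      v <- rep(sgn * e * 0.6, 4)
      v[stageIndex(p$stage)] <- sgn * e
      c(0, v)
    },
    monotonic = c(0, sgn * e * 1:4),
    contra = {
      templates <- list(c(1, 0.3, -0.3, -0.6),   # peak I, ends below control
                        c(0.5, 1, -0.3, -0.6),   # peak II
                        c(0.3, 0.6, 1, -0.6))    # peak III
      id <- p$pattern_id
      tmpl <- if (id <= 3) templates[[id]] else -templates[[id - 3]]
      c(0, tmpl * e)
    },
    # subtype/histology/metastasis markers are handled sample-wise
    subtype_marker = rep(0, 5),
    histology_marker = rep(0, 5),
    metastasis_marker = rep(0, 5)
  )
  off
}

# exact label allocation honouring fractions (largest remainder), shuffled
.allocateLabels <- function(n, fractions) {
  counts <- largestRemainder(fractions, n)
  sample(rep(names(fractions), counts))
}

#' Generate a synthetic stage-annotated cohort
#'
#' Draws a log2-scale expression matrix with per-group means set by the
#' planted profiles in the configuration, and a per-sample annotation with
#' tissue, macro stage, metastasis class (metastatic iff stage IV),
#' molecular subtype and histology allocated exactly according to the
#' configured fractions. Deterministic under a fixed seed.
#'
#' @param config a [cohortConfig].
#' @return a [StageCohort-class] with the planted truth in its metadata.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  seeds <- layerSeeds(config$seed)
  n_cancer <- sum(config$n_per_stage)
  n <- config$n_control + n_cancer

  set.seed(seeds[2])  # label substream
  stage <- c(rep(NA_character_, config$n_control),
             rep(STAGE_LEVELS, config$n_per_stage))
  tissue <- c(rep("normal", config$n_control), rep("cancer", n_cancer))
  subtype <- rep(NA_character_, n)
  histology <- rep(NA_character_, n)
  cancer_idx <- which(tissue == "cancer")
  subtype[cancer_idx] <- .allocateLabels(n_cancer, config$subtype_fractions)
  histology[cancer_idx] <- .allocateLabels(n_cancer, config$histology_fractions)
  metastasis <- ifelse(tissue == "normal", NA_character_,
                       ifelse(stage == "IV", "metastatic", "non_metastatic"))
  sample_id <- sprintf("S%04d", seq_len(n))
  annotation <- data.frame(
    sample_id = sample_id, tissue = tissue,
    stage_raw = ifelse(is.na(stage), NA_character_, tolower(stage)),
    stage_macro = stage, metastasis = metastasis,
    molecular_subtype = subtype, histology = histology,
    stringsAsFactors = FALSE
  )

  set.seed(seeds[1])  # expression substream
  planted <- config$planted_profiles
  n_planted <- length(planted)
  gene_ids <- c(vapply(planted, function(p) p$gene_id, character(1)),
                sprintf("NULL%04d", seq_len(config$n_genes - n_planted)))
  group <- ifelse(is.na(stage), "control", stage)
  group_col <- match(group, c("control", STAGE_LEVELS))

  X <- matrix(rnorm(config$n_genes * n, mean = config$baseline_mean,
                    sd = config$noise_sd),
              nrow = config$n_genes, ncol = n,
              dimnames = list(gene_ids, sample_id))
  for (i in seq_along(planted)) {
    p <- planted[[i]]
    X[i, ] <- X[i, ] + .plantedOffsets(p)[group_col]
    sgn <- if (p$direction == "down") -1 else 1
    if (p$class == "subtype_marker") {
      hit <- !is.na(subtype) & subtype == p$subtype
      X[i, hit] <- X[i, hit] + sgn * p$effect_lfc
    } else if (p$class == "histology_marker") {
      hit <- !is.na(histology) & histology == "ILC"
      X[i, hit] <- X[i, hit] + sgn * p$effect_lfc
    } else if (p$class == "metastasis_marker") {
      hit <- !is.na(metastasis) & metastasis == "metastatic"
      X[i, hit] <- X[i, hit] + sgn * p$effect_lfc
    }
  }

  StageCohort(X, annotation, scale = "log2",
              truth = c(planted, list(layer_seeds = seeds, config = config)))
}

# pull the plantedGene records back out of a cohort's truth metadata
plantedGenes <- function(cohort) {
  tr <- plantedTruth(cohort)
  Filter(function(x) inherits(x, "plantedGene"), tr)
}

#' Multi-omic ground truth for regulator and methylation layers
#'
#' @param mirna_target_map data.frame with columns `mirna`, `target_gene`,
#'   `direction` ("up"/"down": regulator behaviour in cancer),
#'   `salient_stage` ("I".."IV") and logical `temporal_concordant`.
#' @param methylation_couplings list of records, each a list with `gene`,
#'   `component_means` (beta scale, in [0,1]), `component_sds`,
#'   `weights` (summing to 1), `correlation_sign` (+1/-1) and `n_probes`.
#' @return a validated `multiOmicTruth` list.
#' @export
multiOmicTruth <- function(mirna_target_map = NULL,
                           methylation_couplings = list()) {
  if (!is.null(mirna_target_map)) {
    need <- c("mirna", "target_gene", "direction", "salient_stage",
              "temporal_concordant")
    if (!all(need %in% colnames(mirna_target_map))) {
      stop("mapping error: mirna_target_map needs columns ",
           paste(need, collapse = ", "))
    }
    if (!all(mirna_target_map$direction %in% c("up", "down"))) {
      stop("mapping error: regulator directions must be 'up' or 'down'")
    }
  }
  for (cp in methylation_couplings) {
    if (any(cp$component_means < 0 | cp$component_means > 1)) {
      stop("configuration error: beta component means must lie in [0, 1]")
    }
    if (abs(sum(cp$weights) - 1) > 1e-9) {
      stop("configuration error: mixture weights must sum to 1")
    }
    if (!cp$correlation_sign %in% c(-1, 1)) {
      stop("configuration error: correlation_sign must be -1 or +1")
    }
  }
  structure(list(mirna_target_map = mirna_target_map,
                 methylation_couplings = methylation_couplings),
            class = "multiOmicTruth")
}

#' Default multi-omic truth matched to [defaultPlantedProfiles()]
#'
#' Regulators are planted opposite in direction to their targets (the
#' oncomiR/TSmiR pattern) and, where flagged temporally concordant, salient
#' no later than the target.
#'
#' @return a [multiOmicTruth].
#' @export
defaultMultiOmicTruth <- function() {
  map <- data.frame(
    mirna = c("mir-A", "mir-B", "mir-C", "mir-D"),
    target_gene = c("SSIII1", "SSIV1", "SSII2", "SSIII2"),
    direction = c("down", "up", "up", "up"),
    salient_stage = c("II", "III", "II", "IV"),
    temporal_concordant = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  couplings <- list(
    list(gene = "SSIII1", component_means = c(0.2, 0.7),
         component_sds = c(0.05, 0.05), weights = c(0.5, 0.5),
         correlation_sign = -1, n_probes = 3),
    list(gene = "SSIV1", component_means = c(0.15, 0.5, 0.85),
         component_sds = c(0.04, 0.04, 0.04), weights = c(1, 1, 1) / 3,
         correlation_sign = -1, n_probes = 4),
    list(gene = "SSII2", component_means = c(0.3, 0.8),
         component_sds = c(0.05, 0.05), weights = c(0.6, 0.4),
         correlation_sign = -1, n_probes = 2)
  )
  multiOmicTruth(map, couplings)
}

#' Generate the miRNA regulator layer
#'
#' Each planted regulator carries its own stage-salient profile and an
#' anti-coupling to its target gene's expression residuals, so that
#' regulator and target are negatively correlated sample-wise. Couplings
#' flagged temporally concordant must have a regulator salient stage no
#' later than the target's (validated against the cohort's planted truth).
#'
#' @param truth a [multiOmicTruth].
#' @param cohort the [StageCohort-class] carrying the mRNA layer.
#' @param n_null number of additional unregulating null miRNAs.
#' @param coupling strength of the anti-correlation coupling (fraction of a
#'   standardized target residual subtracted from the regulator).
#' @param seed integer; defaults to the cohort's miRNA substream.
#' @return a miRNA x sample log2 expression matrix.
#' @export
generateMirnaLayer <- function(truth, cohort, n_null = 30, coupling = 0.4,
                               seed = NULL) {
  stopifnot(inherits(truth, "multiOmicTruth"))
  map <- truth$mirna_target_map
  X <- exprMatrix(cohort)
  if (!is.null(map) && nrow(map)) {
    missing <- setdiff(map$target_gene, rownames(X))
    if (length(missing)) {
      stop("mapping error: regulator targets absent from the mRNA layer: ",
           paste(missing, collapse = ", "))
    }
    # temporal flag implies regulator salience at or before target salience
    planted <- plantedGenes(cohort)
    tstage <- vapply(planted, function(p) {
      if (identical(p$class, "stage_salient")) p$stage else NA_character_
    }, character(1))
    names(tstage) <- vapply(planted, function(p) p$gene_id, character(1))
    for (i in seq_len(nrow(map))) {
      tg <- tstage[map$target_gene[i]]
      if (map$temporal_concordant[i] && !is.na(tg) &&
          stageIndex(map$salient_stage[i]) > stageIndex(tg)) {
        stop("configuration error: temporally concordant regulator '",
             map$mirna[i], "' is salient later than its target")
      }
    }
  }
  if (is.null(seed)) seed <- plantedTruth(cohort)$layer_seeds[3]
  set.seed(as.integer(seed))

  cfg <- plantedTruth(cohort)$config
  baseline <- if (is.null(cfg)) 6 else cfg$baseline_mean
  noise_sd <- if (is.null(cfg)) 1 else cfg$noise_sd
  n <- ncol(X)
  stage <- stageMacro(cohort)
  group_col <- match(ifelse(is.na(stage), "control", stage),
                     c("control", STAGE_LEVELS))
  n_reg <- if (is.null(map)) 0L else nrow(map)
  ids <- c(if (n_reg) map$mirna, sprintf("mir-null%03d", seq_len(n_null)))
  M <- matrix(rnorm(length(ids) * n, baseline, noise_sd),
              nrow = length(ids), dimnames = list(ids, colnames(X)))
  if (n_reg) {
    for (i in seq_len(n_reg)) {
      pg <- plantedGene(map$mirna[i], "stage_salient", 3,
                        stage = map$salient_stage[i],
                        direction = map$direction[i])
      tg <- X[map$target_gene[i], ]
      resid <- (tg - mean(tg)) / max(sd(tg), 1e-8)
      M[i, ] <- M[i, ] + .plantedOffsets(pg)[group_col] - coupling * resid
    }
  }
  M
}

#' Generate the methylation beta layer
#'
#' For each coupled gene, probes draw beta values from the declared mixture;
#' samples are assigned to components by their expression rank (inverted
#' when `correlation_sign` is -1), producing the requested sign of the
#' beta-vs-expression correlation. Uncoupled probes are logit-normal noise.
#'
#' @param truth a [multiOmicTruth].
#' @param cohort the [StageCohort-class] with the mRNA layer.
#' @param n_null_probes number of probes for unreferenced null genes.
#' @param seed integer; defaults to the cohort's methylation substream.
#' @return list with `beta` (probe x sample matrix in [0,1]) and
#'   `probe_map` (data.frame probe -> gene).
#' @export
generateMethylationLayer <- function(truth, cohort, n_null_probes = 20,
                                     seed = NULL) {
  stopifnot(inherits(truth, "multiOmicTruth"))
  X <- exprMatrix(cohort)
  if (is.null(seed)) seed <- plantedTruth(cohort)$layer_seeds[4]
  set.seed(as.integer(seed))
  n <- ncol(X)
  rows <- list(); map_probe <- character(); map_gene <- character()
  k <- 0L
  for (cp in truth$methylation_couplings) {
    if (!cp$gene %in% rownames(X)) {
      stop("mapping error: coupled gene '", cp$gene,
           "' absent from the mRNA layer")
    }
    expr <- X[cp$gene, ]
    # rank-based component assignment; -1 => high expression, low beta
    ord_means <- order(cp$component_means)
    sizes <- largestRemainder(cp$weights[ord_means], n)
    comp_sorted <- rep(seq_along(sizes), sizes)  # index into ord_means
    r <- rank(expr, ties.method = "first")
    assign_rank <- if (cp$correlation_sign < 0) (n + 1) - r else r
    comp <- ord_means[comp_sorted[assign_rank]]
    for (j in seq_len(cp$n_probes)) {
      k <- k + 1L
      beta <- cp$component_means[comp] +
        rnorm(n, 0, cp$component_sds[comp])
      rows[[k]] <- pmin(pmax(beta, 0), 1)
      map_probe <- c(map_probe, sprintf("cg%07d", k))
      map_gene <- c(map_gene, cp$gene)
    }
  }
  for (j in seq_len(n_null_probes)) {
    k <- k + 1L
    rows[[k]] <- plogis(rnorm(n, 0, 1))
    map_probe <- c(map_probe, sprintf("cg%07d", k))
    map_gene <- c(map_gene, sprintf("MNULL%03d", j))
  }
  beta <- do.call(rbind, rows)
  dimnames(beta) <- list(map_probe, colnames(X))
  list(beta = beta,
       probe_map = data.frame(probe = map_probe, gene = map_gene,
                              stringsAsFactors = FALSE))
}

#' Write / read cohort tables
#'
#' Tab-delimited interchange: gene x sample matrices with a header row of
#' sample IDs, and the annotation as a sample table.
#'
#' @param cohort a [StageCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(dir, "expression.tsv")
  af <- file.path(dir, "annotation.tsv")
  write.table(data.frame(gene_id = rownames(cohort), exprMatrix(cohort),
                         check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(colData(cohort)), af, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expression = ef, annotation = af))
}

#' @rdname writeCohortTables
#' @param expr_file,annotation_file paths written by [writeCohortTables].
#' @param scale expression scale flag of the stored matrix.
#' @export
readCohortTables <- function(expr_file, annotation_file, scale = "log2") {
  tab <- read.delim(expr_file, check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- tab[[1]]
  ann <- read.delim(annotation_file)
  StageCohort(X, ann, scale = scale)
}
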