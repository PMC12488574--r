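#' @importFrom mclust Mclust mclustBIC
NULL

#' Stage-salient miRNA mining
#'
#' Applies the identical two-level contrast protocol used for mRNA
#' ([fitStageModel] + [callStageSalient]) to a miRNA expression matrix.
#'
#' @param X_mir miRNA x sample log2 matrix.
#' @param groups per-sample group labels over control/I/II/III/IV.
#' @param ... thresholds passed to [callStageSalient].
#' @return stage-salience data.frame (see [callStageSalient]).
#' @export
mirnaStageSalience <- function(X_mir, groups, ...) {
  fit <- fitStageModel(X_mir, coding = "cell_means", groups = groups)
  callStageSalient(fit, ...)
}

#' Direction concordance between a regulator and its target
#'
#' A miRNA is concordant in expression with a target gene when their
#' regulation directions are opposite (regulator overexpression with
#' target downregulation, or vice versa).
#'
#' @param gene_direction,mirna_direction "Up"/"Down" (case-insensitive).
#' @return logical flag (vectorized).
#' @export
expressionConcordance <- function(gene_direction, mirna_direction) {
  g <- tolower(as.character(gene_direction))
  m <- tolower(as.character(mirna_direction))
  stopifnot(all(g %in% c("up", "down")), all(m %in% c("up", "down")))
  g != m
}

#' Temporal concordance between regulator and target salience
#'
#' Exists when the regulator's salient stage is at least as early as the
#' target gene's salient stage. Only meaningful when expression
#' concordance already holds.
#'
#' @param mirna_stage,gene_stage stage labels "I".."IV".
#' @return logical flag (vectorized).
#' @export
temporalConcordance <- function(mirna_stage, gene_stage) {
  stageIndex(mirna_stage) <= stageIndex(gene_stage)
}

#' Join salient miRNAs to salient target genes
#'
#' One concordance record per (salient miRNA, salient target gene) pair in
#' the target map, carrying both the direction-concordance flag and, when
#' direction concordance holds, the temporal flag (NA otherwise). Salient
#' genes with no salient regulator and salient regulators with no salient
#' target are listed separately as orphans.
#'
#' @param mirna_salience salience data.frame for the miRNA layer.
#' @param target_map data.frame with columns `mirna` and `gene`.
#' @param gene_salience salience data.frame for the mRNA layer.
#' @return list with `records` (gene, gene_direction, gene_salient_stage,
#'   mirna, mirna_direction, mirna_salient_stage, expression_concordant,
#'   temporal_concordant), `unregulated_genes`, `targetless_mirnas`.
#' @export
joinTargets <- function(mirna_salience, target_map, gene_salience) {
  if (!all(c("mirna", "gene") %in% colnames(target_map))) {
    stop("malformed target map: need columns 'mirna' and 'gene'")
  }
  recs <- list()
  if (nrow(target_map)) {
    for (i in seq_len(nrow(target_map))) {
      mi <- match(target_map$mirna[i], mirna_salience$gene)
      gi <- match(target_map$gene[i], gene_salience$gene)
      if (is.na(mi) || is.na(gi)) next
      ec <- expressionConcordance(gene_salience$direction[gi],
                                  mirna_salience$direction[mi])
      tc <- if (ec) {
        temporalConcordance(mirna_salience$salient_stage[mi],
                            gene_salience$salient_stage[gi])
      } else NA
      recs[[length(recs) + 1]] <- data.frame(
        gene = gene_salience$gene[gi],
        gene_direction = gene_salience$direction[gi],
        gene_salient_stage = gene_salience$salient_stage[gi],
        mirna = mirna_salience$gene[mi],
        mirna_direction = mirna_salience$direction[mi],
        mirna_salient_stage = mirna_salience$salient_stage[mi],
        expression_concordant = ec, temporal_concordant = tc,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), gene_direction = character(),
               gene_salient_stage = character(), mirna = character(),
               mirna_direction = character(),
               mirna_salient_stage = character(),
               expression_concordant = logical(),
               temporal_concordant = logical())
  list(records = records,
       unregulated_genes = setdiff(gene_salience$gene, records$gene),
       targetless_mirnas = setdiff(mirna_salience$gene, records$mirna))
}

#' Methylation-expression correlation (driver screen)
#'
#' Pearson correlation between a gene cluster's methylation (beta) and
#' the gene's expression over matched samples. A cluster is
#' transcriptionally predictive ("driver") when r is at most `r_max`
#' (default -0.3) with p below `p_max`.
#'
#' @param beta numeric vector (cluster methylation per sample) or matrix
#'   (clusters x samples).
#' @param expression numeric vector of the gene's expression, or matrix
#'   aligned row-wise with `beta`.
#' @param r_max correlation threshold (driver iff r <= r_max).
#' @param p_max p-value threshold.
#' @return data.frame with r, p and the driver flag; zero-variance input
#'   yields NA and no driver call.
#' @export
methylationExpressionCorrelation <- function(beta, expression,
                                             r_max = -0.3, p_max = 0.001) {
  if (is.null(dim(beta))) beta <- rbind(beta)
  if (is.null(dim(expression))) {
    expression <- matrix(rep(expression, nrow(beta)), nrow = nrow(beta),
                         byrow = TRUE)
  }
  out <- lapply(seq_len(nrow(beta)), function(i) {
    b <- beta[i, ]; e <- expression[i, ]
    if (sd(b) == 0 || sd(e) == 0) {
      return(data.frame(r = NA_real_, p = NA_real_, driver = FALSE))
    }
    ct <- cor.test(b, e, method = "pearson")
    data.frame(r = unname(ct$estimate), p = ct$p.value,
               driver = unname(ct$estimate) <= r_max & ct$p.value < p_max)
  })
  res <- do.call(rbind, out)
  rownames(res) <- rownames(beta)
  res
}

#' Differential methylation by rank-sum testing
#'
#' Wilcoxon rank-sum test per row (gene or cluster) between two sample
#' groups, BH-adjusted across rows; the effect size is the difference of
#' group mean betas (group2 - group1). A row is called differentially
#' methylated when adj p < `p_max` and |effect| > `effect_min`; the
#' effect sign labels the change Hyper (positive) or Hypo.
#'
#' @param beta rows x samples beta matrix.
#' @param groups two-level factor over samples (>= 3 per level).
#' @param p_max adjusted-p threshold, default 0.05.
#' @param effect_min absolute effect-size threshold, default 0.1.
#' @return data.frame with effect, p, padj, dm_type, called.
#' @export
differentialMethylation <- function(beta, groups, p_max = 0.05,
                                    effect_min = 0.1) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2)
  if (any(table(groups) < 3)) stop("need >= 3 samples per group")
  if (is.null(dim(beta))) beta <- rbind(beta)
  g1 <- groups == levels(groups)[1]
  res <- t(apply(beta, 1, function(b) {
    eff <- mean(b[!g1]) - mean(b[g1])
    p <- if (length(unique(b)) == 1) 1 else
      suppressWarnings(wilcox.test(b[!g1], b[g1])$p.value)
    c(effect = eff, p = p)
  }))
  out <- data.frame(effect = res[, "effect"], p = res[, "p"],
                    padj = p.adjust(res[, "p"], "BH"))
  out$dm_type <- ifelse(out$effect > 0, "Hyper", "Hypo")
  out$called <- out$padj < p_max & abs(out$effect) > effect_min
  out
}

#' Fit a beta-value mixture model
#'
#' Gaussian mixtures with 1..`max_components` components fit by EM on
#' logit-transformed beta values; the component count is chosen by BIC and
#' fitted means are reported back on the beta scale.
#'
#' @param beta numeric vector of beta values (>= 20 observations).
#' @param max_components maximum number of components, default 3.
#' @return a `MixtureFit` list: n_components, means (beta scale), m_means,
#'   sds (logit scale), weights, bic (per candidate count).
#' @export
fitBetaMixture <- function(beta, max_components = 3) {
  if (length(beta) < 20) stop("need >= 20 observations for a mixture fit")
  m <- betaToM(beta)
  fit <- tryCatch(
    Mclust(m, G = seq_len(max_components), modelNames = "V",
           verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fitting did not converge; reporting one component")
    return(structure(list(n_components = 1L, means = mean(clip01(beta)),
                          m_means = mean(m), sds = sd(m), weights = 1,
                          bic = NA_real_), class = "MixtureFit"))
  }
  structure(list(n_components = fit$G,
                 means = as.numeric(mToBeta(fit$parameters$mean)),
                 m_means = as.numeric(fit$parameters$mean),
                 sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
                 weights = as.numeric(fit$parameters$pro),
                 bic = fit$BIC[, 1], classification = fit$classification),
            class = "MixtureFit")
}

#' Cluster the CpG probes of one gene by correlation
#'
#' Average-linkage hierarchical clustering on 1 - Pearson r distances,
#' with the tree cut at the smallest number of clusters for which every
#' within-cluster probe pair correlates above `r_min`. Singleton-safe.
#'
#' @param beta probes x samples beta matrix for one gene.
#' @param r_min within-cluster pairwise correlation floor, default 0.7.
#' @return integer cluster assignment named by probe.
#' @export
clusterProbes <- function(beta, r_min = 0.7) {
  if (is.null(dim(beta))) beta <- rbind(beta)
  n <- nrow(beta)
  if (n == 1) return(setNames(1L, rownames(beta)))
  r <- suppressWarnings(cor(t(beta)))
  r[is.na(r)] <- 0
  hc <- hclust(as.dist(1 - r), method = "average")
  for (k in seq_len(n)) {
    cl <- cutree(hc, k = k)
    ok <- all(vapply(unique(cl), function(g) {
      idx <- which(cl == g)
      if (length(idx) == 1) return(TRUE)
      all(r[idx, idx][upper.tri(r[idx, idx])] > r_min)
    }, logical(1)))
    if (ok) return(cl)
  }
  setNames(seq_len(n), rownames(beta))
}

#' Stage-salience calls on the methylation layer
#'
#' Runs the two-level contrast protocol on one of three gene-level
#' representations of the beta matrix: probe-averaged betas ("averep"),
#' logit-transformed M-values of the probe averages ("mvalue"), or
#' per-sample mixture-component means from a BIC-selected beta mixture
#' ("methylmix"). Effect-size thresholds default to the representation's
#' natural scale (0.1 beta; 1 logit unit).
#'
#' @param beta probes x samples beta matrix.
#' @param probe_map data.frame probe -> gene.
#' @param groups per-sample labels over control/I/II/III/IV.
#' @param route "averep", "mvalue" or "methylmix".
#' @param lfc_min level-I effect threshold (route-scale default).
#' @param p_max,contrast_p_max significance thresholds.
#' @param n_top_per_stage per-stage cap, default Inf (no truncation).
#' @return stage-salience data.frame over genes.
#' @export
methylationStageSalience <- function(beta, probe_map, groups,
                                     route = c("averep", "mvalue",
                                               "methylmix"),
                                     lfc_min = NULL, p_max = 0.001,
                                     contrast_p_max = 0.05,
                                     n_top_per_stage = Inf) {
  route <- match.arg(route)
  genes <- unique(probe_map$gene)
  avg <- t(vapply(genes, function(g) {
    pr <- probe_map$probe[probe_map$gene == g]
    colMeans(beta[pr, , drop = FALSE])
  }, numeric(ncol(beta))))
  rownames(avg) <- genes
  M <- switch(route,
    averep = avg,
    mvalue = betaToM(avg),
    methylmix = {
      t(apply(avg, 1, function(b) {
        fit <- fitBetaMixture(b)
        fit$m_means[fit$classification]
      }))
    })
  if (is.null(lfc_min)) lfc_min <- if (route == "averep") 0.1 else 1
  fit <- fitStageModel(M, coding = "cell_means", groups = groups)
  callStageSalient(fit, lfc_min = lfc_min, p_max = p_max,
                   contrast_p_max = contrast_p_max,
                   n_top_per_stage = n_top_per_stage)
}

#' Consensus of stage-informed methylation models
#'
#' A gene is consensus-salient when every provided call set assigns it
#' the same salient stage. Monotone: adding a further agreeing call set
#' never removes a consensus gene.
#'
#' @param ... two or more salience data.frames (gene / salient_stage).
#' @return data.frame of genes with the agreed stage.
#' @export
methylationSalienceConsensus <- function(...) {
  calls <- list(...)
  stopifnot(length(calls) >= 1)
  shared <- Reduce(intersect, lapply(calls, function(d) d$gene))
  keep <- vapply(shared, function(g) {
    stages <- vapply(calls, function(d) d$salient_stage[d$gene == g][1],
                     character(1))
    length(unique(stages)) == 1
  }, logical(1))
  shared <- shared[keep]
  data.frame(gene = shared,
             salient_stage = vapply(shared, function(g) {
               calls[[1]]$salient_stage[calls[[1]]$gene == g][1]
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Temporal concordance of methylation with expression
#'
#' The methylation pattern of a gene is concordant with its expression
#' when the direction pairing is repressive (hypermethylation with
#' downregulated expression, or hypomethylation with upregulation) and
#' maximal methylation salience occurs no later than the expression
#' extremum (ties concordant by default).
#'
#' @param meth_salient_stage,expr_extremum_stage stage labels "I".."IV".
#' @param dm_type "Hyper" or "Hypo".
#' @param expr_direction "Up" or "Down".
#' @param ties "concordant" (default) or "discordant": whether an equal
#'   stage counts as ahead.
#' @return logical flag (vectorized).
#' @export
methylationTemporalConcordance <- function(meth_salient_stage,
                                           expr_extremum_stage,
                                           dm_type, expr_direction,
                                           ties = c("concordant",
                                                    "discordant")) {
  ties <- match.arg(ties)
  dm <- tolower(as.character(dm_type))
  ed <- tolower(as.character(expr_direction))
  repressive <- (dm == "hyper" & ed == "down") |
    (dm == "hypo" & ed == "up")
  mi <- stageIndex(meth_salient_stage)
  ei <- stageIndex(expr_extremum_stage)
  ahead <- if (ties == "concordant") mi <= ei else mi < ei
  repressive & ahead
}
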