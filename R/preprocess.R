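#' Remove genes with minimal expression variation
#'
#' Drops genes whose sample standard deviation falls below `sigma_min`;
#' the boundary (sd exactly equal to `sigma_min`) is retained. Row order
#' of the surviving genes is preserved.
#'
#' @param X gene x sample numeric matrix (or [StageCohort-class]).
#' @param sigma_min minimum standard deviation to keep a gene.
#' @return object of the same type with low-variance genes removed.
#' @export
filterLowVariance <- function(X, sigma_min = 1) {
  is_cohort <- is(X, "StageCohort")
  M <- if (is_cohort) exprMatrix(X) else X
  sds <- apply(M, 1, sd)
  keep <- sds >= sigma_min
  if (!any(keep)) warning("all genes removed by the variance filter")
  if (is_cohort) X[keep, ] else M[keep, , drop = FALSE]
}

#' Merge AJCC sub-stages into macro stages
#'
#' Collapses AJCC pathologic stage strings to the four macro categories:
#' 1/1A/1B -> I, 2/2A/2B -> II, 3/3A/3B/3C -> III, 4 -> IV. Stage X,
#' missing and unrecognized values map to NA (such cancer samples are
#' dropped before stage-wise modelling). Total and idempotent: macro
#' labels map to themselves.
#'
#' @param stage_raw character vector of AJCC stage strings (with or
#'   without a "stage " prefix, any case).
#' @return factor-free character vector over I/II/III/IV/NA.
#' @export
mergeSubstages <- function(stage_raw) {
  s <- toupper(trimws(as.character(stage_raw)))
  s <- sub("^STAGE\\s*", "", s)
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "1A", "1B", "I", "IA", "IB")] <- "I"
  out[s %in% c("2", "2A", "2B", "II", "IIA", "IIB")] <- "II"
  out[s %in% c("3", "3A", "3B", "3C", "III", "IIIA", "IIIB", "IIIC")] <- "III"
  out[s %in% c("4", "IV")] <- "IV"
  out
}

#' Derive the molecular subtype from IHC status
#'
#' Triple-negative (ER-, PgR-, HER2-) samples are TNBC; hormone-receptor
#' negative but HER2-positive samples are HER2; any hormone-receptor
#' positivity gives a Luminal call. The Luminal A/B distinction requires a
#' Ki-67 labelling index: when `ki67` is missing the two are lumped as
#' "Luminal". Missing IHC fields propagate: a sample with all three
#' receptors unobserved gets NA.
#'
#' @param er,pgr,her2 character vectors over "+", "-" (NA allowed).
#' @param ki67 numeric proportion or NA; threshold 0.14 splits Luminal A/B.
#' @return character vector over Luminal / Luminal A / Luminal B / HER2 /
#'   TNBC / NA.
#' @export
deriveMolecularSubtype <- function(er, pgr, her2, ki67 = NA_real_) {
  n <- max(length(er), length(pgr), length(her2))
  er <- rep_len(as.character(er), n); pgr <- rep_len(as.character(pgr), n)
  her2 <- rep_len(as.character(her2), n); ki67 <- rep_len(ki67, n)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    e <- er[i]; p <- pgr[i]; h <- her2[i]
    if (all(is.na(c(e, p, h)))) next
    hr_pos <- isTRUE(e == "+") || isTRUE(p == "+")
    hr_neg <- isTRUE(e == "-") && isTRUE(p == "-")
    if (hr_pos) {
      out[i] <- if (is.na(ki67[i])) "Luminal" else
        if (ki67[i] < 0.14 && !isTRUE(h == "+")) "Luminal A" else "Luminal B"
    } else if (hr_neg && isTRUE(h == "+")) {
      out[i] <- "HER2"
    } else if (hr_neg && isTRUE(h == "-")) {
      out[i] <- "TNBC"
    }
  }
  out
}

#' Variance-stabilize a raw expression matrix
#'
#' Applies the strictly monotone log2(x + 0.5) transform and, optionally,
#' precision weights from a lowess fit of sqrt(residual sd) against mean
#' log2 expression across genes (the mean-variance trend used in weighted
#' least squares), so that observations at expression levels with inflated
#' variance are down-weighted.
#'
#' @param X non-negative gene x sample matrix (raw scale) or a raw-scale
#'   [StageCohort-class].
#' @param weights logical; also compute voom-style precision weights.
#' @return a list with `log2` (transformed matrix) and `weights` (matrix or
#'   NULL); for a cohort input the cohort is returned with the transformed
#'   assay and `scale = "log2"`, weights in `metadata()$voom_weights`.
#' @export
varianceStabilize <- function(X, weights = TRUE) {
  is_cohort <- is(X, "StageCohort")
  M <- if (is_cohort) exprMatrix(X) else X
  if (any(M < 0, na.rm = TRUE)) stop("negative values in raw expression input")
  L <- log2(M + 0.5)
  W <- NULL
  if (weights) {
    mu <- rowMeans(L)
    s <- sqrt(apply(L, 1, sd))
    if (all(s == s[1])) {
      W <- matrix(1, nrow(L), ncol(L), dimnames = dimnames(L))
    } else {
      tr <- lowess(mu, s, f = 0.5)
      # interpolate the trend at each observation's fitted level
      pred <- approx(tr$x, tr$y, xout = mu, rule = 2)$y
      w_gene <- 1 / pmax(pred, 1e-4)^4  # inverse predicted variance
      W <- matrix(w_gene, nrow(L), ncol(L), dimnames = dimnames(L))
    }
  }
  if (is_cohort) {
    out <- StageCohort(L, as.data.frame(colData(X)), scale = "log2",
                       truth = plantedTruth(X))
    metadata(out)$voom_weights <- W
    return(out)
  }
  list(log2 = L, weights = W)
}

#' Stratified train/test split
#'
#' Splits samples into train and test sets, stratified on a label so each
#' stratum contributes round(stratum_size x train_fraction) training
#' samples, corrected by the largest-remainder rule so the overall train
#' size equals round(n x train_fraction). Strata with fewer than 2 samples
#' go wholly to training with a warning.
#'
#' @param labels per-sample stratification labels (no NAs).
#' @param train_fraction fraction in (0, 1), default 0.8.
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratifiedSplit <- function(labels, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (anyNA(labels)) stop("stratification label contains NA")
  labels <- as.character(labels)
  set.seed(as.integer(seed))
  n <- length(labels)
  strata <- split(seq_len(n), labels)
  sizes <- lengths(strata)
  target_total <- round(n * train_fraction)
  # per-stratum targets, largest-remainder corrected to the overall total
  raw <- sizes * train_fraction
  base <- pmin(floor(raw + 0.5), sizes)  # round-half-up per stratum
  diffr <- target_total - sum(base)
  if (diffr != 0) {
    frac <- raw - floor(raw)
    ord <- order(if (diffr > 0) -frac else frac)
    i <- 1
    while (diffr != 0 && i <= length(ord)) {
      j <- ord[i]
      newv <- base[j] + sign(diffr)
      if (newv >= 0 && newv <= sizes[j]) {
        base[j] <- newv
        diffr <- diffr - sign(diffr)
      }
      i <- i + 1
    }
  }
  train <- integer(0)
  for (s in seq_along(strata)) {
    idx <- strata[[s]]
    if (length(idx) < 2) {
      warning("stratum '", names(strata)[s],
              "' has fewer than 2 samples; assigned wholly to training")
      take <- idx
    } else {
      take <- sample(idx, base[s])
    }
    train <- c(train, take)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling with majority undersampling, using the
#' counting semantics of the classic R implementation: with `perc_over` %
#' oversampling the minority class grows to n_min x (1 + perc_over/100)
#' (each synthetic point a convex combination of a minority point and one
#' of its k minority-class nearest neighbours), and the majority class is
#' downsampled to (perc_under/100) x (n_min x perc_over/100) points,
#' without replacement when possible.
#'
#' @param X sample x feature numeric matrix.
#' @param y binary factor/character labels aligned with rows of `X`.
#' @param perc_over oversampling percentage (default 1000).
#' @param perc_under undersampling percentage (default 300).
#' @param k number of minority nearest neighbours (default 5); reduced
#'   with a warning when the minority class is too small.
#' @param seed integer RNG seed.
#' @return list with balanced `X` and `y`.
#' @export
smoteBalance <- function(X, y, perc_over = 1000, perc_under = 300, k = 5,
                         seed = 1L) {
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2, nrow(X) == length(y))
  set.seed(as.integer(seed))
  counts <- table(y)
  min_lab <- names(counts)[which.min(counts)]
  maj_lab <- names(counts)[which.max(counts)]
  min_idx <- which(y == min_lab)
  maj_idx <- which(y == maj_lab)
  n_min <- length(min_idx)
  if (n_min <= k) {
    k_new <- max(1L, n_min - 1L)
    warning("minority class too small for k = ", k, "; reduced to ", k_new)
    k <- k_new
  }
  n_syn <- round(n_min * perc_over / 100)
  syn <- NULL
  if (n_syn > 0) {
    Xm <- X[min_idx, , drop = FALSE]
    d <- as.matrix(dist(Xm))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    base_pick <- rep_len(seq_len(n_min), n_syn)
    syn <- matrix(NA_real_, n_syn, ncol(X))
    for (s in seq_len(n_syn)) {
      i <- base_pick[s]
      j <- nn[i, sample.int(k, 1)]
      gap <- runif(1)
      syn[s, ] <- Xm[i, ] + gap * (Xm[j, ] - Xm[i, ])
    }
    colnames(syn) <- colnames(X)
    rownames(syn) <- sprintf("synth_%04d", seq_len(n_syn))
  }
  n_maj_keep <- round(perc_under / 100 * n_syn)
  keep_maj <- if (n_maj_keep <= length(maj_idx)) {
    sample(maj_idx, n_maj_keep)
  } else {
    sample(maj_idx, n_maj_keep, replace = TRUE)
  }
  X_out <- rbind(X[min_idx, , drop = FALSE], syn,
                 X[keep_maj, , drop = FALSE])
  y_out <- factor(c(rep(min_lab, n_min + n_syn),
                    rep(maj_lab, length(keep_maj))),
                  levels = levels(y))
  list(X = X_out, y = y_out)
}

#' Feature-specific quantile normalization (FSQN)
#'
#' Harmonizes a target expression matrix onto a reference platform gene by
#' gene: within each gene, target sample values are rank-mapped onto the
#' empirical quantiles of the same gene's reference distribution. Ranks
#' within a gene are preserved exactly; the output per-gene distribution
#' matches the reference up to interpolation.
#'
#' @param target gene x sample matrix to be harmonized.
#' @param reference gene x sample matrix providing per-gene quantiles.
#' @return harmonized matrix with the dimensions of `target`; genes absent
#'   from the reference pass through unchanged with a warning.
#' @export
fsqnHarmonize <- function(target, reference) {
  out <- target
  shared <- intersect(rownames(target), rownames(reference))
  absent <- setdiff(rownames(target), rownames(reference))
  if (length(absent)) {
    warning(length(absent), " gene(s) missing in reference; passed through")
  }
  nt <- ncol(target)
  for (g in shared) {
    ref_sorted <- sort(reference[g, ])
    nr <- length(ref_sorted)
    r <- rank(target[g, ], ties.method = "average")
    probs <- (r - 0.5) / nt
    out[g, ] <- approx(x = (seq_len(nr) - 0.5) / nr, y = ref_sorted,
                       xout = probs, rule = 2)$y
  }
  out
}
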