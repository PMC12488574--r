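#' @importFrom stats rnorm runif quantile approx sd cor lm p.adjust pt pbinom
#'   wilcox.test median lowess predict model.matrix setNames aggregate
#'   complete.cases qlogis plogis dist hclust cutree cor.test var
#' @importFrom utils head read.delim write.table
NULL

STAGE_LEVELS <- c("I", "II", "III", "IV")

#' Largest-remainder integer allocation
#'
#' Distributes `total` units over groups proportionally to `weights`,
#' rounding by the largest-remainder rule so the allocations sum exactly
#' to `total`.
#'
#' @param weights non-negative numeric weights, one per group.
#' @param total integer total to allocate.
#' @return integer vector of allocations summing to `total`.
#' @keywords internal
largestRemainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    return(out)
  }
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# stage label -> ordinal index (I..IV -> 1..4); NA-safe
stageIndex <- function(stage) {
  match(as.character(stage), STAGE_LEVELS)
}

# deterministic per-layer substreams from one user seed
layerSeeds <- function(seed, n = 4L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# clip to open-ish unit interval for logit transforms
clip01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

#' Logit (M-value) transform of methylation beta values
#'
#' @param beta numeric in [0, 1].
#' @param eps clipping bound to avoid infinities.
#' @return log2(beta / (1 - beta)) after clipping.
#' @export
betaToM <- function(beta, eps = 1e-4) {
  b <- clip01(beta, eps)
  log2(b / (1 - b))
}

#' @rdname betaToM
#' @param m M-values.
#' @export
mToBeta <- function(m) {
  2^m / (1 + 2^m)
}

# stratified fold assignment, deterministic under the current RNG state
stratifiedFolds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < k) {
      stop("stratification error: class '", lev, "' has fewer samples (",
           length(idx), ") than folds (", k, ")")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
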