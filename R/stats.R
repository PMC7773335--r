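#' Mean and sample standard deviation
#'
#' @param values numeric vector
#' @return named numeric: `mean` and `sd` (n-1 denominator; `sd` is `NA`
#'   for fewer than two values)
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  c(mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Significance tier stars
#' @param p numeric vector of (adjusted) p values
#' @return character vector: "****" p<0.0001, "***" p<0.001, "**" p<0.01,
#'   "*" p<0.05, "ns" otherwise
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up FDR adjustment: sort ascending, multiply by `n / rank`,
#' enforce monotonicity from the largest p downwards, cap at 1. Returned
#' in the input order.
#'
#' @param pvals numeric vector of p values in \[0, 1\]
#' @return adjusted p values
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  n <- length(pvals)
  if (n <= 1L) return(pvals)
  o <- order(pvals)
  adj <- pvals[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

#' Group-versus-mean testing scheme
#'
#' The two-stage scheme used for per-subset repertoire parameters: an
#' omnibus test across all groups (one-way ANOVA, or Kruskal-Wallis on
#' the nonparametric path), followed, for each group, by a two-sample
#' test of that group's values against the pooled values of all groups
#' (two-sample Welch t-test, or Wilcoxon rank-sum), with Bonferroni
#' correction over the number of groups tested.
#'
#' `parametric = NULL` (default) picks the path with a per-group
#' Shapiro-Wilk normality gate at alpha = 0.05: if any group deviates,
#' the nonparametric path is used. `pooled = "all"` (default) pools every
#' group's values including the tested group, matching the common
#' "versus the base mean of all values" convention; `pooled = "rest"`
#' excludes the tested group, which keeps the two samples independent
#' (see the package vignette for why this matters for calibration).
#'
#' Groups with fewer than 2 values are excluded with a warning.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups)
#' @param parametric TRUE, FALSE, or NULL for the Shapiro-Wilk gate
#' @param pooled `"all"` or `"rest"`
#' @return list with `omnibus` (method, statistic, p) and `per_group`
#'   data.frame (group, n, statistic, p, p_adj, tier); `parametric`
#'   records the path taken
#' @export
group_vs_mean_tests <- function(values_by_group, parametric = NULL,
                                pooled = c("all", "rest")) {
  pooled <- match.arg(pooled)
  g <- values_by_group
  small <- vapply(g, length, 0L) < 2L
  if (any(small)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(g)[small], collapse = ", "))
    g <- g[!small]
  }
  if (length(g) < 2L) stop("need at least 2 groups with n >= 2")
  if (is.null(names(g)) || any(names(g) == ""))
    names(g) <- paste0("group", seq_along(g))

  if (is.null(parametric)) {
    sw <- vapply(g, function(x) {
      if (length(x) < 3L || length(unique(x)) == 1L) return(1)
      stats::shapiro.test(x)$p.value
    }, numeric(1))
    parametric <- all(sw >= 0.05)
  }

  vals <- unlist(g, use.names = FALSE)
  grp <- factor(rep.int(names(g), vapply(g, length, 0L)), levels = names(g))
  omnibus <- if (parametric) {
    ow <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
    data.frame(method = "one-way ANOVA",
               statistic = unname(ow$statistic), p = ow$p.value)
  } else {
    kw <- stats::kruskal.test(vals, grp)
    data.frame(method = "Kruskal-Wallis",
               statistic = unname(kw$statistic), p = kw$p.value)
  }

  k <- length(g)
  per <- do.call(rbind, lapply(names(g), function(nm) {
    x <- g[[nm]]
    y <- if (pooled == "all") vals else unlist(g[names(g) != nm],
                                               use.names = FALSE)
    res <- if (parametric) {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # degenerate constant samples: Welch statistic 0/0; define as no effect
        list(statistic = 0, p.value = 1)
      } else stats::t.test(x, y)
    } else suppressWarnings(stats::wilcox.test(x, y))
    data.frame(group = nm, n = length(x),
               statistic = unname(res$statistic), p = res$p.value,
               stringsAsFactors = FALSE)
  }))
  per$p_adj <- pmin(1, per$p * k)  # Bonferroni over the k group tests
  per$tier <- significance_tier(per$p_adj)
  rownames(per) <- NULL
  list(omnibus = omnibus, per_group = per, parametric = parametric,
       pooled = pooled)
}

#' Principal component analysis of repertoire features
#'
#' Correlation PCA tailored to incommensurate repertoire parameters:
#' columns are z-scored (unless `standardize = FALSE`), constant columns
#' are dropped with a warning, and the standardized matrix is decomposed
#' by [stats::prcomp()]. Component signs follow a deterministic
#' convention: within each component the largest-magnitude loading is
#' made positive.
#'
#' @param features numeric matrix or data.frame, samples x parameters
#'   (>= 3 samples, no missing values)
#' @param standardize z-score columns first? Default TRUE.
#' @return list: `scores` (samples x components), `loadings` (parameters
#'   x components, orthonormal), `explained_variance_ratio` (sums to 1),
#'   `sdev`, `dropped` (names of constant columns removed)
#' @export
pca_features <- function(features, standardize = TRUE) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  if (nrow(x) < 3L) stop("need at least 3 samples")
  if (anyNA(x)) stop("missing values in feature matrix")
  dropped <- character()
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      dropped <- colnames(x)[sds == 0]
      warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
    }
    x <- scale(x)
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2L, flip, "*")
  sco <- sweep(pc$x, 2L, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sco, loadings = rot, explained_variance_ratio = evr,
       sdev = pc$sdev, dropped = dropped)
}
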