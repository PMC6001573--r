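#' Labelled assay matrix
#'
#' Container for a features-by-samples matrix of nonnegative intensities
#' with condition/replicate annotations and an optional 0/1
#' well-above-background flag matrix (1 = well above background).
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   rownames are feature ids, colnames sample labels.
#' @param samples data frame with columns `sample`, `condition`,
#'   `replicate` matching the matrix columns.
#' @param flags optional integer 0/1 matrix of the same shape.
#' @return An object of class `assay_table`.
#' @export
assay_table <- function(values, samples, flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_glia("'values' must be a numeric matrix", "invalid_table")
  if (any(values < 0, na.rm = TRUE))
    stop_glia("assay intensities must be nonnegative", "invalid_table")
  if (!all(c("sample", "condition", "replicate") %in% names(samples)))
    stop_glia("'samples' needs sample, condition, replicate columns",
              "invalid_table")
  if (nrow(samples) != ncol(values))
    stop_glia("sample annotation does not match matrix columns",
              "invalid_table")
  if (any(is.na(samples$sample)) || any(samples$sample == ""))
    stop_glia("missing sample labels", "invalid_table")
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  if (!is.null(flags) && !identical(dim(flags), dim(values)))
    stop_glia("flag matrix shape differs from values", "invalid_table")
  structure(list(values = values, samples = samples, flags = flags),
            class = "assay_table")
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf("assay_table: %d features x %d samples (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", "),
              if (is.null(x$flags)) "" else ", with background flags"))
  invisible(x)
}

#' Remove features flagged too close to background
#'
#' @param table an [assay_table()] with flags (error otherwise).
#' @param policy `"any"` (default: drop a feature flagged below background
#'   in any sample), `"all"` (drop only if flagged in all samples), or
#'   `"majority"` (drop if flagged in more than half the samples).
#' @return The filtered [assay_table()]; dropped ids are recorded in the
#'   `removed_features` attribute.
#' @export
filter_flags <- function(table, policy = c("any", "all", "majority")) {
  stopifnot(inherits(table, "assay_table"))
  policy <- match.arg(policy)
  if (is.null(table$flags))
    stop_glia("flag filtering requires a flag matrix (policy needs flags)",
              "flags_missing")
  bad <- table$flags == 0L
  drop <- switch(policy,
                 any = rowSums(bad) > 0L,
                 all = rowSums(bad) == ncol(bad),
                 majority = rowSums(bad) > ncol(bad) / 2)
  out <- assay_table(table$values[!drop, , drop = FALSE], table$samples,
                     flags = table$flags[!drop, , drop = FALSE])
  attr(out, "removed_features") <- rownames(table$values)[drop]
  out
}

#' Upper-quartile (75th percentile) normalisation
#'
#' Each sample is rescaled so its 75th percentile (linear interpolation
#' between order statistics) equals the geometric mean of all samples'
#' pre-scaling 75th percentiles. Idempotent, and scale-invariant per
#' sample.
#'
#' @param table an [assay_table()].
#' @return The normalised [assay_table()]; the per-sample scale factors
#'   are recorded in the `scale_factors` attribute.
#' @export
normalize_75th <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  v <- table$values
  if (any(colSums(v > 0, na.rm = TRUE) < 4L))
    stop_glia("every sample needs at least 4 positive values",
              "invalid_table")
  q75 <- apply(v, 2, quantile, probs = 0.75, na.rm = TRUE, type = 7,
               names = FALSE)
  if (any(q75 <= 0))
    stop_glia("a sample has a nonpositive 75th percentile", "invalid_table")
  target <- exp(mean(log(q75)))
  sf <- target / q75
  out <- assay_table(sweep(v, 2, sf, "*"), table$samples,
                     flags = table$flags)
  attr(out, "scale_factors") <- sf
  out
}

#' Select differentially expressed features by fold change and moderated t
#'
#' Per-feature log2 fold change between two condition groups combined with
#' a moderated two-sample t statistic: each feature's pooled variance is
#' shrunk toward the mean feature variance with fixed weight
#' `shrinkage` (0 = ordinary t test; p values are calibrated at 0).
#' A feature is selected iff `p < p_threshold` and
#' `|log2FC| > fc_threshold_log2`.
#'
#' @param table an [assay_table()] of positive intensities (log taken
#'   internally).
#' @param group_a,group_b condition labels; log2FC is a - b.
#' @param p_threshold,fc_threshold_log2 selection gates.
#' @param shrinkage prior weight on the mean feature variance, in \[0, 1\].
#' @return A `deg_result` data frame: `feature`, `log2_fc`, `p_value`,
#'   `selected`.
#' @export
select_degs <- function(table, group_a, group_b, p_threshold = 0.05,
                        fc_threshold_log2 = 1, shrinkage = 0.5) {
  stopifnot(inherits(table, "assay_table"))
  check_number(shrinkage, "shrinkage", min = 0, max = 1)
  ia <- which(table$samples$condition == group_a)
  ib <- which(table$samples$condition == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop_glia("need at least 2 replicates per group", "invalid_design")
  v <- table$values
  if (any(v <= 0))
    stop_glia("nonpositive intensities cannot be log-transformed",
              "invalid_table")
  la <- log2(v[, ia, drop = FALSE]); lb <- log2(v[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  s2_mod <- (1 - shrinkage) * s2 + shrinkage * mean(s2)
  lfc <- ma - mb
  tstat <- lfc / sqrt(s2_mod * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df = na + nb - 2)
  out <- data.frame(feature = rownames(v), log2_fc = lfc, p_value = p,
                    selected = p < p_threshold &
                      abs(lfc) > fc_threshold_log2,
                    row.names = NULL)
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Principal component analysis of assay samples
#'
#' Samples are the observations, features the variables (centred across
#' samples; optionally unit-scaled). The proportion of variance (POV) is
#' reported for every component and sums to 1; each component's sign is
#' fixed so its largest-magnitude feature loading is positive.
#'
#' @param table an [assay_table()] with >= 3 samples.
#' @param scale. unit-scale features (correlation PCA); default FALSE
#'   (covariance PCA).
#' @param log2 log2-transform intensities first.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `pov`, `loadings` and `sdev`.
#' @export
pca_conditions <- function(table, scale. = FALSE, log2 = FALSE) {
  stopifnot(inherits(table, "assay_table"))
  x <- t(table$values)
  if (log2) {
    if (any(x <= 0)) stop_glia("nonpositive intensities under log2",
                               "invalid_table")
    x <- base::log2(x)
  }
  if (nrow(x) < 3L)
    stop_glia("PCA needs at least 3 samples", "invalid_design")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (scale.) {
    sds <- apply(x, 2, sd)
    x[, sds > 0] <- sweep(x[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
    x <- x[, sds > 0, drop = FALSE]
  }
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos))
    stop_glia("matrix has rank 0 after centring", "invalid_table")
  d <- sv$d[pos]
  u <- sv$u[, pos, drop = FALSE]
  vv <- sv$v[, pos, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (k in seq_along(d)) {
    j <- which.max(abs(vv[, k]))
    if (vv[j, k] < 0) { vv[, k] <- -vv[, k]; u[, k] <- -u[, k] }
  }
  scores <- u %*% diag(d, nrow = length(d))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_along(d))
  structure(list(scores = scores, pov = d^2 / sum(d^2), loadings = vv,
                 sdev = d / sqrt(nrow(x) - 1)),
            class = "pca_result")
}

#' Group-comparison tests
#'
#' The statistics used across the pipeline: unpaired or paired t test,
#' one-way ANOVA with post-hoc Bonferroni-corrected pairwise t tests
#' (pairwise p multiplied by the number of comparisons and capped at 1),
#' and the two-sample Kolmogorov-Smirnov test.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param design `"unpaired"`, `"paired"`, `"anova_bonferroni"` or `"ks"`.
#' @return A list with `statistic`, `p_value`, per-group `means`, `sds`
#'   and `n`, a `degenerate` flag (TRUE when a paired test has
#'   zero-variance differences, in which case statistic and p are NA) and,
#'   for the ANOVA design, a `pairwise` data frame of Bonferroni-corrected
#'   comparisons.
#' @export
compare_groups <- function(values_by_group,
                           design = c("unpaired", "paired",
                                      "anova_bonferroni", "ks")) {
  design <- match.arg(design)
  g <- values_by_group
  if (!is.list(g) || length(g) < 2L)
    stop_glia("need at least two groups", "invalid_design")
  if (is.null(names(g))) names(g) <- paste0("group", seq_along(g))
  if (any(vapply(g, length, integer(1)) < 2L))
    stop_glia("need at least 2 observations per group", "invalid_design")
  base <- list(means = vapply(g, mean, numeric(1)),
               sds = vapply(g, sd, numeric(1)),
               n = vapply(g, length, integer(1)),
               degenerate = FALSE, pairwise = NULL)
  if (design %in% c("unpaired", "paired", "ks") && length(g) != 2L)
    stop_glia(sprintf("design '%s' needs exactly two groups", design),
              "invalid_design")
  if (design == "paired" && length(g[[1]]) != length(g[[2]]))
    stop_glia("paired design needs equal group lengths", "invalid_design")
  res <- switch(design,
    unpaired = {
      if (var(g[[1]]) + var(g[[2]]) == 0) {
        if (mean(g[[1]]) == mean(g[[2]]))
          list(statistic = 0, p_value = 1)
        else list(statistic = NA_real_, p_value = NA_real_,
                  degenerate = TRUE)
      } else {
        tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
        list(statistic = unname(tt$statistic), p_value = tt$p.value)
      }
    },
    paired = {
      dif <- g[[1]] - g[[2]]
      if (var(dif) == 0)
        list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE)
      else {
        tt <- t.test(g[[1]], g[[2]], paired = TRUE)
        list(statistic = unname(tt$statistic), p_value = tt$p.value)
      }
    },
    ks = {
      kt <- suppressWarnings(ks.test(g[[1]], g[[2]]))
      list(statistic = unname(kt$statistic), p_value = kt$p.value)
    },
    anova_bonferroni = {
      dat <- data.frame(
        y = unlist(g, use.names = FALSE),
        grp = factor(rep(names(g), vapply(g, length, integer(1)))))
      fit <- aov(y ~ grp, data = dat)
      ss <- summary(fit)[[1]]
      pairs <- utils::combn(names(g), 2)
      m <- ncol(pairs)
      pw <- do.call(rbind, lapply(seq_len(m), function(q) {
        a <- pairs[1, q]; b <- pairs[2, q]
        tt <- t.test(g[[a]], g[[b]], var.equal = TRUE)
        data.frame(group_a = a, group_b = b,
                   p_raw = tt$p.value,
                   p_bonferroni = min(1, tt$p.value * m))
      }))
      list(statistic = ss[["F value"]][1], p_value = ss[["Pr(>F)"]][1],
            pairwise = pw)
    })
  utils::modifyList(base, res)
}
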