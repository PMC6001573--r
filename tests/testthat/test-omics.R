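make_table <- function(values, conditions, flags = NULL) {
  samples <- data.frame(sample = paste0("s", seq_len(ncol(values))),
                        condition = conditions,
                        replicate = stats::ave(seq_along(conditions),
                                               conditions, FUN = seq_along))
  colnames(values) <- samples$sample
  assay_table(values, samples, flags = flags)
}

test_that("flag filtering applies its policy and errors without flags", {
  set.seed(1)
  v <- matrix(rlnorm(40, 4), 10, 4)
  fl <- matrix(1L, 10, 4)
  fl[3, 2] <- 0L                 # one feature flagged in one sample
  fl[7, ] <- 0L                  # one feature flagged everywhere
  tb <- make_table(v, c("a", "a", "b", "b"), flags = fl)
  expect_equal(nrow(filter_flags(tb)$values), 8L)            # any
  expect_equal(nrow(filter_flags(tb, "all")$values), 9L)     # all
  expect_equal(nrow(filter_flags(tb, "majority")$values), 9L)
  expect_setequal(attr(filter_flags(tb), "removed_features"),
                  rownames(tb$values)[c(3, 7)])
  tb_noflags <- make_table(v, c("a", "a", "b", "b"))
  expect_error(filter_flags(tb_noflags), class = "flags_missing")
  # unflagged table passes through unchanged
  tb_clean <- make_table(v, c("a", "a", "b", "b"),
                         flags = matrix(1L, 10, 4))
  expect_equal(filter_flags(tb_clean)$values, tb_clean$values)
  # generator flags match a brute-force recount
  g <- generate_assay_matrix(assay_spec(n_features = 200,
                                        flag_fraction = 0.2, seed = 2),
                             flavor = "expression")
  expect_equal(nrow(filter_flags(g)$values),
               sum(rowSums(g$flags == 0L) == 0L))
})

test_that("75th-percentile normalisation aligns, is idempotent and guarded", {
  set.seed(3)
  v <- matrix(rlnorm(600, 4, 1), 150, 4)
  tb <- make_table(v, c("a", "a", "b", "b"))
  nt <- normalize_75th(tb)
  q <- apply(nt$values, 2, quantile, probs = 0.75, type = 7, names = FALSE)
  expect_lt(diff(range(q)), 1e-9)
  # idempotence
  nt2 <- normalize_75th(nt)
  expect_lt(max(abs(nt2$values - nt$values)), 1e-9)
  # identical samples are unchanged
  same <- make_table(cbind(v[, 1], v[, 1], v[, 1], v[, 1]),
                     c("a", "a", "b", "b"))
  expect_equal(normalize_75th(same)$values, same$values, tolerance = 1e-12)
  # a doubled sample is pulled back onto the others
  dbl <- make_table(cbind(v[, 1], 2 * v[, 1]), c("a", "b"))
  expect_error(dbl2 <- normalize_75th(dbl), NA)
  expect_equal(dbl2$values[, 1], unname(dbl2$values[, 2]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # too few positive values
  vv <- v[1:5, ]; vv[2:5, 1] <- 0
  expect_error(normalize_75th(make_table(vv, c("a", "a", "b", "b"))),
               class = "invalid_table")
})

test_that("DEG selection applies the fold-change and p gates", {
  set.seed(4)
  n <- 200
  base <- rlnorm(n, 5, 0.5)
  noise <- function() matrix(rlnorm(n * 3, 0, 0.07), n, 3)
  va <- base * noise(); vb <- base * noise()
  # plant a 4-fold and a 1.5-fold feature
  va[1, ] <- va[1, ] * 4
  va[2, ] <- va[2, ] * 1.5
  tb <- make_table(cbind(va, vb), rep(c("a", "b"), each = 3))
  dg <- select_degs(tb, "a", "b")
  expect_true(dg$selected[1])                     # |log2FC| = 2 > 1
  expect_false(dg$selected[2])                    # |log2FC| ~ 0.585 < 1
  # the fold gate dominates: nothing inside the gate is ever selected
  expect_false(any(dg$selected[abs(dg$log2_fc) <= 1]))
  # identical groups: all zero fold changes, nothing selected
  same <- make_table(cbind(va, va), rep(c("a", "b"), each = 3))
  dg0 <- select_degs(same, "a", "b")
  expect_equal(dg0$log2_fc, rep(0, n))
  expect_false(any(dg0$selected))
  # replicate guard
  one <- make_table(cbind(va[, 1, drop = FALSE], vb), c("a", rep("b", 3)))
  expect_error(select_degs(one, "a", "b"), class = "invalid_design")
})

test_that("type-I rate is calibrated at shrinkage 0 (scaled null)", {
  # 5 seeds x 1000 features here; the acceptance suite runs 20 x 2000
  ps <- unlist(lapply(1:5, function(s) {
    tb <- generate_assay_matrix(assay_spec(
      n_features = 1000, conditions = list(a = 1, b = 1), n_replicates = 3,
      noise_cv = 0.2, seed = s))
    select_degs(tb, "a", "b", shrinkage = 0)$p_value
  }))
  rate <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("PCA identities: duplicates, POV, eigen oracle, rank guard", {
  set.seed(5)
  v <- matrix(rlnorm(24, 4), 6, 4)
  v[, 2] <- v[, 1]               # duplicated condition profile
  tb <- make_table(v, c("a", "a", "b", "b"))
  pc <- pca_conditions(tb)
  expect_lt(max(abs(pc$scores[1, ] - pc$scores[2, ])), 1e-9)
  expect_equal(sum(pc$pov), 1)
  expect_true(all(diff(pc$pov) <= 1e-12))
  # 6x4: scores match an independent covariance eigen-solve up to sign
  v2 <- matrix(rlnorm(24, 3, 0.8), 6, 4)
  tb2 <- make_table(v2, c("a", "a", "b", "b"))
  pc2 <- pca_conditions(tb2)
  x <- scale(t(v2), center = TRUE, scale = FALSE)
  eig <- eigen(cov(x))
  or_scores <- x %*% eig$vectors
  for (k in 1:2) {
    s <- sign(sum(or_scores[, k] * pc2$scores[, k]))
    expect_equal(unname(pc2$scores[, k]), s * unname(or_scores[, k]),
                 tolerance = 1e-8)
  }
  expect_equal(pc2$pov[1:2],
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-8)
  # rank-0 matrix errors
  flat <- make_table(matrix(5, 4, 4), c("a", "a", "b", "b"))
  expect_error(pca_conditions(flat), class = "invalid_table")
  expect_error(pca_conditions(make_table(v[, 1:2], c("a", "b"))),
               class = "invalid_design")
})

test_that("PC1 separates amyloid from amyloid+NGF more than from control", {
  # qualitative anti-inflammatory structure; 10 seeds (scaled from 20)
  wins <- vapply(1:10, function(s) {
    tb <- generate_assay_matrix(cytokine_panel_spec(seed = s))
    pc <- pca_conditions(tb)
    cm <- function(cond) colMeans(pc$scores[tb$samples$condition == cond,
                                            1, drop = FALSE])
    abs(cm("abeta") - cm("abeta_ngf")) > abs(cm("ctrl") - cm("abeta_ngf"))
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("group-comparison tests cover the four designs", {
  # identical groups, unpaired: t = 0, p = 1
  cg <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)), "unpaired")
  expect_equal(cg$statistic, 0)
  expect_equal(cg$p_value, 1)
  # paired constant shift: degenerate-variance flag
  cp <- compare_groups(list(a = c(1, 2, 3), b = c(2, 3, 4)), "paired")
  expect_true(cp$degenerate)
  expect_true(is.na(cp$p_value))
  # paired with variance works
  set.seed(6)
  x <- rnorm(10); y <- x + rnorm(10, 1, 0.5)
  cp2 <- compare_groups(list(a = x, b = y), "paired")
  expect_equal(cp2$p_value, t.test(x, y, paired = TRUE)$p.value)
  # ANOVA p agrees with a direct F-distribution oracle
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  av <- compare_groups(g, "anova_bonferroni")
  grand <- mean(unlist(g))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(av$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(av$p_value, pf(f_oracle, 2, 15, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_true(all(av$pairwise$p_bonferroni <= 1))
  expect_equal(av$pairwise$p_bonferroni,
               pmin(1, av$pairwise$p_raw * 3))
  # KS design runs and agrees with stats::ks.test
  kk <- compare_groups(list(a = x, b = y), "ks")
  expect_equal(kk$p_value, suppressWarnings(ks.test(x, y))$p.value)
  # design/data mismatches error
  expect_error(compare_groups(list(a = 1:3, b = 1:4), "paired"),
               class = "invalid_design")
  expect_error(compare_groups(list(a = 1:3, b = 1:3, c = 1:3), "unpaired"),
               class = "invalid_design")
  expect_error(compare_groups(list(a = 1:3), "unpaired"),
               class = "invalid_design")
})
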