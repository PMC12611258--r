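test_that("pairing joins on gene id and excludes NA fold changes", {
  x <- de_table(c("a", "b", "c", "x_only"), 10, c(1, 2, 3, 4),
                padj = 0.01, analysis_label = "X")
  y <- de_table(c("a", "b", "c", "y_only"), 10, c(1, NA, 3, 4),
                padj = 0.01, analysis_label = "Y")
  pairs <- pair_tables(x, y)
  expect_setequal(pairs$gene_id, c("a", "b", "c"))  # join semantics
  expect_equal(pairs$category[pairs$gene_id == "b"], "excluded_na")
  classified <- classify_points(pairs)
  expect_equal(as.character(classified$category[classified$gene_id == "b"]),
               "excluded_na")
  # identical tables pair each gene with itself
  self <- pair_tables(x, x)
  expect_equal(self$x_l2fc, self$y_l2fc)
  # excluded_na genes contribute to no statistic
  expect_equal(attr(sign_concordance(list(x, y)), "n"), 2)
})

test_that("point classification follows the category precedence table", {
  spec <- data.frame(
    x_l2fc = c(2,   0.5, 3,   0.5, 0.2, -0.3, 1.5, -2,  1,  0.99),
    y_l2fc = c(-1.5, 0.3, 0.2, 0.3, 3,  -0.2, 2.5, -3, -1,  0.99),
    x_padj = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.5, 0.01, 0.5, 0.01, 0.01),
    y_padj = c(0.01, 0.01, 0.5,  0.5,  0.01, 0.5, 0.01, 0.01, 0.01, 0.01))
  ft <- paired_fixture(spec)
  pairs <- classify_points(pair_tables(ft$x, ft$y))
  expect_equal(as.character(pairs$category),
               c("shared_strong",     # sig both, strong
                 "shared_weak",       # sig both, both |l2fc| < 1
                 "x_only_weak",       # sig X, |y| < 1, |x| >= 1
                 "either_weak_both",  # sig X only but both weak
                 "y_only_weak",       # sig Y, |x| < 1 -> weak split on x
                 "not_de",            # sig neither
                 "shared_strong",
                 "y_only_strong",     # sig Y, |x| = 2 >= 1
                 "shared_strong",     # boundary |l2fc| = 1 counts as strong
                 "shared_weak"))
  counts <- table(pairs$category)
  expect_equal(sum(counts), nrow(spec))  # categories partition the join
  # stable under row reordering
  perm <- sample(nrow(spec))
  ft2 <- paired_fixture(spec[perm, ])
  pairs2 <- classify_points(pair_tables(ft2$x, ft2$y))
  expect_equal(unname(table(pairs2$category)), unname(counts))
})

test_that("Pearson subsets reproduce the closed-form sums", {
  spec <- data.frame(x_l2fc = c(0, 1, 2, 3), y_l2fc = c(0, 2, 3, 5),
                     x_padj = 0.01, y_padj = 0.01)
  ft <- paired_fixture(spec)
  pairs <- pair_tables(ft$x, ft$y)
  x <- spec$x_l2fc; y <- spec$y_l2fc; n <- 4
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pearson_subset(pairs, "shared"), r_oracle)
  expect_equal(pearson_subset(pairs, "union"), r_oracle)
  # perfect lines
  line <- paired_fixture(data.frame(x_l2fc = 1:5, y_l2fc = 1:5,
                                    x_padj = 0.01, y_padj = 0.01))
  expect_equal(pearson_subset(pair_tables(line$x, line$y), "shared"), 1.0)
  anti <- paired_fixture(data.frame(x_l2fc = 1:5, y_l2fc = -(1:5),
                                    x_padj = 0.01, y_padj = 0.01))
  expect_equal(pearson_subset(pair_tables(anti$x, anti$y), "shared"), -1.0)
  # degenerate variance flagged
  flat <- paired_fixture(data.frame(x_l2fc = c(1, 1, 1), y_l2fc = 1:3,
                                    x_padj = 0.01, y_padj = 0.01))
  r <- pearson_subset(pair_tables(flat$x, flat$y), "shared")
  expect_true(is.na(r) && attr(r, "undefined"))
})

test_that("OLS fit matches the normal equations and the r^2 identity", {
  spec <- data.frame(x_l2fc = c(0, 1, 2, 3), y_l2fc = c(0, 2, 3, 5),
                     x_padj = 0.01, y_padj = 0.01)
  ft <- paired_fixture(spec)
  pairs <- pair_tables(ft$x, ft$y)
  fit <- ols_fit(pairs, "shared")
  x <- spec$x_l2fc; y <- spec$y_l2fc
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope_oracle)
  expect_equal(fit$intercept, mean(y) - slope_oracle * mean(x))
  expect_equal(fit$r_squared, pearson_subset(pairs, "shared")^2)
  exact <- paired_fixture(data.frame(x_l2fc = 1:6, y_l2fc = 2 * (1:6) + 1,
                                     x_padj = 0.01, y_padj = 0.01))
  efit <- ols_fit(pair_tables(exact$x, exact$y), "shared")
  expect_equal(efit$slope, 2)
  expect_equal(efit$intercept, 1)
  expect_equal(efit$r_squared, 1)
})

test_that("removing extreme fold changes restores a slope near one", {
  set.seed(77)
  n <- 50
  x <- rnorm(n, 0, 3)
  spec <- data.frame(x_l2fc = c(x, rep(-28, 5)),
                     y_l2fc = c(x + rnorm(n, 0, 0.2), rep(-5, 5)),
                     x_padj = 0.01, y_padj = 0.01)
  ft <- paired_fixture(spec)
  pairs <- pair_tables(ft$x, ft$y)
  sens <- outlier_sensitivity(pairs, "shared", extreme_thresh = 20)
  expect_length(sens$removed, 5)
  expect_lt(abs(sens$fit_trimmed$slope - 1), abs(sens$fit_all$slope - 1))
  expect_equal(abs(sens$fit_trimmed$slope - 1), 0, tolerance = 0.05)
  # no extreme points, or an infinite threshold: both fits identical
  clean <- outlier_sensitivity(pairs, "shared", extreme_thresh = Inf)
  expect_equal(clean$fit_all, clean$fit_trimmed)
  expect_length(clean$removed, 0)
})

test_that("swapping tables transposes categories and preserves correlations", {
  cfg <- regime_config("constrained", n_tfs = 2, universe_size = 800,
                       deg_count = 150, core_size = 200, rho = 0.7,
                       n_unexpressed = 50, na_rate = 0.02, seed = 19)
  tabs <- gen_de_tables(cfg)
  xy <- classify_points(pair_tables(tabs[[1]], tabs[[2]]))
  yx <- classify_points(pair_tables(tabs[[2]], tabs[[1]]))
  cx <- table(xy$category); cy <- table(yx$category)
  expect_equal(cx[["x_only_weak"]], cy[["y_only_weak"]])
  expect_equal(cx[["y_only_strong"]], cy[["x_only_strong"]])
  expect_equal(cx[["shared_strong"]], cy[["shared_strong"]])
  expect_equal(pearson_subset(xy, "shared"), pearson_subset(yx, "shared"))
  expect_equal(pearson_subset(xy, "union"), pearson_subset(yx, "union"))
  fxy <- ols_fit(xy, "shared"); fyx <- ols_fit(yx, "shared")
  r2 <- pearson_subset(xy, "shared")^2
  expect_equal(fxy$slope * fyx$slope, r2)  # slope_yx * slope_xy = r^2
  expect_equal(discordant_count(xy), discordant_count(yx))
})

test_that("sign concordance counts strictly same-signed fold-change vectors", {
  t1 <- tiny_table(c("a", "b", "c"), log2fc = c(1, -2, 3), padj = 0.01)
  expect_equal(as.numeric(sign_concordance(list(t1, t1, t1))), 1.0)
  t2 <- tiny_table(c("a", "b", "c"), log2fc = c(2, -1, -0.1), padj = 0.01)
  t3 <- tiny_table(c("a", "b", "c"), log2fc = c(1, -3, 3), padj = 0.01)
  # gene c: signs (3, -0.1, 3) discordant; a concordant; b concordant
  expect_equal(as.numeric(sign_concordance(list(t1, t2, t3))), 2 / 3)
  zero <- tiny_table("a", log2fc = 0, padj = 0.01)
  expect_equal(as.numeric(sign_concordance(list(zero, zero))), 0)  # 0 breaks it
  none <- tiny_table("a", log2fc = 1, padj = 0.5)
  out <- sign_concordance(list(none, none))
  expect_true(is.na(out) && attr(out, "undefined"))
})

test_that("independent signs give concordance near 2^(1-k)", {
  cfg <- regime_config("constrained", n_tfs = 4, universe_size = 6000,
                       deg_count = 3000, core_size = 3000, rho = 1,
                       sigma_g = 0, sigma_e = 1, n_unexpressed = 0, seed = 5)
  tabs <- gen_de_tables(cfg)
  conc <- sign_concordance(tabs)
  expect_equal(attr(conc, "n"), 3000)
  expect_equal(as.numeric(conc), 2^(1 - 4), tolerance = 0.25)
})

test_that("nestedness is the contained fraction of the inner set", {
  inner <- gene_set(letters[1:10], "in", "deg")
  outer <- gene_set(letters[3:26], "out", "deg")
  expect_equal(nestedness_fraction(inner, outer), 0.8)
  expect_equal(nestedness_fraction(letters[1:5], letters), 1.0)
  expect_equal(nestedness_fraction(c("q"), c("z")), 0.0)
  expect_equal(nestedness_fraction(c("a", "b", "c", "d", "e", "f", "g", "h",
                                     "i", "j"), letters[6:15]), 0.5)
  empty <- nestedness_fraction(character(), letters)
  expect_true(is.na(empty) && attr(empty, "undefined"))
})

test_that("discordant counts cover only oppositely signed shared genes", {
  spec <- data.frame(x_l2fc = c(1, 2, -1, 3, -2, 0.5),
                     y_l2fc = c(2, -1, 1, 4, -3, 0.7),
                     x_padj = 0.01, y_padj = 0.01)
  ft <- paired_fixture(spec)
  pairs <- classify_points(pair_tables(ft$x, ft$y))
  expect_equal(discordant_count(pairs), 2)
  same <- paired_fixture(data.frame(x_l2fc = 1:4, y_l2fc = 2:5,
                                    x_padj = 0.01, y_padj = 0.01))
  expect_equal(discordant_count(classify_points(pair_tables(same$x, same$y))), 0)
  nosig <- paired_fixture(data.frame(x_l2fc = c(1, -1, 2), y_l2fc = c(-1, 1, 2),
                                     x_padj = 0.5, y_padj = 0.5))
  expect_equal(discordant_count(classify_points(pair_tables(nosig$x, nosig$y))), 0)
})

test_that("averaged fold changes omit genes missing anywhere", {
  t1 <- tiny_table(c("a", "b", "c"), log2fc = c(1, 4, NA))
  t2 <- tiny_table(c("a", "b", "d"), log2fc = c(2, 6, 1))
  t3 <- tiny_table(c("a", "b", "c"), log2fc = c(3, 2, 1))
  t4 <- tiny_table(c("a", "b", "c"), log2fc = c(6, 0, 1))
  avg <- average_l2fc(list(t1, t2, t3, t4))
  expect_equal(avg[["a"]], 3.0)  # mean(1, 2, 3, 6)
  expect_equal(avg[["b"]], 3.0)
  expect_false("c" %in% names(avg))  # NA in t1
  expect_false("d" %in% names(avg))  # absent from t1
  expect_equal(average_l2fc(list(t3, t3))[["a"]], 3)
})

test_that("shared-subset correlation recovers the generator's target", {
  cfg <- regime_config("constrained", n_tfs = 2, universe_size = 10000,
                       deg_count = 2500, core_size = 2500, rho = 1,
                       sigma_g = 1, sigma_e = 0.5, n_unexpressed = 0, seed = 101)
  tabs <- gen_de_tables(cfg)
  pairs <- pair_tables(tabs[[1]], tabs[[2]])
  target <- 1 / (1 + 0.5^2)
  expect_equal(pearson_subset(pairs, "shared"), target, tolerance = 0.07)
})
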