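test_that("retinal means average the images of each retina", {
  per_image <- data.frame(
    image_id = paste0("i", 1:6),
    retina_id = rep(c("r1", "r2", "r3"), each = 2),
    genotype = rep(c("wt", "wt", "mut"), each = 2),
    value = c(2, 4, 1, 5, 10, 20))
  tab <- retina_means(per_image)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$value[match(c("r1", "r2", "r3"), tab$retina_id)],
               c(3, 3, 15))
  # single-image retina passes through unchanged
  one <- retina_means(per_image[1, , drop = FALSE])
  expect_equal(one$value, 2)
  # conflicting genotype labels within a retina are rejected
  bad <- per_image
  bad$genotype[2] <- "mut"
  expect_error(retina_means(bad), "conflicting genotype")
})

test_that("one-way ANOVA and Tukey HSD match independent computation", {
  # fixture with hand-computable sums of squares (3 groups, n = 5)
  tab <- data.frame(
    retina_id = paste0("r", 1:15),
    genotype = rep(c("a", "b", "c"), each = 5),
    metric = "m",
    value = c(51, 87, 50, 48, 79, 82, 91, 97, 98, 90, 79, 84, 74, 98, 63))
  res <- anova_tukey(tab)
  expect_equal(res$anova$statistic,
               brute_anova_F(tab$value, tab$genotype), tolerance = 1e-6)
  expect_equal(nrow(res$tukey), 3)
  expect_true(all(res$tukey$p_adjusted >= 0 & res$tukey$p_adjusted <= 1))

  # equal group means but within-group spread -> F = 0, p = 1
  same <- tab
  same$value <- rep(c(1, 2, 3, 4, 5), 3)
  res0 <- anova_tukey(same)
  expect_equal(res0$anova$statistic, 0)
  expect_equal(res0$anova$p_raw, 1)

  expect_error(anova_tukey(tab[c(1:5, 6), ]), "degenerate")
})

test_that("two-group ANOVA is algebraically the pooled t-test", {
  tab <- data.frame(retina_id = paste0("r", 1:11),
                    genotype = rep(c("wt", "mut"), c(5, 6)),
                    metric = "m",
                    value = c(5.1, 4.8, 5.5, 5.0, 4.6,
                              6.2, 5.9, 6.8, 6.1, 5.7, 6.4))
  a <- anova_tukey(tab)$anova
  t <- t_test_groups(tab)
  expect_equal(a$p_raw, t$p_raw, tolerance = 1e-12)
  expect_equal(a$statistic, t$statistic^2, tolerance = 1e-12)
})

test_that("Student's t-test behaves under label swap and identical groups", {
  tab <- data.frame(retina_id = paste0("r", 1:8),
                    genotype = rep(c("a", "b"), each = 4),
                    metric = "m",
                    value = c(1, 2, 3, 4, 1, 2, 3, 4))
  res <- t_test_groups(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)

  tab2 <- data.frame(retina_id = paste0("r", 1:8),
                     genotype = rep(c("a", "b"), each = 4),
                     metric = "m",
                     value = c(1, 2, 3, 4, 5, 6, 7, 8))
  swapped <- tab2
  swapped$genotype <- rep(c("b", "a"), each = 4)
  r1 <- t_test_groups(tab2)
  r2 <- t_test_groups(swapped)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_raw, r2$p_raw)

  # hand-computed: pooled t for these groups
  v1 <- c(1, 2, 3, 4); v2 <- c(5, 6, 7, 8)
  sp2 <- (3 * var(v1) + 3 * var(v2)) / 6
  t_hand <- (mean(v1) - mean(v2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r1$statistic, t_hand)

  expect_error(t_test_groups(rbind(tab2,
    data.frame(retina_id = "r9", genotype = "c", metric = "m", value = 1))),
    "exactly 2")
})

test_that("two-way ANOVA partitions variance over genotype x level", {
  set.seed(19)
  layout <- expand.grid(retina = paste0("r", 1:6),
                        genotype = c("wt", "mut"),
                        level = c("low", "mid", "high"))
  layout$value <- rnorm(nrow(layout)) +
    ifelse(layout$genotype == "mut", 2, 0) +
    as.numeric(layout$level)
  res <- two_way_anova(layout)
  expect_setequal(res$term, c("genotype", "level", "genotype:level",
                              "Residuals"))
  # balanced design: sums of squares add up to the total
  total_ss <- sum((layout$value - mean(layout$value))^2)
  expect_equal(sum(res$sum_sq), total_ss, tolerance = 1e-10)
  expect_lt(res$p_raw[res$term == "genotype"], 1e-4)

  expect_error(two_way_anova(layout[layout$level != "low" |
                                      layout$genotype != "wt", ]),
               "incomplete")
})

test_that("a strong genotype shift is detected at realistic group sizes", {
  # 7 retinas per genotype, 3 threshold levels, shift ~3 SD
  set.seed(23)
  layout <- expand.grid(retina = paste0("r", 1:7),
                        genotype = c("ctrl", "mutant"),
                        level = c("t1", "t2", "t3"))
  layout$value <- rnorm(nrow(layout), sd = 1) +
    ifelse(layout$genotype == "mutant", 3, 0) +
    2 * as.numeric(layout$level)
  res <- two_way_anova(layout)
  expect_lt(res$p_raw[res$term == "genotype"], 1e-4)
})

test_that("BH adjustment matches the direct step-up construction", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  set.seed(29)
  for (k in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # monotone in the input order statistics
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
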