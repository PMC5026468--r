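test_that("expected score follows the base-10 logistic and sums to 1", {
  expect_equal(expected_score(0, 0), 0.5)
  expect_equal(expected_score(400, 0, scale = 400), 10 / 11)
  set.seed(1)
  ra <- rnorm(50, 0, 300); rb <- rnorm(50, 0, 300)
  expect_equal(expected_score(ra, rb) + expected_score(rb, ra),
               rep(1, 50))
})

test_that("matchup updates are zero-sum with larger exchanges for upsets", {
  cfg <- elo_config(k_factor = 32)
  st <- elo_init(c("A", "B"), cfg)
  expect_true(all(st$ratings == 0))  # every image starts at 0
  st2 <- apply_matchup(st, list(image_a = "A", image_b = "B", winner = "A",
                                rater = "u"), cfg)
  expect_equal(unname(st2$ratings), c(16, -16))  # E = 0.5 -> k/2
  expect_equal(sum(st2$ratings), 0)

  # upset: low-rated beats high-rated -> delta > k/2; reverse -> < k/2
  st3 <- st; st3$ratings <- c(A = 200, B = -200)
  upset <- apply_matchup(st3, list(image_a = "A", image_b = "B",
                                   winner = "B", rater = "u"), cfg)
  favored <- apply_matchup(st3, list(image_a = "A", image_b = "B",
                                     winner = "A", rater = "u"), cfg)
  d_upset <- upset$history[[1]]$delta
  d_favored <- favored$history[[1]]$delta
  expect_gt(d_upset, 16)
  expect_lt(d_favored, 16)
  expect_equal(d_upset + d_favored, 32)  # complementary expected scores

  expect_error(apply_matchup(st, list(image_a = "A", image_b = "Z",
                                      winner = "A", rater = "u"), cfg),
               "unknown image")
})

test_that("total rating is conserved across random matchup sequences", {
  cfg <- elo_config()
  ids <- paste0("i", 1:12)
  st <- elo_init(ids, cfg)
  set.seed(5)
  for (k in 1:300) {
    pair <- sample(ids, 2)
    st <- apply_matchup(st, list(image_a = pair[1], image_b = pair[2],
                                 winner = sample(pair, 1), rater = "u"),
                        cfg)
    expect_lt(abs(sum(st$ratings)), 1e-9)
  }
  expect_equal(length(st$history), 300)
})

test_that("a dominant image rises monotonically with bounded steps", {
  cfg <- elo_config(k_factor = 32)
  st <- elo_init(c("good", "bad"), cfg)
  trace <- numeric(50)
  for (k in 1:50) {
    st <- apply_matchup(st, list(image_a = "good", image_b = "bad",
                                 winner = "good", rater = "u"), cfg)
    trace[k] <- st$ratings[["good"]]
  }
  steps <- diff(c(0, trace))
  expect_true(all(steps > 0))
  expect_true(all(steps <= 32))
  expect_true(all(diff(steps) < 0))  # diminishing gains as the gap grows
})

test_that("replaying a fixed comparison log is deterministic", {
  set.seed(9)
  ids <- paste0("img", 1:8)
  latent <- setNames(rnorm(8), ids)
  recs <- gen_comparisons(latent, 120, seed = 4)
  a <- replay_comparisons(ids, recs)
  b <- replay_comparisons(ids, recs)
  expect_identical(a$ratings, b$ratings)
  h <- elo_history(a)
  expect_equal(nrow(h), 120)
  expect_equal(h$image_a, recs$image_a)
})

test_that("ratings recover simulated latent fasciculation scores", {
  set.seed(42)
  ids <- sprintf("img%02d", 1:30)
  latent <- setNames(rnorm(30, 0, 2), ids)
  recs <- gen_comparisons(latent, 30 * 50 / 2, n_raters = 6,
                          noise_scale = 1, seed = 7)
  st <- replay_comparisons(ids, recs)
  expect_gt(cor(st$ratings[ids], latent, method = "spearman"), 0.9)
})

test_that("independent raters produce consistent rating vectors", {
  set.seed(31)
  ids <- sprintf("img%02d", 1:20)
  latent <- setNames(rnorm(20, 0, 2), ids)
  recs <- gen_comparisons(latent, 3 * 20 * 50 / 2, n_raters = 3,
                          noise_scale = 1, seed = 11)
  per_rater <- lapply(paste0("rater", 1:3), function(r)
    replay_comparisons(ids, recs[recs$rater == r, ])$ratings[ids])
  cors <- combn(3, 2, function(ij)
    cor(per_rater[[ij[1]]], per_rater[[ij[2]]], method = "spearman"))
  expect_true(all(cors >= 0.8))
})

test_that("tournaments converge on separable genotype rankings", {
  set.seed(3)
  images <- data.frame(image_id = sprintf("im%02d", 1:18),
                       retina_id = rep(sprintf("%s_r%d",
                                               rep(c("wt", "het", "mut"),
                                                   each = 2),
                                               rep(1:2, 3)), each = 3),
                       genotype = rep(c("wt", "het", "mut"), each = 6),
                       stringsAsFactors = FALSE)
  latent <- setNames(rep(c(3, 0, -3), each = 6) + rnorm(18, 0, 0.2),
                     images$image_id)
  st <- run_tournament(images, bt_chooser(latent, noise_scale = 1e-9),
                       config = elo_config(max_rounds = 100,
                                           stability_window = 5),
                       seed = 8)
  expect_true(st$converged)
  expect_lte(st$rounds_run, 100)
  gmeans <- tapply(st$ratings, setNames(images$genotype, images$image_id)[
    names(st$ratings)], mean)
  expect_equal(names(sort(gmeans)), c("mut", "het", "wt"))
  expect_lt(abs(sum(st$ratings)), 1e-9)
})

test_that("per-retina aggregation of ratings", {
  images <- data.frame(image_id = c("a", "b", "c"),
                       retina_id = c("r1", "r1", "r2"),
                       genotype = c("wt", "wt", "wt"),
                       stringsAsFactors = FALSE)
  st <- elo_init(c("a", "b", "c"))
  st$ratings <- c(a = 10, b = -10, c = 5)
  tab <- retina_scores(st, images)
  expect_equal(tab$value[tab$retina_id == "r1"], 0)
  expect_equal(tab$value[tab$retina_id == "r2"], 5)
  expect_error(retina_scores(st, images[1:2, ]), "unmapped")
})

test_that("genotype comparisons use exact rank-sum p-values with BH", {
  tab <- data.frame(retina_id = paste0("r", 1:12),
                    genotype = rep(c("wt", "mut"), each = 6),
                    metric = "elo_score",
                    value = c(7:12, 1:6),  # completely separated
                    stringsAsFactors = FALSE)
  res <- compare_genotypes(tab)
  expect_equal(res$p_raw, 2 / choose(12, 6))
  expect_equal(res$p_raw, exhaustive_wilcox_p(7:12, 1:6))

  # identical groups: no evidence either way
  tab2 <- tab; tab2$value <- rep(1:6, 2)
  res2 <- suppressWarnings(compare_genotypes(tab2))
  expect_gt(res2$p_raw, 0.99)

  # BH across three pairs
  tab3 <- data.frame(retina_id = paste0("r", 1:9),
                     genotype = rep(c("a", "b", "c"), each = 3),
                     metric = "elo_score",
                     value = c(1, 2, 3, 2, 3, 4, 10, 11, 12),
                     stringsAsFactors = FALSE)
  res3 <- compare_genotypes(tab3)
  expect_equal(res3$p_adjusted, p.adjust(res3$p_raw, "BH"))

  # genotypes with < 2 retinas are dropped with a warning
  tab4 <- rbind(tab, data.frame(retina_id = "r13", genotype = "het",
                                metric = "elo_score", value = 5))
  expect_warning(res4 <- compare_genotypes(tab4), "excluding")
  expect_equal(nrow(res4), 1)
})
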