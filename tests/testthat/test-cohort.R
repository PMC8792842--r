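mock_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$included <- TRUE
  df
}

test_that("summaries report n(%), mean(SD) and median(IQR width) by the type-7 rule", {
  tab <- mock_table(x = c(1, 2, 3, 4, 5),
                    grp = factor(rep("a", 5)),
                    cat = factor(rep("deep", 5)))
  s <- summarize_cohort(tab, c("x", "cat"))
  xs <- s[s$variable == "x", ]
  expect_equal(xs$median, 3)
  expect_equal(xs$iqr, 2)   # Q3 = 4, Q1 = 2 under linear interpolation
  expect_equal(xs$mean, 3)
  cs <- s[s$variable == "cat", ]
  expect_equal(cs$n, 5L)
  expect_equal(cs$pct, 100)

  # permutation invariance in row order
  tab2 <- tab[c(4, 1, 5, 3, 2), ]
  expect_equal(summarize_cohort(tab2, c("x", "cat")),
               summarize_cohort(tab, c("x", "cat")))

  # excluded rows are dropped; empty groups are omitted with a warning
  tab$included[tab$grp == "a"][1] <- FALSE
  expect_equal(summarize_cohort(tab, "x")$n, 4L)
  tab3 <- mock_table(x = 1:4, g = factor(c("a", "a", "b", "b"),
                                         levels = c("a", "b", "c")))
  expect_warning(s3 <- summarize_cohort(tab3, "x", group_by = "g"), "empty")
  expect_setequal(unique(s3$group), c("a", "b"))
})

test_that("generator medians are recovered from a large synthetic cohort", {
  co <- make_cohort(500, seed = 313)
  tab <- mock_table(age = co$clinical$age, v1 = co$truth$true_v1_ml)
  s <- summarize_cohort(tab, c("age", "v1"))
  expect_equal(s$median[s$variable == "age"], 61, tolerance = 0.05)
  expect_equal(s$median[s$variable == "v1"], 20, tolerance = 0.15)
})

test_that("Fisher's exact test fires on sparse tables and matches hypergeometric enumeration", {
  # 2x2 table [[8,2],[1,9]]: expected cells < 5
  tab <- mock_table(
    resp = factor(rep(c("yes", "no", "yes", "no"), c(8, 2, 1, 9))),
    grp = factor(rep(c("g1", "g2"), c(10, 10))))
  res <- compare_groups(tab, "resp", "grp")
  expect_equal(res$test, "Fisher exact")

  # independent oracle: enumerate every table with the observed margins
  # a = count of "no" in g1; margins: 11 "no", 9 "yes", 10 drawn into g1
  a_range <- max(0, 10 - 9):min(11, 10)
  pr <- dhyper(a_range, 11, 9, 10)
  p_obs <- dhyper(2, 11, 9, 10)
  p_oracle <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-8)

  # large balanced table goes through chi-squared
  tab2 <- mock_table(
    resp = factor(rep(c("yes", "no", "yes", "no"), c(30, 25, 22, 33))),
    grp = factor(rep(c("g1", "g2"), c(55, 55))))
  expect_equal(compare_groups(tab2, "resp", "grp")$test, "chi-squared")
})

test_that("two identical large samples are never significant", {
  set.seed(5)
  x <- rnorm(300)
  tab <- mock_table(x = c(x, x), g = factor(rep(c("a", "b"), each = 300)))
  res <- compare_groups(tab, "x", "g")
  expect_gt(res$p_value, 0.9)
  # selection is a pure function of the data
  res2 <- compare_groups(tab, "x", "g")
  expect_identical(res$test, res2$test)
  expect_identical(res$p_value, res2$p_value)
  expect_error(compare_groups(mock_table(x = rep(1, 10),
                                         g = factor(rep(c("a", "b"), 5))),
                              "x", "g"), "constant")
})

test_that("a one-SD shift at n = 200 per group is detected in >90% of replicates", {
  set.seed(77)
  rej <- vapply(1:200, function(i) {
    tab <- mock_table(x = c(rnorm(200), rnorm(200, 1)),
                      g = factor(rep(c("a", "b"), each = 200)))
    compare_groups(tab, "x", "g")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("skewed data routes to rank-based tests, >2 groups to ANOVA/Kruskal", {
  set.seed(8)
  tab <- mock_table(x = rlnorm(400), g = factor(rep(c("a", "b"), each = 200)))
  expect_equal(compare_groups(tab, "x", "g")$test, "Mann-Whitney U")
  tab3 <- mock_table(x = rnorm(300), g = factor(rep(c("a", "b", "c"), 100)))
  expect_equal(compare_groups(tab3, "x", "g")$test, "ANOVA")
  tab4 <- mock_table(x = rlnorm(300), g = factor(rep(c("a", "b", "c"), 100)))
  expect_equal(compare_groups(tab4, "x", "g")$test, "Kruskal-Wallis")
})

test_that("region direction synthesis averages unit vectors with resultant length", {
  tab <- mock_table(move_x = rep(0, 4), move_y = rep(-2, 4),
                    move_z = rep(0, 4),
                    move_distance_mm = rep(2, 4),
                    region_label = factor(rep("brain stem", 4)))
  s <- synthesize_region_directions(tab)
  expect_equal(c(s$mean_ux, s$mean_uy, s$mean_uz), c(0, -1, 0))
  expect_equal(s$resultant_length, 1)
  expect_equal(s$mean_distance_mm, 2)
  expect_true(s$direction_defined)

  # perfect cancellation
  tab2 <- mock_table(move_x = c(1, -1), move_y = c(0, 0), move_z = c(0, 0),
                     move_distance_mm = c(1, 1),
                     region_label = factor(rep("cerebellum", 2)))
  s2 <- synthesize_region_directions(tab2)
  expect_equal(s2$resultant_length, 0)
  expect_false(s2$direction_defined)

  # zero vectors excluded from direction but kept in the distance mean
  tab3 <- mock_table(move_x = c(0, 0, 3), move_y = c(0, 0, 0),
                     move_z = c(0, 0, 4),
                     move_distance_mm = c(0, 0, 5),
                     region_label = factor(rep("frontal", 3)))
  s3 <- synthesize_region_directions(tab3)
  expect_equal(s3$n_direction, 1L)
  expect_equal(s3$mean_distance_mm, 5 / 3)
  expect_equal(c(s3$mean_ux, s3$mean_uy, s3$mean_uz), c(0.6, 0, 0.8))
})

test_that("a planted posterior bias is recovered per region within 15 degrees", {
  co <- make_cohort(60, bias_direction = c(0, -1, 0), bias_strength = 3,
                    noise_sd = 1, seed = 404)
  tab <- mock_table(move_x = co$truth$true_disp_x,
                    move_y = co$truth$true_disp_y,
                    move_z = co$truth$true_disp_z,
                    move_distance_mm = sqrt(co$truth$true_disp_x^2 +
                                            co$truth$true_disp_y^2 +
                                            co$truth$true_disp_z^2),
                    region_label = co$clinical$region_label)
  s <- synthesize_region_directions(tab)
  main <- s[s$n >= 10, ]
  expect_gt(nrow(main), 0)
  for (i in seq_len(nrow(main))) {
    mu <- c(main$mean_ux[i], main$mean_uy[i], main$mean_uz[i])
    ang <- acos(sum(mu * c(0, -1, 0)) / sqrt(sum(mu^2))) * 180 / pi
    expect_lt(ang, 15)
  }
})

test_that("axis-type cross-tab reports the unchanged fraction as the trace share", {
  tab <- mock_table(axis_type_initial = rep("AP", 6),
                    axis_type_repeat = rep("AP", 6))
  ct <- axis_type_cross_tab(tab)
  expect_equal(ct$fraction_unchanged, 1)

  tab2 <- mock_table(
    axis_type_initial = c(rep("AP", 12), rep("SI", 5), "LR", "NL", "AP"),
    axis_type_repeat = c(rep("AP", 12), rep("SI", 5), "LR", "NL", "LR"))
  ct2 <- axis_type_cross_tab(tab2)
  expect_equal(ct2$fraction_unchanged, 19 / 20)
  expect_equal(sum(ct2$table), 20)
  expect_equal(ct2$table["AP", "LR"], 1)
})
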