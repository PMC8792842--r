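test_that("length changes are signed repeat-minus-initial differences", {
  expect_equal(unname(length_changes(c(44, 22, 29), c(50, 32, 32))),
               c(6, 10, 3))
  expect_equal(unname(length_changes(c(30, 20, 25), c(30, 20, 25))),
               c(0, 0, 0))
  # antisymmetry
  expect_equal(unname(length_changes(c(50, 32, 32), c(44, 22, 29))),
               c(-6, -10, -3))
  expect_error(length_changes(c(0, 1, 1), c(1, 1, 1)), "positive")
})

test_that("direction change picks the dominant axis and respects the similarity rule", {
  expect_equal(classify_direction_change(c(6, 10, 3)), "LR")
  expect_equal(classify_direction_change(c(0, 0, 0)), "none")
  # 4.5/5 = 0.9 >= 0.850: the two leading changes are similar
  expect_equal(classify_direction_change(c(5, 4.5, 1)), "none")
  # below the 1 mm floor
  expect_equal(classify_direction_change(c(0.9, 0.2, 0.1)), "none")
  # exact tie of the maximum
  expect_equal(classify_direction_change(c(5, -5, 1)), "none")
  # sign does not matter
  expect_equal(classify_direction_change(c(-8, 2, 1)), "AP")
})

test_that("direction change agrees with a brute-force argmax-plus-similarity oracle", {
  oracle <- function(d, eps = 1, lo = 0.850) {
    a <- abs(d)
    imax <- 1
    for (i in 2:3) if (a[i] > a[imax]) imax <- i
    others <- a[-imax]
    if (a[imax] < eps) return("none")
    if (max(others) >= lo * a[imax]) return("none")
    c("AP", "LR", "SI")[imax]
  }
  set.seed(7)
  d <- matrix(rnorm(3 * 10000, 0, 5), ncol = 3)
  expect_identical(apply(d, 1, classify_direction_change),
                   apply(d, 1, oracle))
})

test_that("geometric center is the world centroid of the largest 26-component", {
  # centered cube
  g <- array(0L, c(9, 9, 9)); g[4:6, 4:6, 4:6] <- 1L
  expect_equal(geometric_center(hematoma_mask(g)), c(4, 4, 4))

  # two components: only the 100-voxel one counts
  g2 <- array(0L, c(20, 12, 12))
  g2[2:6, 2:6, 3:6] <- 1L             # 100 voxels
  g2[15:16, 9:10, 9:10] <- 1L         # 8 voxels, far away
  big_idx <- which(g2 == 1L, arr.ind = TRUE)
  big <- big_idx[big_idx[, 1] <= 6, ]
  expect_equal(geometric_center(hematoma_mask(g2)),
               unname(colMeans(big) - 1))

  # single voxel, anisotropic spacing
  g3 <- array(0L, c(5, 5, 5)); g3[2, 3, 4] <- 1L
  expect_equal(geometric_center(hematoma_mask(g3, spacing = c(1, 2, 3))),
               c(1, 4, 9))

  # affine translation moves the world center accordingly
  aff <- diag(4); aff[1:3, 4] <- c(-10, 5, 2)
  expect_equal(geometric_center(hematoma_mask(g, affine = aff)),
               c(-6, 9, 6))
})

test_that("component labelling agrees with igraph on random fields", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:5) {
    g <- array(rbinom(10 * 9 * 8, 1, 0.25), c(10, 9, 8))
    if (sum(g) == 0) next
    comps <- hemomorph:::label_components_26(g)
    idx <- which(g == 1L, arr.ind = TRUE)
    n <- nrow(idx)
    adj <- which(as.matrix(dist(idx, method = "maximum")) <= 1, arr.ind = TRUE)
    adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
    gr <- if (nrow(adj) > 0)
      igraph::graph_from_edgelist(adj, directed = FALSE)
    else igraph::make_empty_graph(directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
    memb <- igraph::components(gr)
    expect_equal(length(comps), memb$no)
    expect_equal(sort(vapply(comps, nrow, integer(1))),
                 sort(unname(memb$csize)))
  }
})

test_that("center movement reports distance, vector and plane projections", {
  mv <- center_movement(c(0, 0, 0), c(3, 4, 0))
  expect_equal(mv$distance, 5)
  expect_equal(unname(mv$projections$axial), c(3, 4))
  expect_equal(unname(mv$projections$coronal), c(3, 0))
  expect_equal(unname(mv$projections$sagittal), c(4, 0))
  mv0 <- center_movement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mv0$distance, 0)
  expect_true(all(unlist(mv0$projections) == 0))
})

test_that("pure translations are recovered within half a voxel per axis", {
  t_true <- c(2, -3, 6)
  sp <- synthetic_spec(c(10, 14, 11), displacement = t_true,
                       irregularity_amp = 0.2, seed = 8)
  cs <- make_paired_case(sp, grid_shape = c(72, 72, 72))
  mv <- center_movement(geometric_center(cs$initial),
                        geometric_center(cs$repeat_))
  expect_true(all(abs(mv$vector - t_true) <= 0.5))
})

test_that("expansion classification applies the inclusive 6 mL / 33% rule", {
  e <- classify_expansion(15.6, 23.5)
  expect_true(e$expansion)
  expect_equal(e$abs_change_ml, 7.9)
  expect_false(classify_expansion(20, 20)$expansion)
  # relative-only route: 36.7% with only 1.1 mL absolute
  e2 <- classify_expansion(3.0, 4.1)
  expect_true(e2$expansion)
  expect_lt(e2$abs_change_ml, 6)
  # inclusive boundaries
  expect_true(classify_expansion(30, 36)$expansion)        # abs exactly 6
  expect_true(classify_expansion(9, 11.97)$expansion)      # rel exactly 33
  expect_error(classify_expansion(0, 5), "positive")
  # monotone in repeat volume
  flags <- classify_expansion(rep(10, 50), seq(5, 25, length.out = 50))$expansion
  expect_true(all(diff(flags) >= 0))
})

test_that("Dice coefficient counts overlap and hits exact boundary values", {
  a <- hematoma_mask(array(1L, c(5, 5, 4)))
  expect_equal(dice_coefficient(a, a), 1)

  g1 <- array(0L, c(10, 10, 4)); g1[1:5, , 1] <- 1L
  g2 <- array(0L, c(10, 10, 4)); g2[6:10, , 1] <- 1L
  expect_equal(dice_coefficient(hematoma_mask(g1), hematoma_mask(g2)), 0)

  # |A| = |B| = 100, overlap 50 -> 0.5
  h1 <- array(0L, c(20, 10, 2)); h1[1:10, 1:10, 1] <- 1L
  h2 <- array(0L, c(20, 10, 2)); h2[6:15, 1:10, 1] <- 1L
  expect_equal(dice_coefficient(hematoma_mask(h1), hematoma_mask(h2)), 0.5)
  # symmetry
  expect_equal(dice_coefficient(hematoma_mask(h2), hematoma_mask(h1)), 0.5)

  expect_error(dice_coefficient(a, hematoma_mask(array(1L, c(5, 5, 5)))),
               "shape")
  z <- hematoma_mask(array(0L, c(5, 5, 4)))
  expect_error(dice_coefficient(z, z), "empty")
})

test_that("registration QC threshold 0.93 is inclusive", {
  expect_true(qc_registration(0.95))
  expect_true(qc_registration(0.93))
  expect_false(qc_registration(0.90))
  expect_error(qc_registration(1.2), "\\[0, 1\\]")
})

test_that("pair reports compose all change metrics consistently", {
  sp <- synthetic_spec(c(12, 16, 13), growth_factors = c(1.25, 1.05, 1.02),
                       displacement = c(1.5, -2.5, 1),
                       irregularity_amp = 0.15, seed = 21)
  cs <- make_paired_case(sp, grid_shape = c(80, 80, 80))
  pr <- pair_report(cs$initial, cs$repeat_)

  # identical pair: all null changes
  pr0 <- pair_report(cs$initial, cs$initial)
  expect_equal(pr0$delta_ap, 0)
  expect_equal(pr0$direction_change, "none")
  expect_false(pr0$expansion)
  expect_equal(pr0$dice, 1)
  expect_false(pr0$axis_type_changed)

  # antisymmetry under swapping the scans
  pr_rev <- pair_report(cs$repeat_, cs$initial)
  expect_equal(pr_rev$delta_ap, -pr$delta_ap)
  expect_equal(pr_rev$delta_lr, -pr$delta_lr)
  expect_equal(pr_rev$delta_si, -pr$delta_si)
  expect_equal(unname(pr_rev$move_vector), -unname(pr$move_vector))
  expect_equal(pr_rev$move_distance_mm, pr$move_distance_mm)

  # ground-truth agreement
  expect_true(all(abs(pr$move_vector - cs$truth$true_center_shift) <= 0.5))
  expect_equal(pr$metrics_repeat$volume_ml / pr$metrics_initial$volume_ml,
               prod(sp$growth_factors), tolerance = 0.03)
  expect_equal(pr$expansion, cs$truth$true_expansion)

  # registration QC pass-through
  pr_qc <- pair_report(cs$initial, cs$repeat_, reg_dice = 0.91)
  expect_false(pr_qc$qc_pass)
  expect_false(pr_qc$qc_assumed)
  expect_true(pr$qc_assumed)

  # flat form carries one row
  df <- as.data.frame(pr)
  expect_equal(nrow(df), 1)
  expect_true(all(c("volume_ml_initial", "delta_lr", "move_distance_mm",
                    "expansion") %in% names(df)))

  # incomparable grids are refused
  other <- hematoma_mask(array(1L, c(10, 10, 10)))
  expect_error(pair_report(cs$initial, other), "not comparable")
})
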