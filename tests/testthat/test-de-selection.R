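test_that("a protein identical in both groups is never selected", {
  withr::with_seed(1, {
    mat <- matrix(rnorm(20 * 36), nrow = 20)
    mat[1, ] <- rep(c(1, 2, 3, 4), 9) # same values whatever the grouping
  })
  x <- make_intensity(mat)
  design <- make_design(x, n_cca = 19)
  plan <- build_folds(design, seed = 1)
  de <- select_de(x, design, plan)
  expect_false(de$is_de[1])
  expect_true(de$quantifiable[1])
})

test_that("selection is an intersection rule and monotone in alpha", {
  cfg <- sim_config(n_proteins = 150, frac_de = 0.2, seed = 21)
  design <- simulate_cohort(cfg)
  x <- normalize_intensity(simulate_matrix(cfg, design)$matrix)
  plan <- build_folds(design, seed = 21)
  de <- select_de(x, design, plan, alpha = 0.01)
  pcols <- as.matrix(de[, sprintf("p_fold_%d", 1:6)])
  # is_de implies every fold p below alpha (stringency invariant)
  expect_true(all(pcols[de$is_de, ] < 0.01))
  # selected set only shrinks when alpha is lowered
  stricter <- select_de(x, design, plan, alpha = 0.001)
  expect_true(all(de$protein[stricter$is_de] %in% de$protein[de$is_de]))
  # direction is consistent with the overall mean difference
  expect_true(all(de$direction[de$is_de] ==
    ifelse(de$log2_fc[de$is_de] > 0, "up", "down")))
  expect_error(select_de(x, design, plan, alpha = 1.2), class = "serodiff_config_error")
})

test_that("quantifiability requires enough observations per group per fold", {
  cfg <- sim_config(n_proteins = 30, missing_rate = 0, seed = 3)
  design <- simulate_cohort(cfg)
  sim <- simulate_matrix(cfg, design)
  mat <- intensity_matrix(sim$matrix)
  # blank out all but one CCA value for protein 1: below min_obs in any fold
  cca_ids <- design$sample_id[design$group == "CCA"]
  mat[1, cca_ids[-1]] <- NA
  x <- make_intensity(mat)
  plan <- build_folds(design, seed = 3)
  de <- select_de(x, design, plan)
  expect_false(de$quantifiable[1])
  expect_false(de$is_de[1])
  expect_true(is.na(de$max_fold_p[1]))
  expect_true(all(de$quantifiable[-1]))
})

test_that("null simulations select almost nothing", {
  # P(all 6 fold tests reject) is bounded by any single fold's alpha
  counts <- purrr::map_int(1:5, function(s) {
    cfg <- sim_config(n_proteins = 300, frac_de = 0, seed = s)
    design <- simulate_cohort(cfg)
    x <- normalize_intensity(simulate_matrix(cfg, design)$matrix)
    plan <- build_folds(design, seed = s)
    sum(select_de(x, design, plan)$is_de)
  })
  expect_lte(mean(counts), 300 * 0.01)
})

test_that("fold-level Welch p-values are uniform under the null", {
  # complete null, no missing values: downstream p-values ~ U(0,1)
  cfg <- sim_config(n_proteins = 1000, frac_de = 0, missing_rate = 0, seed = 17)
  design <- simulate_cohort(cfg)
  x <- normalize_intensity(simulate_matrix(cfg, design)$matrix)
  plan <- build_folds(design, seed = 17)
  de <- select_de(x, design, plan)
  ks <- suppressWarnings(stats::ks.test(de$p_fold_1, "punif"))
  expect_gt(ks$p.value, 0.01)
  ks_all <- suppressWarnings(stats::ks.test(de$p_all, "punif"))
  expect_gt(ks_all$p.value, 0.01)
})

test_that("strong spiked effects are recovered with high sensitivity", {
  # the strongest published configuration: effect 1.67, SDs 0.3 / 0.7
  hits <- purrr::map_lgl(1:50, function(s) {
    with_seed <- withr::with_seed
    with_seed(s, {
      n_cca <- 19
      n_bbtd <- 17
      spike <- c(rnorm(n_cca, 1.67, 0.3), rnorm(n_bbtd, 0, 0.7))
      noise <- matrix(rnorm(19 * 36, 0, 0.5), nrow = 19)
      mat <- rbind(spike, noise)
      x <- make_intensity(mat)
      design <- make_design(x, n_cca = n_cca)
      plan <- build_folds(design, seed = s)
      select_de(x, design, plan)$is_de[1]
    })
  })
  expect_gte(mean(hits), 0.9)
})

test_that("partition_up_down splits selected proteins by direction", {
  cfg <- sim_config(
    n_proteins = 40, frac_de = 0.25, effect_low = 1.5, effect_high = 1.7,
    sd_low = 0.2, sd_high = 0.4, missing_rate = 0, seed = 6
  )
  design <- simulate_cohort(cfg)
  sim <- simulate_matrix(cfg, design)
  x <- normalize_intensity(sim$matrix)
  plan <- build_folds(design, seed = 6)
  de <- select_de(x, design, plan)
  ud <- partition_up_down(de)
  # 10 spiked effects, 5 of each sign, all strong: every spike is recovered
  # with the right direction (false positives from the 30 null proteins are
  # possible but rare, so they are counted separately)
  spikes <- sim$truth$protein[sim$truth$is_de]
  expect_equal(sum(ud$up$protein %in% spikes), 5)
  expect_equal(sum(ud$down$protein %in% spikes), 5)
  expect_lte(nrow(ud$up) + nrow(ud$down) - 10, 1)
  expect_true(all(ud$up$log2_fc > 0))
  expect_true(all(ud$down$log2_fc < 0))
  expect_true(!is.unsorted(ud$up$max_fold_p))
  expect_true(!is.unsorted(ud$down$max_fold_p))
  # empty table gives two empty lists
  null_de <- select_de(x, design, plan, alpha = 1e-12)
  ud0 <- partition_up_down(null_de)
  expect_equal(nrow(ud0$up) + nrow(ud0$down), sum(null_de$is_de))

  g <- glance(de)
  expect_equal(g$n_de, g$n_up + g$n_down)
  expect_equal(g$n_proteins, 40)
})
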