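strong_sim <- function(seed, n_proteins = 30, effect = 2.0, sd = 0.3) {
  cfg <- sim_config(
    n_proteins = n_proteins, frac_de = 0.5,
    effect_low = effect, effect_high = effect,
    sd_low = sd, sd_high = sd, missing_rate = 0, seed = seed
  )
  design <- simulate_cohort(cfg)
  sim <- simulate_matrix(cfg, design)
  list(x = sim$matrix, design = design, truth = sim$truth)
}

test_that("clustering separates strongly contrasted groups", {
  s <- strong_sim(seed = 41)
  cl <- cluster_heatmap(s$x, s$design, proteins = s$truth$protein[s$truth$is_de])
  expect_equal(cl$misassignments, 0L)
  expect_setequal(cl$assignments$sample_id, s$design$sample_id)
  # leaf order is a permutation of the samples
  expect_setequal(cl$sample_order, s$design$sample_id)
})

test_that("display values are clipped and label order does not matter", {
  s <- strong_sim(seed = 42)
  ids <- s$truth$protein[s$truth$is_de]
  cl <- cluster_heatmap(s$x, s$design, proteins = ids)
  expect_true(all(abs(cl$display$z) <= 3 + 1e-12))
  # permuting sample order in the design changes nothing but ordering
  perm <- withr::with_seed(1, s$design[sample(nrow(s$design)), ])
  cl2 <- cluster_heatmap(s$x, perm, proteins = ids)
  expect_equal(cl2$misassignments, cl$misassignments)
  a1 <- cl$assignments[order(cl$assignments$sample_id), ]
  a2 <- cl2$assignments[order(cl2$assignments$sample_id), ]
  # same partition up to cluster relabelling: one nonzero cell per row
  ct <- table(a1$cluster, a2$cluster)
  expect_true(all(rowSums(ct > 0) == 1))
})

test_that("duplicated samples merge at height zero; constant rows are dropped", {
  mat <- matrix(rnorm(40), nrow = 10)
  mat <- cbind(mat, mat[, 4]) # duplicate of sample 4
  colnames(mat) <- sprintf("S%d", 1:5)
  x <- make_intensity(mat)
  design <- tibble::tibble(
    sample_id = colnames(mat),
    group = c("CCA", "CCA", "BBTD", "BBTD", "BBTD")
  )
  cl <- cluster_heatmap(x, design)
  expect_equal(min(cl$sample_hclust$height), 0)
  pos <- match(c("S4", "S5"), cl$sample_order)
  expect_equal(abs(diff(pos)), 1) # adjacent leaves
  # constant protein rows are excluded with a warning
  mat2 <- rbind(mat, 7)
  rownames(mat2) <- sprintf("P%03d", 1:11)
  expect_warning(cluster_heatmap(make_intensity(mat2), design), "constant")
})

test_that("null data cluster at chance agreement with the labels", {
  agreements <- purrr::map_dbl(1:100, function(s) {
    cfg <- sim_config(n_proteins = 20, frac_de = 0, missing_rate = 0, seed = s)
    design <- simulate_cohort(cfg)
    sim <- simulate_matrix(cfg, design)
    cl <- cluster_heatmap(sim$matrix, design)
    1 - cl$misassignments / nrow(design)
  })
  expect_lt(abs(mean(agreements) - 0.5), 0.15) # chance level under the null
})

test_that("PCA recovers a single axis of separation in the noise-free limit", {
  # two identical point clouds translated apart along one protein axis
  base <- matrix(rnorm(5 * 8, sd = 1e-3), nrow = 5)
  mat <- cbind(base, base)
  mat[1, 9:16] <- mat[1, 9:16] + 10
  colnames(mat) <- sprintf("S%02d", 1:16)
  x <- make_intensity(mat)
  design <- tibble::tibble(
    sample_id = colnames(mat),
    group = rep(c("BBTD", "CCA"), each = 8)
  )
  pc <- pca_scores(x, design, n_comp = 3)
  expect_gt(pc$explained[1], 0.999)
  # PC1 is aligned with the shifted protein axis: groups split on PC1
  sc <- pc$scores
  expect_true(
    max(sc$PC1[sc$group == "BBTD"]) < min(sc$PC1[sc$group == "CCA"]) ||
      min(sc$PC1[sc$group == "BBTD"]) > max(sc$PC1[sc$group == "CCA"])
  )
})

test_that("PCA scores are orthogonal and separation exceeds 1 on strong effects", {
  seps <- purrr::map_dbl(1:20, function(s) {
    st <- strong_sim(seed = s)
    pc <- pca_scores(st$x, st$design, proteins = st$truth$protein[st$truth$is_de])
    cors <- cor(as.matrix(pc$scores[, c("PC1", "PC2", "PC3")]))
    expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
    pc$separation
  })
  expect_true(all(seps > 1))
})

test_that("volcano coordinates mirror the DE table", {
  cfg <- sim_config(n_proteins = 80, frac_de = 0.2, seed = 13)
  design <- simulate_cohort(cfg)
  x <- normalize_intensity(simulate_matrix(cfg, design)$matrix)
  de <- select_de(x, design, build_folds(design, seed = 13))
  v <- volcano(de, cutoff = 0.01)
  expect_equal(nrow(v), sum(de$quantifiable))
  expect_identical(v$de, de$is_de[de$quantifiable])
  # boundary convention is strict: p exactly at the cutoff is not flagged
  fake <- de
  fake$max_fold_p[de$quantifiable][1] <- 0.01
  expect_false(volcano(fake, cutoff = 0.01)$de[1])
  # equal group means give zero fold change
  expect_equal(v$log2_fc, de$log2_fc[de$quantifiable])
})

test_that("box summaries follow the linear-interpolation quartile convention", {
  mat <- matrix(c(1, 2, 3, 4, 5, 1, 1, 1, 1, 1), nrow = 1)
  colnames(mat) <- sprintf("S%02d", 1:10)
  rownames(mat) <- "P001"
  x <- make_intensity(mat)
  design <- tibble::tibble(
    sample_id = colnames(mat), group = rep(c("CCA", "BBTD"), each = 5)
  )
  b <- top_protein_boxes(x, design, proteins = "P001")
  cca <- b[b$group == "CCA", ]
  expect_equal(cca$min, 1)
  expect_equal(cca$q1, 2) # type-7 quartile of {1..5}
  expect_equal(cca$median, 3)
  expect_equal(cca$q3, 4)
  expect_equal(cca$max, 5)
  bbtd <- b[b$group == "BBTD", ]
  expect_true(all(bbtd[, c("min", "q1", "median", "q3", "max")] == 1)) # degenerate box
  expect_error(top_protein_boxes(x, design, proteins = "nope"), "nope",
    class = "serodiff_data_error"
  )
})

test_that("top proteins are picked by fold change and medians track the truth", {
  s <- strong_sim(seed = 55, n_proteins = 40, effect = 1.67, sd = 0.3)
  x <- s$x
  design <- s$design
  de <- select_de(x, design, build_folds(design, seed = 55))
  b <- top_protein_boxes(x, design, detable = de, n_top = 5)
  expect_equal(length(unique(b$protein)), 5)
  med <- tidyr::pivot_wider(b[, c("protein", "group", "median")],
    names_from = "group", values_from = "median"
  )
  truth <- s$truth[match(med$protein, s$truth$protein), ]
  expect_equal(med$CCA - med$BBTD, truth$effect, tolerance = 0.35)
})
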