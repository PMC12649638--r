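test_that("gene filtering honours the mean gate and variance ranking", {
  set.seed(4)
  m <- matrix(rnorm(100, mean = 5), 10, 10,
              dimnames = list(paste0("g", 1:10), NULL))
  expect_identical(filter_genes(m, min_mean = 0, top_n = 10L), m)
  got <- filter_genes(m, min_mean = 0, top_n = 3L)
  v <- apply(m, 1, var)
  expect_setequal(rownames(got),
                  names(sort(v, decreasing = TRUE))[1:3])
  # constant gene always loses the variance race
  m2 <- rbind(m[1:3, ], const = rep(5, 10))
  expect_false("const" %in% rownames(filter_genes(m2, top_n = 3L)))
  expect_warning(filter_genes(m, min_mean = 0, top_n = 50L), "keeping all")
  expect_error(filter_genes(m, min_mean = 100), "no genes")
})

test_that("correlation and distance matrices satisfy their identities", {
  set.seed(5)
  m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  m[2, ] <- -m[1, ]           # perfect anti-correlation
  cd <- correlation_and_distance(m)
  expect_equal(diag(cd$R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(cd$D), rep(0, 4), ignore_attr = TRUE)
  expect_equal(cd$R[1, 2], -1)
  expect_equal(cd$D[1, 2], 0)  # unsigned network: |-1| = 1
  expect_true(all(cd$D >= 0 & cd$D <= 1))
  # brute-force two-pass Pearson oracle
  brute <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- m[i, ] - mean(m[i, ]); xj <- m[j, ] - mean(m[j, ])
    brute[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(cd$R, brute, ignore_attr = TRUE, tolerance = 1e-12)
  m[3, ] <- 7
  expect_error(correlation_and_distance(m), "g3")
})

test_that("two leaves merge at their distance", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2)
  l <- ward_linkage(D)
  expect_equal(l$height, 0.4)
  expect_identical(l$size, 2L)
})

test_that("uniform distances follow the lowest-id tie rule", {
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  l <- ward_linkage(D)
  # leaves 1,2 first, then leaves 3,4, then the two pairs
  expect_identical(sort(l$merge[1, ]), c(-2L, -1L))
  expect_identical(sort(l$merge[2, ]), c(-4L, -3L))
  expect_identical(sort(l$merge[3, ]), c(1L, 2L))
  expect_equal(l$height[1], 0.5)
})

test_that("linkage agrees with the reference Ward.D2 implementation", {
  set.seed(6)
  for (i in 1:5) {
    n <- sample(20:40, 1)
    x <- matrix(rnorm(n * 4), n)
    D <- as.matrix(dist(x))
    l <- ward_linkage(D)
    h <- hclust(as.dist(D), method = "ward.D2")
    expect_equal(l$height, h$height, tolerance = 1e-9)
    for (k in c(2, 4, 6))
      expect_gt(suppressWarnings(abs(mclust::adjustedRandIndex(
        cutree(as.hclust(l), k), cutree(h, k)))), 0.999)
    # Ward heights increase weakly along the merge sequence
    expect_true(all(diff(l$height) >= -1e-9))
  }
})

test_that("static cut, minimum size and recursive split behave as specified", {
  cfg <- sim_config(n_genes = 80, module_sizes = c(40L, 40L), n_per_group = 10,
                    loading_range = c(1, 1), noise_sd = 0, trait_effect = 0,
                    driven_module_index = 1, seed = 2)
  s <- simulate_expression(cfg)
  cd <- correlation_and_distance(s$expr)
  l <- ward_linkage(cd$D)
  # default cut separates the two exact modules, matching truth
  lab <- cut_dendrogram(l, min_size = 10L)
  expect_identical(sort(unique(lab)), c("blue", "turquoise"))
  expect_equal(length(unique(lab[s$truth$gene_module == 1])), 1L)
  expect_equal(length(unique(lab[s$truth$gene_module == 2])), 1L)
  # cut above the root: refinement separates the two distinct branches
  lab2 <- cut_dendrogram(l, cut_height = max(l$height) + 1, min_size = 10L)
  expect_identical(sort(unique(lab2)), c("blue", "turquoise"))
  # cut above the root on homogeneous data: one module with all genes
  set.seed(77)
  blob <- matrix(rnorm(300), 30, 10,
                 dimnames = list(paste0("b", 1:30), NULL))
  lb <- ward_linkage(correlation_and_distance(blob)$D)
  labb <- cut_dendrogram(lb, cut_height = max(lb$height) + 1, min_size = 5L)
  expect_identical(unique(labb), "turquoise")
  # cut below every merge: everything grey (noisy tree, all heights > 0)
  labg <- cut_dendrogram(lb, cut_height = min(lb$height) / 2, min_size = 5L)
  expect_true(all(labg == "grey"))
  # min_size larger than any cluster also greys everything
  expect_true(all(cut_dendrogram(l, min_size = 60L) == "grey"))
  expect_error(cut_dendrogram(l, cut_height = 0), "positive")
  expect_error(cut_dendrogram(l, min_size = 1L), "min_size")
})

test_that("module colors follow size rank with index tie-break", {
  cfg <- sim_config(n_genes = 100, module_sizes = c(30L, 50L, 20L),
                    n_per_group = 10, loading_range = c(1, 1), noise_sd = 0,
                    trait_effect = 0, driven_module_index = 1, seed = 9)
  s <- simulate_expression(cfg)
  cd <- correlation_and_distance(s$expr)
  lab <- cut_dendrogram(ward_linkage(cd$D), min_size = 5L)
  # largest true module (index 2, size 50) must be turquoise
  expect_identical(unique(lab[s$truth$gene_module == 2]), "turquoise")
  expect_identical(unique(lab[s$truth$gene_module == 1]), "blue")
  expect_identical(unique(lab[s$truth$gene_module == 3]), "brown")
})

test_that("eigengenes are unit-variance first principal components", {
  # rank-1 module: every gene is an affine copy of one profile
  base <- rnorm(12)
  m <- rbind(g1 = base, g2 = 2 * base + 3, g3 = -base + 1,
             g4 = 0.5 * base)
  labels <- rep("turquoise", 4)
  me <- module_eigengenes(m, labels)
  expect_equal(me$var_explained[["turquoise"]], 1, tolerance = 1e-12)
  expect_equal(sd(me$eigengenes["turquoise", ]), 1, tolerance = 1e-12)
  z <- (base - mean(base)) / sd(base)
  expect_equal(abs(cor(me$eigengenes["turquoise", ], z)), 1,
               tolerance = 1e-12)
  # sign convention: positively correlated with the module mean z-profile
  zmean <- colMeans(t(scale(t(m))))
  expect_gte(cor(me$eigengenes["turquoise", ], zmean), 0)
  # flipping every gene flips nothing observable after re-standardizing
  me2 <- module_eigengenes(-m, labels)
  expect_equal(abs(cor(me$eigengenes[1, ], me2$eigengenes[1, ])), 1,
               tolerance = 1e-12)
  expect_warning(module_eigengenes(rbind(m, solo = rnorm(12)),
                                   c(labels, "blue")), "single gene")
})

test_that("eigengene variance explained approaches the squared loading", {
  cfg <- sim_config(n_genes = 60, module_sizes = 50L, n_per_group = 100,
                    loading_range = c(0.9, 0.9), trait_effect = 0,
                    driven_module_index = 1, seed = 13)
  s <- simulate_expression(cfg)
  labels <- ifelse(s$truth$gene_module == 1, "turquoise", "grey")
  me <- module_eigengenes(s$expr, labels)
  expect_equal(me$var_explained[["turquoise"]], 0.81, tolerance = 0.05)
})

test_that("eigengene merging respects the similarity threshold", {
  # two modules driven by the same latent must collapse into one
  cfg <- sim_config(n_genes = 80, module_sizes = 80L, n_per_group = 10,
                    loading_range = c(0.95, 0.95), trait_effect = 0,
                    driven_module_index = 1, seed = 21)
  s <- simulate_expression(cfg)
  labels <- rep(c("turquoise", "blue"), each = 40)   # artificial split
  merged <- merge_modules(s$expr, labels)
  expect_identical(unique(merged), "turquoise")
  # independent latents at many samples stay apart
  cfg2 <- sim_config(n_genes = 80, module_sizes = c(40L, 40L),
                     n_per_group = 200, loading_range = c(0.9, 0.9),
                     trait_effect = 0, driven_module_index = 1, seed = 22)
  s2 <- simulate_expression(cfg2)
  lab2 <- ifelse(s2$truth$gene_module == 1, "turquoise", "blue")
  merged2 <- merge_modules(s2$expr, lab2)
  expect_identical(length(setdiff(unique(merged2), "grey")), 2L)
  # hard post-condition on arbitrary noisy data
  set.seed(23)
  noisy <- matrix(rnorm(600), 60, 10,
                  dimnames = list(paste0("g", 1:60), NULL))
  lab3 <- rep(c("turquoise", "blue", "brown"), each = 20)
  merged3 <- merge_modules(noisy, lab3)
  mods <- setdiff(unique(merged3), "grey")
  if (length(mods) >= 2L) {
    C <- cor(t(module_eigengenes(noisy, merged3)$eigengenes))
    diag(C) <- -Inf
    expect_lte(max(C), 0.75)
  }
})

test_that("kME recovers planted loadings and is affine-invariant", {
  cfg <- sim_config(n_genes = 60, module_sizes = 50L, n_per_group = 250,
                    loading_range = c(0.8, 0.8), trait_effect = 0,
                    driven_module_index = 1, seed = 31)
  s <- simulate_expression(cfg)
  labels <- ifelse(s$truth$gene_module == 1, "turquoise", "grey")
  me <- module_eigengenes(s$expr, labels)
  K <- kme(s$expr, me$eigengenes)
  own <- K[s$truth$gene_module == 1, "turquoise"]
  expect_true(all(abs(own - 0.8) < 0.05))
  # gene identical to its eigengene
  m2 <- rbind(s$expr[1:10, ], copy = me$eigengenes["turquoise", ])
  K2 <- kme(m2, me$eigengenes)
  expect_equal(K2["copy", "turquoise"], 1, tolerance = 1e-12)
  # Pearson is invariant to affine rescaling
  m3 <- s$expr[1:10, , drop = FALSE]
  expect_equal(kme(3 * m3 + 7, me$eigengenes), kme(m3, me$eigengenes),
               tolerance = 1e-12)
})

test_that("module-trait inference flags the planted association", {
  cfg <- sim_config(n_genes = 200, module_sizes = c(60L, 60L, 60L),
                    n_per_group = 5, loading_range = c(0.7, 0.95),
                    trait_effect = 3, driven_module_index = 1, seed = 41)
  s <- simulate_expression(cfg)
  labels <- module_colors(3)[pmax(s$truth$gene_module, 1)]
  labels[s$truth$gene_module == 0] <- "grey"
  me <- module_eigengenes(s$expr, labels)
  traits <- data.frame(group = as.numeric(s$metadata$group == "feeding"))
  mt <- module_trait(me$eigengenes, traits)
  expect_equal(mt$q_value, benjamini_hochberg(mt$p_value))
  expect_true(all(mt$q_value >= mt$p_value - 1e-12))
  # trait identical to an eigengene is maximally significant
  traits2 <- data.frame(me_copy = me$eigengenes[1, ])
  mt2 <- module_trait(me$eigengenes, traits2)
  row <- mt2[mt2$module == rownames(me$eigengenes)[1], ]
  expect_equal(row$pearson_r, 1, tolerance = 1e-12)
  expect_lt(row$p_value, 1e-12)
  expect_true(row$significant)
  # single module x single trait: q = p
  mt3 <- module_trait(me$eigengenes[1, , drop = FALSE], traits)
  expect_equal(mt3$q_value, mt3$p_value)
  expect_error(module_trait(me$eigengenes,
                            data.frame(flat = rep(1, 10))), "constant")
})

test_that("the driven module usually attains the smallest trait q (truth labels)", {
  sizes <- scaled_sizes_2000()
  hits <- vapply(1:20, function(sd) {
    cfg <- sim_config(n_genes = 2000, module_sizes = sizes, n_per_group = 5,
                      loading_range = c(0.6, 0.95), trait_effect = 2,
                      driven_module_index = 4, seed = sd)
    s <- simulate_expression(cfg)
    labels <- module_colors(13)[s$truth$gene_module]
    me <- module_eigengenes(s$expr, labels)
    mt <- module_trait(me$eigengenes,
                       data.frame(group = as.numeric(s$metadata$group == "feeding")))
    mt$module[which.min(mt$q_value)] == module_colors(13)[4]
  }, logical(1))
  expect_gt(sum(hits), 10)   # majority over 20 simulated studies
})

test_that("network export is deterministic and threshold-faithful", {
  cfg <- sim_config(n_genes = 35, module_sizes = c(20L, 15L), n_per_group = 10,
                    loading_range = c(1, 1), noise_sd = 0, trait_effect = 0,
                    driven_module_index = 1, seed = 51)
  s <- simulate_expression(cfg)
  cd <- correlation_and_distance(s$expr)
  labels <- module_colors(2)[pmax(s$truth$gene_module, 1)]
  labels[s$truth$gene_module == 0] <- "grey"
  me <- module_eigengenes(s$expr, labels)
  K <- kme(s$expr, me$eigengenes)
  nw <- export_network(cd$R, labels, K, edge_min_abs_r = 0.6)
  # zero-noise unit loadings: complete graph within each module
  expect_equal(nrow(nw$edges), choose(20, 2) + choose(15, 2))
  expect_true(all(abs(nw$edges$weight - 1) < 1e-9))
  expect_identical(nrow(nw$nodes), 35L)
  # impossible threshold on noisy data gives no edges
  set.seed(52)
  noisy <- matrix(rnorm(200), 20, 10,
                  dimnames = list(paste0("n", 1:20), NULL))
  cdn <- correlation_and_distance(noisy)
  labn <- rep(c("turquoise", "blue"), each = 10)
  men <- module_eigengenes(noisy, labn)
  nwn <- export_network(cdn$R, labn, kme(noisy, men$eigengenes),
                        edge_min_abs_r = 1.0)
  expect_identical(nrow(nwn$edges), 0L)
  # hand count on a 5-gene fixture
  sub <- s$expr[1:5, ]
  cds <- correlation_and_distance(sub + matrix(rnorm(length(sub), sd = 0.4), nrow(sub)))
  labs <- rep("turquoise", 5)
  mes <- module_eigengenes(sub, labs)
  nws <- export_network(cds$R, labs, kme(sub, mes$eigengenes),
                        edge_min_abs_r = 0.8)
  hand <- sum(abs(cds$R[upper.tri(cds$R)]) >= 0.8)
  expect_identical(nrow(nws$edges), hand)
})
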