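test_that("adjacency obeys the unsigned/signed soft-threshold contracts", {
  R <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(adjacency_from_correlation(R, 2, "unsigned")[1, 2], 0.25)
  Rneg <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(adjacency_from_correlation(Rneg, 3, "signed")[1, 2], 0)
  Rpos <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(adjacency_from_correlation(Rpos, 7, "unsigned")[1, 2], 1)
  bad <- matrix(c(1, 0.2, 0.4, 1), 2, 2)
  expect_error(adjacency_from_correlation(bad, 2), "symmetric")
})

test_that("adjacency and TOM are symmetric in [0,1] with unit diagonal", {
  set.seed(101)
  for (rep in 1:10) {
    R <- random_cor_matrix(sample(5:25, 1))
    A <- adjacency_from_correlation(R, sample(1:8, 1),
                                    sample(c("unsigned", "signed"), 1))
    expect_lt(max(abs(A - t(A))), 1e-12)
    expect_true(all(A >= 0 & A <= 1))
    expect_equal(unname(diag(A)), rep(1, nrow(A)))
    tom <- tom_similarity(A)
    expect_lt(max(abs(tom - t(tom))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  }
})

test_that("TOM matches the triple-loop oracle, including the 3-node fixture", {
  # A12 = A13 = 0.5, A23 = 0: TOM_23 = (0.5 * 0.5 + 0) / (0.5 + 1 - 0)
  A <- diag(3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.5
  tom <- tom_similarity(A)
  expect_equal(tom[2, 3], 0.25 / 1.5)
  expect_equal(tom[2, 3], oracle_tom(A)[2, 3])

  # isolated pair: no edge, no shared neighbors
  A0 <- diag(3); A0[1, 2] <- A0[2, 1] <- 0.9
  expect_equal(tom_similarity(A0)[1, 3], 0)

  set.seed(202)
  for (n in c(5, 12, 20, 30)) {
    A <- adjacency_from_correlation(random_cor_matrix(n), 4, "unsigned")
    expect_lt(max(abs(tom_similarity(A) - oracle_tom(A))), 1e-12)
  }
})

test_that("scale-free fit is 1 for an exact power-law degree sequence", {
  # k = 2^j with multiplicity 2^(10-j): log10 p(k) is exactly linear in
  # log10 k with negative slope, one value per bin
  k <- rep(2^(1:10), times = 2^(10:1))
  expect_equal(holocorr:::.scale_free_fit(k), 1.0, tolerance = 1e-12)
  # reversed frequencies give a positive slope, hence a negative signed fit
  k_up <- rep(2^(1:10), times = 2^(1:10))
  expect_lt(holocorr:::.scale_free_fit(k_up), 0)
})

test_that("power scan picks the first candidate crossing the fit target", {
  set.seed(7)
  sim <- simulate_bundle(recovery_spec(3, n_features = 15, n_background = 10))
  lay <- sim$bundle$layers$host
  params <- network_params(power_grid = 1:8, rsq_target = 0.5)
  scan <- suppressWarnings(soft_threshold_scan(lay, params))
  fit <- scan$fit_table
  hit <- which(fit$scale_free_rsq >= params$rsq_target)
  expected <- if (length(hit)) fit$power[hit[1]] else
    fit$power[which.max(fit$scale_free_rsq)]
  expect_equal(scan$chosen_power, expected)
  # mean connectivity strictly decreases with beta (oracle: direct degrees)
  R <- cor(lay$values)
  k1 <- mean(colSums(abs(R)^1) - 1)
  k2 <- mean(colSums(abs(R)^2) - 1)
  expect_equal(fit$mean_connectivity[fit$power == 1], k1)
  expect_equal(fit$mean_connectivity[fit$power == 2], k2)
  expect_true(all(diff(fit$mean_connectivity) < 0))

  const <- tiny_layer(cbind(matrix(rnorm(20), 10, 2), rep(1, 10)))
  expect_error(suppressWarnings(soft_threshold_scan(const, params)),
               "zero-variance")
})

test_that("static cut recovers perfect blocks and respects min_module_size", {
  block_tom <- function(sizes, within = 1, between = 0) {
    n <- sum(sizes)
    tom <- matrix(between, n, n)
    at <- 0
    for (s in sizes) {
      tom[at + seq_len(s), at + seq_len(s)] <- within
      at <- at + s
    }
    diag(tom) <- 1
    dimnames(tom) <- list(paste0("f", 1:n), paste0("f", 1:n))
    tom
  }
  tom <- block_tom(c(4, 3))
  a <- cut_dendrogram_to_modules(tom, network_params(min_module_size = 2))
  expect_identical(a$labels, c(rep("M1", 4), rep("M2", 3)))

  # one block under min size becomes unassigned
  a2 <- cut_dendrogram_to_modules(tom, network_params(min_module_size = 4))
  expect_identical(a2$labels, c(rep("M1", 4), rep("unassigned", 3)))

  # hand-traced 6-feature average-linkage cut: blocks {1,2,3}, {4,5,6} with
  # within-TOM 0.8 and between-TOM 0.1 merge internally at D = 0.2 and join
  # at D = 0.9; a 0.99 * 0.9 cut separates the two branches
  tom6 <- block_tom(c(3, 3), within = 0.8, between = 0.1)
  a3 <- cut_dendrogram_to_modules(tom6, network_params(min_module_size = 3))
  expect_identical(a3$labels, c(rep("M1", 3), rep("M2", 3)))

  expect_warning(
    cut_dendrogram_to_modules(block_tom(c(2, 2)),
                              network_params(min_module_size = 5)),
    "unassigned")
})

test_that("module eigengene matches an independent principal-component oracle", {
  set.seed(11)
  n <- 30
  # rank-1: all members the same profile
  z <- rnorm(n)
  lay <- tiny_layer(cbind(z, z, z), features = c("a", "b", "c"))
  e <- module_eigengene(lay, c("a", "b", "c"))
  expect_equal(abs(cor(e, z)), 1)
  expect_gt(cor(e, z), 0)          # sign oriented toward the mean profile
  expect_equal(sum(e^2), 1)        # unit norm

  # random 5-member module vs prcomp on the standardized submatrix
  X <- matrix(rnorm(n * 5), n, 5)
  lay2 <- tiny_layer(X)
  e2 <- module_eigengene(lay2, lay2$feature_ids)
  pc1 <- prcomp(X, center = TRUE, scale. = TRUE)$x[, 1]
  expect_equal(abs(cor(e2, pc1)), 1, tolerance = 1e-9)

  # anti-correlated pair: orientation rule still yields a well-defined sign
  lay3 <- tiny_layer(cbind(z, -z), features = c("p", "q"))
  e3 <- module_eigengene(lay3, c("p", "q"))
  expect_equal(abs(cor(e3, z)), 1)

  lay4 <- tiny_layer(cbind(z, rep(2, n)), features = c("p", "flat"))
  expect_error(module_eigengene(lay4, c("p", "flat")), "flat")
})

test_that("modules from one latent factor merge; independent ones do not", {
  set.seed(21)
  n <- 50
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, m) sapply(seq_len(m), function(i) 0.9 * f +
                                sqrt(1 - 0.81) * rnorm(n))
  lay <- tiny_layer(cbind(mk(f1, 10), mk(f1, 10), mk(f2, 10)))
  labels <- c(rep("M1", 10), rep("M2", 10), rep("M3", 10))
  assign0 <- structure(list(feature_ids = lay$feature_ids, labels = labels,
                            unassigned_label = "unassigned", tree = NULL),
                       class = "module_assignment")
  merged <- merge_close_modules(lay, assign0, merge_cut_height = 0.25)
  mods <- unique(merged$labels)
  expect_equal(length(mods), 2L)
  # the two same-factor blocks carry one label, the independent block another
  expect_equal(length(unique(merged$labels[1:20])), 1L)
  expect_false(merged$labels[1] == merged$labels[21])

  # merge_cut_height = 0 demands correlation >= 1: nothing merges
  none <- merge_close_modules(lay, assign0, merge_cut_height = 0)
  expect_equal(length(unique(none$labels)), 3L)
})

test_that("intramodular connectivity equals hand-computed adjacency row sums", {
  # module {f1,f2,f3}, |cor| = 0.9 (1-2), 0.8 (1-3), 0.5 (2-3)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.8
  R[2, 3] <- R[3, 2] <- 0.5
  dimnames(R) <- list(paste0("f", 1:3), paste0("f", 1:3))
  assign1 <- structure(list(feature_ids = paste0("f", 1:3),
                            labels = rep("M1", 3),
                            unassigned_label = "unassigned", tree = NULL),
                       class = "module_assignment")
  A1 <- adjacency_from_correlation(R, 1, "unsigned")
  expect_equal(unname(intramodular_connectivity(A1, assign1)),
               c(1.7, 1.4, 1.3))
  A2 <- adjacency_from_correlation(R, 2, "unsigned")
  expect_equal(unname(intramodular_connectivity(A2, assign1)),
               c(1.45, 1.06, 0.89))

  # size-2 module: both members carry the single edge weight
  assign2 <- structure(list(feature_ids = paste0("f", 1:3),
                            labels = c("M1", "M1", "unassigned"),
                            unassigned_label = "unassigned", tree = NULL),
                       class = "module_assignment")
  A <- diag(3); A[1, 2] <- A[2, 1] <- 0.7
  dimnames(A) <- list(paste0("f", 1:3), paste0("f", 1:3))
  expect_equal(unname(intramodular_connectivity(A, assign2)), c(0.7, 0.7, 0))
})

test_that("hub selection takes the max-k_within member with lexicographic ties", {
  set.seed(5)
  lay <- tiny_layer(matrix(rnorm(30), 10, 3), features = c("f1", "f2", "f3"))
  assign1 <- structure(list(feature_ids = c("f1", "f2", "f3"),
                            labels = rep("M1", 3),
                            unassigned_label = "unassigned", tree = NULL),
                       class = "module_assignment")
  kw <- c(f1 = 1.7, f2 = 1.4, f3 = 1.3)
  th <- top_hub_per_module(lay, assign1, kw)
  expect_identical(unname(th$hubs), "f1")
  expect_identical(th$hub_layer$feature_ids, "f1")
  expect_equal(th$hub_layer$values[, 1], lay$values[, "f1"])
  expect_identical(th$hub_layer$provenance, "hubs")

  kw_tie <- c(f1 = 1.4, f2 = 1.4, f3 = 1.0)
  expect_message(th2 <- top_hub_per_module(lay, assign1, kw_tie), "tie")
  expect_identical(unname(th2$hubs), "f1")
})

test_that("hub k_within dominates its module after full detection", {
  sim <- simulate_bundle(recovery_spec(4))
  det <- detect_modules(sim$bundle$layers$host, planted_params(20))
  a <- det$assignment
  for (m in names(det$hubs)) {
    members <- a$feature_ids[a$labels == m]
    expect_gte(det$k_within[[det$hubs[[m]]]], max(det$k_within[members]))
  }
  expect_equal(length(det$hub_layer$feature_ids), length(det$hubs))
  # eigengenes are unit norm
  expect_equal(unname(colSums(det$eigengenes^2)),
               rep(1, ncol(det$eigengenes)))
})

test_that("detection is deterministic and invariant to feature permutation", {
  sim <- simulate_bundle(recovery_spec(9))
  lay <- sim$bundle$layers$host
  d1 <- detect_modules(lay, planted_params(20))
  d2 <- detect_modules(lay, planted_params(20))
  expect_identical(d1$assignment$labels, d2$assignment$labels)
  expect_identical(d1$hubs, d2$hubs)

  set.seed(31)
  perm <- sample(length(lay$feature_ids))
  lay_p <- omics_layer(lay$values[, perm], layer_id = "host")
  d3 <- detect_modules(lay_p, planted_params(20))
  lab1 <- setNames(d1$assignment$labels, d1$assignment$feature_ids)
  lab3 <- setNames(d3$assignment$labels, d3$assignment$feature_ids)
  expect_equal(adjusted_rand_index(lab1[lay$feature_ids],
                                   lab3[lay$feature_ids]), 1)
  expect_setequal(unname(d1$hubs), unname(d3$hubs))
})

test_that("noiseless planted modules are recovered exactly", {
  spec <- simulation_spec(
    n_samples = 30,
    layers = list(list(layer_id = "host",
                       modules = list(
                         list(module_id = "A", n_features = 10, loading = 1),
                         list(module_id = "B", n_features = 10, loading = 1)),
                       n_background = 0)),
    seed = 2)
  sim <- simulate_bundle(spec)
  det <- detect_modules(sim$bundle$layers$host, planted_params(5))
  rec <- evaluate_recovery(sim$truth, det, "host")
  expect_equal(rec$ari, 1)
})

test_that("user label maps rename modules across all outputs", {
  sim <- simulate_bundle(recovery_spec(12))
  det <- detect_modules(sim$bundle$layers$host, planted_params(20))
  ren <- relabel_modules(det, c(M1 = "carbohydrate"))
  expect_true("carbohydrate" %in% ren$assignment$labels)
  expect_true("carbohydrate" %in% names(ren$hubs))
  expect_true("carbohydrate" %in% colnames(ren$eigengenes))
  expect_error(relabel_modules(det, c(M99 = "x")), "unknown modules")
})
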