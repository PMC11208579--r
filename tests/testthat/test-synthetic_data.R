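test_that("generated phylogenies are ultrametric, reproducible and scaled", {
  t1 <- generate_phylogeny(4, seed = 7)
  t2 <- generate_phylogeny(4, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  tree <- generate_phylogeny(40, seed = 3)
  depths <- ape::node.depth.edgelength(tree)[seq_len(40)]
  expect_lt(diff(range(depths)), 1e-9)           # all tips equidistant

  D <- patristic_matrix(tree)
  expect_gte(max(D), 150)
  expect_lte(max(D), 178 + 1e-9)
})

test_that("range generation produces contiguity, forced overlap and sparsity", {
  tree2 <- generate_phylogeny(4, seed = 5)
  forced <- setNames(rep(210L, 2), tree2$tip.label[1:2])
  rg <- generate_ranges(tree2, grid_dims = c(20, 20), mean_range_cells = 12,
                        seed = 2, seed_cells = forced)
  expect_gt(jaccard_overlap(rg[[1]], rg[[2]]), 0)

  corners <- setNames(c(1L, 400L), tree2$tip.label[1:2])
  rg2 <- generate_ranges(tree2, grid_dims = c(20, 20), mean_range_cells = 5,
                         p_cluster = 0, seed = 2, seed_cells = corners)
  expect_equal(jaccard_overlap(rg2[[1]], rg2[[2]]), 0)

  big <- small_sim()
  M <- build_overlap_matrix(big$ranges)
  off <- M[upper.tri(M)]
  expect_gt(mean(off == 0), 0.5)    # most host pairs never overlap
})

test_that("null generative model hits the base rate; effects are monotone", {
  spec0 <- generative_spec(
    n_hosts = 60, n_mites = 2000, seed = 21,
    true_coefficients = setNames(numeric(18),
                                 names(default_true_coefficients())),
    multihost_base_rate = 0.29)
  tree <- generate_phylogeny(spec0$n_hosts, seed = spec0$seed)
  ranges <- generate_ranges(tree, seed = spec0$seed + 1)
  hosts <- generate_host_traits(tree, ranges, seed = spec0$seed + 2)
  gen <- generate_mites(spec0, hosts, tree, ranges)
  rate <- mean(gen$truth$true_label)
  se <- sqrt(0.29 * 0.71 / 2000)
  expect_lt(abs(rate - 0.29), 3 * se)

  beta_imm <- setNames(numeric(18), names(default_true_coefficients()))
  beta_imm["immunity_contact.secondary"] <- 6
  spec1 <- generative_spec(n_hosts = 60, n_mites = 2000, seed = 22,
                           true_coefficients = beta_imm)
  gen1 <- generate_mites(spec1, hosts, tree, ranges)
  sec <- gen1$mites$immunity_contact == "secondary"
  prim <- gen1$mites$immunity_contact == "primary"
  expect_gt(mean(gen1$truth$true_label[sec]),
            mean(gen1$truth$true_label[prim]))
})

test_that("default spec reproduces the 71:29 single/multi class imbalance", {
  sim <- simulate_dataset(generative_spec(n_hosts = 120, n_mites = 1445,
                                          seed = 31))
  expect_lt(abs(mean(sim$truth$true_label) - 0.286), 0.03)
})

test_that("mismatched coefficient names raise a spec error", {
  beta <- default_true_coefficients()
  names(beta)[1] <- "nonsense"
  spec <- generative_spec(n_hosts = 20, n_mites = 50, seed = 1,
                          true_coefficients = beta)
  tree <- generate_phylogeny(20, seed = 1)
  ranges <- generate_ranges(tree, seed = 2)
  hosts <- generate_host_traits(tree, ranges, seed = 3)
  expect_error(generate_mites(spec, hosts, tree, ranges),
               "true_coefficients")
})

test_that("detection thinning is exact at its limits and pub-correlated", {
  s <- small_sim()
  perfect <- inject_unobserved(s$truth[, 1:5], s$mites,
                               detection_halfsat = 0, seed = 9)
  expect_equal(perfect$truth$observed_hosts, s$truth$true_hosts)
  expect_equal(perfect$truth$observed_label,
               as.integer(s$truth$n_true_hosts > 1))

  blind <- inject_unobserved(s$truth[, 1:5], s$mites,
                             detection_halfsat = 1e9, seed = 9)
  expect_true(all(blind$truth$observed_label == 0))
  expect_true(all(lengths(strsplit(blind$truth$observed_hosts, ";")) == 1))

  big <- simulate_dataset(generative_spec(n_hosts = 100, n_mites = 3000,
                                          seed = 41))
  multi <- big$truth[big$truth$true_label == 1, ]
  pubs <- big$mites$publication_count[match(multi$mite_id,
                                            big$mites$mite_id)]
  lo <- mean(multi$planted_noise[pubs < 5])
  hi <- mean(multi$planted_noise[pubs >= 5])
  expect_gt(lo, hi)   # noise concentrates among poorly studied species
})

test_that("observed host sets are subsets of true sets and non-empty", {
  s <- small_sim()
  true_l <- strsplit(s$truth$true_hosts, ";")
  obs_l <- strsplit(s$truth$observed_hosts, ";")
  expect_true(all(mapply(function(o, t) all(o %in% t), obs_l, true_l)))
  expect_true(all(lengths(obs_l) >= 1))
})

test_that("the whole generator is bit-reproducible in its seed", {
  a <- simulate_dataset(generative_spec(n_hosts = 30, n_mites = 60, seed = 17))
  b <- simulate_dataset(generative_spec(n_hosts = 30, n_mites = 60, seed = 17))
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$ranges, b$ranges)
  expect_identical(a$truth, b$truth)
  expect_identical(a$assoc_observed, b$assoc_observed)
})
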