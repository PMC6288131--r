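test_that("disease signature keeps the top decile by |z| with signs", {
  set.seed(61)
  z <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  sig <- build_disease_signature(z)
  expect_length(sig, 10L)
  expect_setequal(names(sig), names(sort(abs(z), decreasing = TRUE)[1:10]))
  expect_identical(sig, z[names(sig)]) # signs retained
  # lexicographic tie rule
  zt <- setNames(rep(1, 20), sprintf("g%02d", 20:1))
  expect_equal(names(build_disease_signature(zt)),
               sprintf("g%02d", 1:2))
  # the published heritable-gene count yields a 527-gene signature
  z5261 <- setNames(rnorm(5261), sprintf("g%05d", 1:5261))
  expect_length(build_disease_signature(z5261), 527L)
  expect_error(build_disease_signature(numeric(0)), "empty")
})

test_that("cosine connectivity matches hand arithmetic and conventions", {
  sig <- c(a = 1, b = 2, c = -1)
  expect_equal(cosine_connectivity(sig, sig * 3.7), 1)
  expect_equal(cosine_connectivity(sig, -sig), -1)
  prof <- c(a = 0, b = 1, c = 1)
  expect_equal(cosine_connectivity(sig, prof), 1 / (sqrt(6) * sqrt(2)),
               tolerance = 1e-12)
  # scale invariance and sign flip
  set.seed(62)
  p2 <- setNames(rnorm(3), c("a", "b", "c"))
  s0 <- cosine_connectivity(sig, p2)
  expect_equal(cosine_connectivity(sig, 100 * p2), s0)
  expect_equal(cosine_connectivity(sig, -p2), -s0)
  # fewer than two shared genes or zero norm is unscorable
  expect_true(is.na(cosine_connectivity(sig, c(a = 1))))
  expect_true(is.na(cosine_connectivity(sig, c(a = 0, b = 0, c = 0))))
})

test_that("condition collapse keeps the extreme score, ties negative", {
  expect_equal(collapse_conditions(c(0.2, -0.5))$score, -0.5)
  expect_equal(collapse_conditions(c(0.9, -0.3))$score, 0.9)
  tie <- collapse_conditions(c(0.4, -0.4), c("c1", "c2"))
  expect_equal(tie$score, -0.4)
  expect_equal(tie$best_condition, "c2")
  expect_null(collapse_conditions(NA_real_))
})

test_that("perturbagen scoring collapses conditions and ranks drugs", {
  set.seed(63)
  genes <- sprintf("g%02d", 1:30)
  z <- setNames(rnorm(30), genes)
  sig <- build_disease_signature(z, 0.5)
  profiles <- matrix(rnorm(30 * 6), nrow = 30,
                     dimnames = list(genes, paste0("c", 1:6)))
  # drug D1 has a strongly reversing condition c2
  profiles[names(sig), "c2"] <- -z[names(sig)]
  meta <- data.frame(condition_id = paste0("c", 1:6),
                     perturbagen_id = rep(c("D1", "D2", "D3"), each = 2))
  sc <- score_perturbagens(sig, profiles, meta)
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$perturbagen_id[1], "D1") # rank 1 = most negative
  expect_equal(sc[sc$perturbagen_id == "D1", ]$best_condition, "c2")
  expect_equal(sc[sc$perturbagen_id == "D1", ]$score, -1)
  expect_setequal(sc$rank, 1:3)
})

test_that("permutation null pools n_perm x n_drugs scores", {
  set.seed(64)
  genes <- sprintf("g%03d", 1:100)
  z <- setNames(rnorm(100), genes)
  profiles <- matrix(rnorm(100 * 50), nrow = 100,
                     dimnames = list(genes, paste0("d", 1:50)))
  null <- permutation_null(z, profiles, n_perm = 20, seed = 1)
  expect_length(null$pooled_null, 20 * 50)
  expect_equal(null$n_drugs, 50L)
  expect_equal(permutation_null(z, profiles, n_perm = 5, alpha = 0,
                                seed = 1)$threshold,
               min(permutation_null(z, profiles, n_perm = 5, alpha = 0,
                                    seed = 1)$pooled_null))
})

test_that("permutation threshold approaches the analytic null quantile", {
  # independent normal profiles: the null cosine of an m-dimensional
  # normal vector against a fixed signature is distributed as
  # 2 * Beta((m-1)/2, (m-1)/2) - 1, so the alpha threshold should
  # approach that distribution's alpha quantile
  set.seed(65)
  n_genes <- 200
  genes <- sprintf("g%03d", 1:n_genes)
  z <- setNames(rnorm(n_genes), genes)
  profiles <- matrix(rnorm(n_genes * 200), nrow = n_genes,
                     dimnames = list(genes, paste0("d", 1:200)))
  null <- permutation_null(z, profiles, n_perm = 100, seed = 2)
  m <- ceiling(0.1 * n_genes)
  q_exact <- 2 * qbeta(0.05, (m - 1) / 2, (m - 1) / 2) - 1
  expect_lt(abs(null$threshold - q_exact), 0.02)
})

test_that("significant reversers use a strict threshold", {
  sc <- data.table::data.table(
    perturbagen_id = c("D1", "D2", "D3"),
    score = c(-0.5, -0.386, 0.1), best_condition = "c", rank = 1:3)
  expect_equal(significant_reversers(sc, -0.386), "D1")
  expect_length(significant_reversers(sc, -0.9), 0L)
})

test_that("overlap permutation p-value matches the hypergeometric tail", {
  all_drugs <- sprintf("d%03d", 1:100)
  ref <- all_drugs[1:10]
  # full overlap of a 10-drug significant set
  p_full <- set_overlap_permutation_p(ref, ref, all_drugs,
                                      n_iter = 1e5, seed = 3)
  exact_full <- phyper(9, 10, 90, 10, lower.tail = FALSE)
  se <- sqrt(exact_full * (1 - exact_full) / 1e5)
  expect_lt(abs(p_full - exact_full), 3 * se + 2 / 1e5)
  # partial overlap
  sig <- c(all_drugs[6:10], all_drugs[51:55])
  p_part <- set_overlap_permutation_p(sig, ref, all_drugs,
                                      n_iter = 2e4, seed = 4)
  exact <- phyper(4, 10, 90, 10, lower.tail = FALSE)
  se <- sqrt(exact * (1 - exact) / 2e4)
  expect_lt(abs(p_part - exact), 3 * se + 1e-4)
  # degenerate cases
  expect_equal(set_overlap_permutation_p(character(0), ref, all_drugs), 1)
  expect_equal(set_overlap_permutation_p(all_drugs[20:29], all_drugs,
                                         all_drugs, n_iter = 100,
                                         seed = 5), 1)
  expect_equal(set_overlap_permutation_p(all_drugs[20:29], ref[0],
                                         all_drugs, n_iter = 100,
                                         seed = 5), 1)
})

test_that("median rank enrichment detects a planted top drug set", {
  set.seed(66)
  sc <- data.table::data.table(
    perturbagen_id = sprintf("d%04d", 1:1000),
    score = sort(rnorm(1000)), best_condition = "c")
  sc[, rank := rank(score)]
  top <- sc$perturbagen_id[1:20]
  res <- median_rank_enrichment(sc, top, n_iter = 1e4, seed = 6)
  expect_equal(res$median_rank_all, 500.5)
  expect_equal(res$median_rank_set, 10.5) # exact median of 1..20
  expect_equal(res$shift, 490)
  expect_lte(res$p, 1e-4)
  # the full set shifts nothing
  all_res <- median_rank_enrichment(sc, sc$perturbagen_id,
                                    n_iter = 100, seed = 7)
  expect_equal(all_res$shift, 0)
  expect_equal(all_res$p, 1)
  expect_error(median_rank_enrichment(sc, "absent"), "intersect")
})
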