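test_that("variance filter keeps the right number of features, deterministically", {
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("g", 10:1), paste0("s", 1:6)))
  kept <- variance_filter(m, fraction = 0.4, transform = "none")
  expect_identical(nrow(kept), 4L)
  # a constant feature never outranks a varying one
  m2 <- m; m2["g5", ] <- 3
  expect_false("g5" %in% rownames(variance_filter(m2, 0.9, transform = "none")))
  # exact variance ties break lexicographically by feature id
  m3 <- rbind(zz = c(1, 2, 1, 2), aa = c(5, 6, 5, 6), mm = c(0, 0, 0, 0))
  colnames(m3) <- paste0("s", 1:4)
  expect_identical(rownames(variance_filter(m3, fraction = 1/3, transform = "none")), "aa")
})

test_that("TOM matches the hand-evaluated 3-node formula and its invariants", {
  # inject a known adjacency through a matrix whose |cor|^1 equals it
  ms <- simulate_module_structure(n_genes = 30, n_samples = 12, n_modules = 2,
                                  noise_sd = 0.4, seed = 13)
  net <- build_network(ms$expr, beta = 6)
  tom <- net$tom
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  # hand case: a12=0.8, a13=0.6, a23=0.4 -> TOM12 = (0.6*0.4 + 0.8)/1.4.
  # Build three sample profiles with those exact correlations from a
  # mean-zero orthonormal basis, and use beta = 1 so adjacency = |cor|.
  q <- withr::with_seed(1, qr.Q(qr(cbind(1, matrix(rnorm(12 * 3), 12, 3)))))
  e <- q[, 2:4]                     # orthonormal, each orthogonal to 1
  c2 <- (0.4 - 0.8 * 0.6) / 0.6     # solves cor(b, c) = 0.4 given cor(a, c) = 0.6
  m <- rbind(a = e[, 1],
             b = as.numeric(e %*% c(0.8, 0.6, 0)),   # cor(a, b) = 0.8
             c = as.numeric(e %*% c(0.6, c2, sqrt(1 - 0.36 - c2^2))))
  colnames(m) <- paste0("s", 1:12)
  net1 <- build_network(m, beta = 1)
  expect_equal(unname(net1$adjacency[1, 2]), 0.8, tolerance = 1e-9)
  expect_equal(unname(net1$adjacency[1, 3]), 0.6, tolerance = 1e-9)
  expect_equal(unname(net1$adjacency[2, 3]), 0.4, tolerance = 1e-9)
  expect_equal(unname(net1$tom[1, 2]), 1.04 / 1.4, tolerance = 1e-9)
  expect_error(build_network(m[, 1:2]), "3 samples")
})

test_that("soft power selection falls back with a warning when nothing is scale-free", {
  ms <- simulate_module_structure(n_genes = 60, n_samples = 10, n_modules = 2,
                                  noise_sd = 0.2, seed = 15)
  expect_warning(net <- build_network(ms$expr, beta = "auto"), "beta = 6")
  expect_identical(net$beta, 6L)
  expect_identical(build_network(ms$expr, beta = 3)$beta, 3L)
})

test_that("module detection separates planted blocks and ignores noise", {
  ms <- simulate_module_structure(n_genes = 150, n_samples = 20, n_modules = 2,
                                  noise_sd = 0, seed = 2)
  asg <- detect_modules(build_network(ms$expr, beta = 6)$tom, ms$expr)
  expect_identical(max(asg), 2L)
  expect_true(all(table(asg, ms$truth$module) %in% c(0, table(ms$truth$module))))

  noise <- withr::with_seed(3, matrix(rnorm(150 * 20), 150, 20,
                                      dimnames = list(paste0("g", 1:150), NULL)))
  asg_n <- detect_modules(build_network(noise, beta = 6)$tom, noise)
  expect_identical(max(asg_n), 0L)
})

test_that("feature permutation permutes assignments identically", {
  ms <- simulate_module_structure(n_genes = 120, n_samples = 20, n_modules = 2,
                                  noise_sd = 0.4, seed = 17)
  net <- build_network(ms$expr, beta = 6)
  asg <- detect_modules(net$tom, ms$expr)
  perm <- withr::with_seed(5, sample(nrow(ms$expr)))
  expr_p <- ms$expr[perm, ]
  asg_p <- detect_modules(build_network(expr_p, beta = 6)$tom, expr_p)
  expect_identical(asg_p[names(asg)], asg)
})

test_that("a larger merge height never increases the module count", {
  ms <- simulate_module_structure(n_genes = 300, n_samples = 24, n_modules = 3,
                                  noise_sd = 0.5, seed = 9)
  tom <- build_network(ms$expr, beta = 6)$tom
  heights <- c(0.05, 0.25, 0.6, 0.9)
  counts <- vapply(heights, function(h) {
    max(detect_modules(tom, ms$expr, merge_cut_height = h))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("eigengenes equal the brute-force first principal component", {
  ms <- simulate_module_structure(n_genes = 36, n_samples = 15, n_modules = 2,
                                  noise_sd = 0.5, seed = 19)
  asg <- setNames(ms$truth$module, ms$truth$feature_id)
  me <- module_eigengenes(ms$expr, asg)
  for (m in 1:2) {
    x <- ms$expr[names(asg)[asg == m], ]
    xs <- t(scale(t(x)))
    # oracle: full eigendecomposition of the sample-sample covariance
    ev <- eigen(crossprod(xs), symmetric = TRUE)$vectors[, 1]
    ev <- ev / sd(ev)
    if (mean(cor(ev, t(xs))) < 0) ev <- -ev
    expect_equal(unname(me[, paste0("ME", m)]), unname(ev), tolerance = 1e-8)
    # the eigengene explains at least as much variance as any member profile
    var_expl <- function(v) mean(cor(v, t(xs))^2)
    member_best <- max(apply(xs, 1, var_expl))
    expect_gte(var_expl(me[, paste0("ME", m)]) + 1e-12, member_best)
  }
  # single-feature module: the standardized feature itself
  asg1 <- setNames(c(1L, rep(0L, 35)), ms$truth$feature_id)
  me1 <- module_eigengenes(ms$expr, asg1)
  prof <- scale(ms$expr[1, ])[, 1]
  expect_equal(abs(cor(me1[, 1], prof)), 1, tolerance = 1e-12)
  # constant features are named in the error
  expr_bad <- ms$expr; expr_bad[2, ] <- 7
  asg2 <- setNames(c(1L, 1L, rep(0L, 34)), ms$truth$feature_id)
  expect_error(module_eigengenes(expr_bad, asg2), "constant")
})

test_that("module-trait correlation matches cor.test and a permutation oracle", {
  ms <- simulate_module_structure(seed = 7)
  asg <- setNames(ms$truth$module, ms$truth$feature_id)
  me <- module_eigengenes(ms$expr, asg)
  mt <- module_trait(me, ms$trait)
  for (i in seq_len(nrow(mt))) {
    ct <- cor.test(me[, mt$module[i]], ms$trait)
    expect_equal(mt$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mt$p_value[i], ct$p.value, tolerance = 1e-9)
  }
  # permutation oracle for the module-2 eigengene (a mid-strength correlation)
  obs <- abs(cor(me[, "ME2"], ms$trait))
  perm_p <- withr::with_seed(23, {
    mean(replicate(4000, abs(cor(me[, "ME2"], sample(ms$trait)))) >= obs)
  })
  p_pkg <- mt$p_value[mt$module == "ME2"]
  expect_lt(abs(perm_p - p_pkg), 3 * sqrt(p_pkg * (1 - p_pkg) / 4000) + 0.01)
  # degenerate traits are flagged
  expect_warning(mt0 <- module_trait(me[, 1, drop = FALSE],
                                     rep(1, ncol(ms$expr))), "zero variance")
  expect_true(all(is.na(mt0$r)))
  # trait identical to an eigengene
  mt1 <- module_trait(me, me[, "ME1"])
  expect_equal(mt1$r[mt1$module == "ME1"], 1)
  expect_equal(mt1$p_value[mt1$module == "ME1"], 0)
})

test_that("top-edge export keeps the strongest fraction per module", {
  ms <- simulate_module_structure(n_genes = 102, n_samples = 16, n_modules = 1,
                                  noise_sd = 0.5, seed = 29)
  asg <- setNames(rep(1L, 100), ms$truth$feature_id[1:100])
  edges <- top_edges(ms$expr[1:100, ], asg, fraction = 0.01)
  expect_identical(nrow(edges), 50L)  # ceiling(0.01 * 4950)
  # kept minimum |r| >= dropped maximum |r|
  r_all <- cor(t(ms$expr[1:100, ]))
  all_r <- abs(r_all[upper.tri(r_all)])
  expect_gte(min(abs(edges$r)), sort(all_r, decreasing = TRUE)[51])
  # a 2-feature module always keeps its single edge
  asg2 <- setNames(c(1L, 1L), ms$truth$feature_id[101:102])
  expect_identical(nrow(top_edges(ms$expr[101:102, ], asg2, fraction = 0.01)), 1L)
})
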