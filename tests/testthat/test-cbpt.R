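# Node statistic, clustering, mass, and the permutation engine.

test_that("partial Spearman equals the rank-residual regression oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 40
    C <- cbind(rnorm(n), sample(1:5, n, TRUE))   # includes ties
    x <- rnorm(n) + 0.5 * C[, 1]
    y <- rnorm(n) + 0.3 * C[, 2]
    got <- partial_spearman(x, y, C)
    want <- partial_spearman_oracle(x, y, C)
    expect_equal(got$rho, want$rho, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("monotone association survives an irrelevant covariate", {
  set.seed(3)
  x <- rnorm(30)
  y <- 2 * x + 1
  got <- partial_spearman(x, y, rnorm(30))
  expect_gte(got$rho, 0.95)
})

test_that("partialing removes a shared covariate signal", {
  set.seed(5)
  rhos <- replicate(100, {
    cov <- rnorm(100)
    x <- cov + rnorm(100, sd = 0.1)   # x is almost the covariate
    partial_spearman(x, rnorm(100), cov)$rho
  })
  expect_lt(mean(abs(rhos)), 0.1)
  expect_gt(mean(abs(rhos) < 0.2), 0.95)
  # x exactly equal to the covariate: zero rank-residual variance, flagged
  cov <- rnorm(50)
  deg <- partial_spearman(cov, rnorm(50), cov)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho))
  expect_error(partial_spearman(rnorm(20), rnorm(20), cbind(cov[1:20], cov[1:20])),
               "collinear")
})

test_that("independent inputs give uniform p-values", {
  set.seed(9)
  ps <- replicate(1000, partial_spearman(rnorm(100), rnorm(100), rnorm(100))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cluster formation matches a label-propagation component oracle", {
  g <- make_grid(60, 4)
  adj <- build_adjacency(g)
  set.seed(77)
  for (rep in 1:5) {
    p <- runif(60)
    p[sample(60, 20)] <- runif(20, 0, 1e-4)
    rho <- runif(60, -1, 1) * 0.8
    cl <- form_clusters(rho, p, adj, alpha_node = 0.001, min_size = 1)
    # rebuild with the oracle
    want <- list()
    sig <- which(p < 0.001)
    for (sgn in c(1, -1)) {
      for (comp in components_oracle(sig[sign(rho[sig]) == sgn], adj))
        want[[length(want) + 1L]] <- list(nodes = comp, sign = sgn)
    }
    key <- function(l) sort(vapply(l, function(cc)
      paste(cc$sign, paste(cc$nodes, collapse = ",")), character(1)))
    expect_identical(key(cl), key(want))
    for (cc in cl) {
      expect_true(all(sign(rho[cc$nodes]) == cc$sign))
      expect_equal(cc$mass, sum(atanh(rho[cc$nodes])))
      expect_identical(sign(cc$mass), cc$sign)
    }
  }
})

test_that("a 15-node blob survives and an 11-node blob dies on the 1202 grid", {
  g <- make_grid(1202, 78)
  adj <- build_adjacency(g)
  rho <- rep(0, 1202)
  p <- rep(0.5, 1202)
  p[1:11] <- 1e-6
  rho[1:11] <- -0.5
  expect_length(form_clusters(rho, p, adj), 0)   # min_size defaults to 12
  p[1:15] <- 1e-6
  rho[1:15] <- -0.5
  out <- form_clusters(rho, p, adj)
  expect_length(out, 1)
  expect_length(out[[1]]$nodes, 15)
  # nothing significant at all -> empty
  expect_length(form_clusters(rho, rep(0.5, 1202), adj), 0)
})

test_that("cluster mass is the Fisher-Z sum", {
  expect_identical(cluster_mass(rep(0, 5)), 0)
  expect_equal(cluster_mass(0.5), atanh(0.5))
  expect_equal(cluster_mass(c(0.3, -0.3)), 0)
  expect_error(cluster_mass(c(0.5, 1)), "Fisher")
})

test_that("CBPT detects a planted negative cluster with the right members", {
  cfg <- sim_config(n_nodes = 48, n_regions = 6, n_epochs = 1, noise_sd = 4,
                    group_sizes = c(CI = 70, MCI = 30),
                    recall_intercepts = c(CI = 50, MCI = 50),
                    cluster_nodes = 10:24, seed = 55)
  grid <- make_grid(48, 6)
  ch <- simulate_cohort(cfg, grid)
  cb <- cbpt_run(ch$strength, ch$cohort$delayed_recall,
                 covariates = ch$cohort$age, grid = grid,
                 n_perm = 300, seed = 19)
  sig <- significant_clusters(cb)
  expect_gte(length(sig), 1)
  expect_equal(sig[[1]]$sign, -1)
  expect_gte(jaccard(sig[[1]]$nodes, 10:24), 0.5)
  # markers equal brute-force column means; p in the attainable range
  for (cl in cb$clusters) {
    expect_equal(cl$marker,
                 rowMeans(ch$strength[, cl$nodes, drop = FALSE]),
                 tolerance = 1e-14)
    expect_gte(cl$p_perm, 1 / (cb$n_perm + 1))
    expect_lte(cl$p_perm, 1)
  }
})

test_that("constant behaviour yields no clusters", {
  set.seed(2)
  g <- make_grid(30, 3)
  S <- matrix(rnorm(20 * 30), 20, 30)
  cb <- cbpt_run(S, rep(5, 20), grid = g, n_perm = 100, seed = 1)
  expect_length(cb$clusters, 0)
})

test_that("detection rate does not decrease with planted effect size", {
  grid <- make_grid(27, 3)
  adj <- build_adjacency(grid)
  rate <- vapply(c(-5, -25, -50), function(beta) {
    hits <- 0
    for (r in 1:6) {
      cfg <- sim_config(n_nodes = 27, n_regions = 3, n_epochs = 1,
                        cluster_nodes = 1:8, effect_beta = beta,
                        noise_sd = 4, group_sizes = c(CI = 40, MCI = 20),
                        recall_intercepts = c(CI = 50, MCI = 50),
                        seed = 100 + r)
      ch <- simulate_cohort(cfg, grid)
      cb <- cbpt_run(ch$strength, ch$cohort$delayed_recall,
                     covariates = ch$cohort$age, adjacency = adj,
                     n_perm = 100, seed = r, min_size = 3)
      if (length(significant_clusters(cb))) hits <- hits + 1
    }
    hits / 6
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("exhaustive enumeration at n = 6 matches Monte-Carlo p-values", {
  set.seed(41)
  n <- 6
  g <- make_grid(12, 2)
  x <- rnorm(n)
  S <- outer(x, rnorm(12, sd = 0.2)) + matrix(rnorm(n * 12, sd = 0.5), n)
  y <- x + rnorm(n, sd = 0.4)
  expect_warning(
    ex <- cbpt_run(S, y, grid = g, n_perm = 5000, seed = 1, alpha_node = 0.05,
                   min_size = 2),
    "enumerating"
  )
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 720)
  mc <- cbpt_run(S, y, grid = g, n_perm = 600, seed = 2, alpha_node = 0.05,
                 min_size = 2)
  expect_gt(length(ex$clusters), 0)
  for (k in seq_along(ex$clusters)) {
    pe <- ex$clusters[[k]]$p_perm
    pm <- mc$clusters[[k]]$p_perm
    se <- sqrt(pe * (1 - pe) / 600)
    expect_lt(abs(pe - pm), 3 * se + 1 / 600)
  }
})

test_that("the Freedman-Lane scheme is available and calibrated in range", {
  set.seed(12)
  g <- make_grid(30, 3)
  S <- matrix(rnorm(40 * 30), 40, 30)
  cb <- cbpt_run(S, rnorm(40), covariates = rnorm(40), grid = g,
                 n_perm = 200, seed = 3, perm_scheme = "freedman_lane")
  expect_s3_class(cb, "cbpt")
  expect_identical(cb$perm_scheme, "freedman_lane")
})
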