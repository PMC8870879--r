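test_that("relevance step separates planted structure from noise", {
  tab <- generate_feature_table(2000, 3, 2, 0, 10, seed = 1)
  roles <- attr(tab, "planted_roles")
  s1 <- fc_step1_relevance(tab, "y")
  relevant <- names(roles)[startsWith(roles, "relevant")]
  expect_true(all(relevant %in% s1$s1))
  expect_false(any(names(roles)[roles == "noise"] %in% s1$s1))
  # a feature identical to the target ranks first with SU = 1
  tab2 <- tab
  tab2$X1 <- tab2$y
  s2 <- fc_step1_relevance(tab2, "y")
  expect_identical(s2$su_ranking$feature[1], "X1")
  expect_equal(s2$su_ranking$su[1], 1.0)
  # fixed threshold semantics: delta = 0 keeps everything
  s3 <- fc_step1_relevance(tab, "y", selection_config(relevance_threshold = 0))
  expect_setequal(s3$s1, setdiff(names(tab), "y"))
})

test_that("all-noise tables yield an empty relevant set", {
  empty <- vapply(1:40, function(s) {
    tab <- generate_feature_table(500, 0, 0, 0, 15, seed = s + 300)
    suppressWarnings(length(fc_step1_relevance(tab, "y")$s1) == 0)
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("redundancy step removes exact duplicates deterministically", {
  set.seed(2)
  n <- 1000
  x <- runif(n, -1, 1)
  d <- tibble::tibble(f1 = x, f2 = x, f3 = runif(n, -1, 1),
                      y = x + 0.5 * runif(n, -1, 1))
  s2 <- fc_step2_redundancy(d, "y")
  expect_length(intersect(c("f1", "f2"), s2$s_prime), 1)
  expect_true(nrow(s2$audit) >= 1)
  # audit log reconstructs the removal: removed feature displaced by a kept one
  expect_true(all(s2$audit$displaced_by %in% s2$s_prime |
                    s2$audit$displaced_by %in% s2$audit$removed == FALSE))
})

test_that("a p too large to trigger the test leaves S1 untouched", {
  tab <- generate_feature_table(1000, 3, 0, 0, 3, seed = 3)
  cfg <- selection_config(p_start = 50, p_step = 0.1, p_floor = 49.5)
  s1 <- fc_step1_relevance(tab, "y", cfg)
  s2 <- fc_step2_redundancy(tab, "y", cfg, step1 = s1)
  expect_setequal(s2$s_prime, s1$s1)
})

test_that("S-prime recovers the planted originals and is ordered within S1", {
  hits <- vapply(1:20, function(s) {
    tab <- generate_feature_table(2000, 3, 2, 5, 10, seed = s)
    roles <- attr(tab, "planted_roles")
    s2 <- fc_step2_redundancy(tab, "y")
    expect_true(all(s2$s_prime %in% fc_step1_relevance(tab, "y")$s1))
    setequal(s2$s_prime, names(roles)[startsWith(roles, "relevant")])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ReliefF diff follows its closed forms", {
  expect_equal(relieff_diff(2, 5, "numeric", range = c(0, 10)), 0.3)
  expect_equal(relieff_diff(1, 1, "nominal"), 0)
  expect_equal(relieff_diff(1, 2, "nominal"), 1)
  expect_equal(relieff_diff(0, 10, "numeric", range = c(0, 10)), 1.0)
  expect_warning(z <- relieff_diff(3, 3, "numeric", range = c(2, 2)), "range")
  expect_equal(z, 0)
})

test_that("ReliefF ranks an interacting pair above noise and nulls stay small", {
  hits <- vapply(1:5, function(s) {
    d <- xor_table(n = 2000, n_noise = 10, seed = s)
    w <- relieff_weights(d, "y", seed = s)
    min(w$weight[w$feature %in% c("x1", "x2")]) >
      max(w$weight[!w$feature %in% c("x1", "x2")])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # pure-noise features have near-zero weights
  set.seed(11)
  noise_tab <- generate_feature_table(2000, 0, 0, 0, 6, seed = 11)
  w0 <- relieff_weights(noise_tab, "y", seed = 11)
  expect_true(all(abs(w0$weight) < 0.05))
})

test_that("a perfect class indicator dominates ReliefF weights", {
  set.seed(12)
  n <- 600
  y <- runif(n)
  d <- tibble::tibble(ind = as.numeric(discretize(y, 5)$labels) / 5,
                      a = runif(n), b = runif(n), y = y)
  w <- relieff_weights(d, "y", selection_config(target_bins = 5), seed = 12)
  expect_identical(w$feature[1], "ind")
})

test_that("rank fusion averages positions with documented tie-breaks", {
  fused <- fuse_rankings(c("a", "b", "c"), c("a", "b", "c"), top_k = 3)
  expect_identical(fused$feature, c("a", "b", "c"))
  f2 <- fuse_rankings(c("a", "b", "c"), c("c", "b", "a"), top_k = 3)
  expect_true(all(f2$mean_rank == 2))
  expect_identical(f2$feature, c("a", "b", "c")) # ties broken by FC rank
  f3 <- fuse_rankings(c("a", "b"), c("b", "c"), top_k = 3)
  expect_equal(f3$mean_rank[f3$feature == "b"], 1.5)
  expect_warning(f4 <- fuse_rankings(c("a"), c("a"), top_k = 5), "top_k")
  expect_equal(nrow(f4), 1)
})

test_that("Pearson baseline prefers linear over symmetric nonlinear features", {
  set.seed(13)
  n <- 2000
  x_lin <- runif(n, -1, 1); x_quad <- runif(n, -1, 1)
  d <- tibble::tibble(lin = x_lin, quad = x_quad,
                      y = 2 * x_lin + 2 * (x_quad^2 - mean(x_quad^2)) +
                        rnorm(n, 0, 0.2))
  pb <- pearson_baseline_rank(d, "y")
  expect_lt(which(pb$feature == "lin"), which(pb$feature == "quad"))
  expect_identical(pb$feature[nrow(pb)], "quad")
  dd <- d; dd$dup <- dd$lin
  pb2 <- pearson_baseline_rank(dd, "y")
  expect_lte(abs(which(pb2$feature == "dup") - which(pb2$feature == "lin")), 1)
  dc <- d; dc$flat <- 1
  pb3 <- pearson_baseline_rank(dc, "y")
  expect_identical(pb3$feature[nrow(pb3)], "flat")
  expect_identical(pb3$flag[nrow(pb3)], "constant")
})

test_that("full selector output is internally consistent and permutation-stable", {
  tab <- generate_feature_table(1500, 3, 1, 2, 6, seed = 14)
  sel <- select_features(tab, "y", seed = 14)
  expect_true(all(sel$s_prime %in% sel$s1))
  expect_lte(nrow(sel$fused), sel$config$top_k)
  td <- tidy(sel)
  expect_true(all(c("su", "relieff_weight", "in_s_prime") %in% names(td)))
  # permuting feature columns leaves the selected sets unchanged
  perm <- c(sample(setdiff(names(tab), "y")), "y")
  sel2 <- select_features(tab[perm], "y", seed = 14)
  expect_setequal(sel2$s_prime, sel$s_prime)
  expect_setequal(sel2$fused$feature, sel$fused$feature)
})
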