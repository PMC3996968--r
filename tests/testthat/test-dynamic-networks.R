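test_that("activity thresholds match hand arithmetic in both forms", {
  # zero-variance gene: both forms reduce to the mean
  ex0 <- make_expr(list(matrix(2, 4, 1)))
  for (f in c("range_consistent", "eq1_literal")) {
    m <- compute_activity_scores(ex0, alpha = 1.5, form = f)
    expect_equal(m$ac_score, 2)
  }

  # two values 1 +/- 1/sqrt(2): mu = 1, sample sd = 1 exactly
  ex1 <- make_expr(list(c(1 - 1 / sqrt(2), 1 + 1 / sqrt(2))))
  m_rc <- compute_activity_scores(ex1, alpha = 1.5, form = "range_consistent")
  expect_equal(m_rc$mu, 1)
  expect_equal(m_rc$sigma, 1)
  # mu + alpha * sigma^3 / (1 + sigma^2) = 1 + 1.5 * 1/2
  expect_equal(m_rc$ac_score, 1.75)

  m_lit <- compute_activity_scores(ex1, form = "eq1_literal")
  # F = 1/(1+1) = 0.5; thr1 = 1, thr2 = mu*sigma = 1 -> 0.5 + 0.5
  expect_equal(m_lit$f, 0.5)
  expect_equal(m_lit$ac_score, 1.0)

  expect_error(compute_activity_scores(ex1, alpha = 0), "positive")
  expect_error(compute_activity_scores(ex1, alpha = -1), "positive")
})

test_that("pooling a reference series shifts mean and sd to the pooled values", {
  ex <- make_expr(list(c(1, 2, 3)), ids = "G01")
  ref <- make_expr(list(c(5, 6, 7)), ids = "G01")
  m <- compute_activity_scores(ex, form = "range_consistent", reference = ref)
  expect_equal(m$mu, mean(c(1:3, 5:7)))
  expect_equal(m$sigma, sd(c(1:3, 5:7)))
  ref2 <- make_expr(list(c(5, 6, 7)), ids = "ZZZ")
  expect_error(compute_activity_scores(ex, reference = ref2), "no genes")
})

test_that("activity binarization is an inclusive threshold on replicate means", {
  ex <- make_expr(list(c(3, 0), c(1, 0)))  # 2 genes x 2 timepoints
  model <- compute_activity_scores(ex)
  model$ac_score <- c(2, 2)
  expect_equal(unname(binarize_activity(ex, model, 1)), c(1L, 0L))
  # exact equality counts as active
  model$ac_score <- c(3, 1)
  expect_equal(unname(binarize_activity(ex, model, 1)), c(1L, 1L))
  # all below -> zero vector
  model$ac_score <- c(10, 10)
  expect_equal(sum(binarize_activity(ex, model, 1)), 0L)
  expect_error(binarize_activity(ex, model, 3), "out of range")
})

test_that("activity network is the rank-one outer product", {
  a <- activity_network(c(1, 0, 1))
  expect_equal(a, rbind(c(1, 0, 1), c(0, 0, 0), c(1, 0, 1)))
  expect_equal(activity_network(c(0, 0)), matrix(0, 2, 2))
  expect_equal(activity_network(c(1, 1)), matrix(1, 2, 2))
  expect_error(activity_network(c(0.5, 1)), "binary")
  # idempotence up to the active count: Act^2 = sum(delta) * Act
  delta <- c(1, 1, 0, 1)
  act <- activity_network(delta)
  expect_equal(act %*% act, sum(delta) * act)
})

test_that("windowed co-expression reproduces hand-computed Pearson values", {
  # T = 3, one replicate; window at t = 2 covers all three timepoints
  ex <- make_expr(list(c(1, 2, 3), c(1, 2, 4), c(3, 2, 1), c(1, 2, 3)))
  coe <- windowed_coexpression(ex, 2)
  r <- 0.981980506061966  # cor((1,2,3), (1,2,4))
  expect_equal(coe["G01", "G02"], (r + 1) / 2, tolerance = 1e-12)
  expect_equal(coe["G01", "G04"], 1.0)   # identical profiles
  expect_equal(coe["G01", "G03"], 0.0)   # exact anticorrelation
  expect_equal(coe["G01", "G01"], 1.0)   # non-constant diagonal
  expect_true(all(coe >= 0 & coe <= 1))
  expect_equal(coe, t(coe))
})

test_that("constant genes get co-expression 0.5 by convention", {
  ex <- make_expr(list(c(1, 2, 3), c(5, 5, 5)))
  coe <- windowed_coexpression(ex, 2)
  expect_equal(coe["G01", "G02"], 0.5)
  expect_equal(coe["G02", "G02"], 0.5)
})

test_that("combining masks by activity and static interactome", {
  ppi <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  act <- activity_network(c(1, 1, 0))
  coe <- matrix(0.5, 3, 3); diag(coe) <- 1
  a <- combine_networks(coe, act, ppi)
  expect_equal(a[1, 2], 0.5)       # surviving edge keeps CoE weight
  expect_equal(a[2, 3], 0)         # inactive endpoint kills the edge
  expect_equal(a, t(a))
  expect_equal(combine_networks(coe, act, matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_error(combine_networks(coe, act, ppi[1:2, 1:2]), "shapes differ")
  bad <- ppi; bad[1, 1] <- 1
  expect_error(combine_networks(coe, act, bad), "zero-diagonal")
})

test_that("higher-order adjacency squares the matrix and zeroes the diagonal", {
  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))  # path graph 1-2-3
  h <- higher_order(path, order = 2, rescale = "none")
  expect_equal(h[1, 3], 1)          # two-step path through node 2
  expect_equal(diag(h), rep(0, 3))
  hm <- higher_order(path, order = 2, rescale = "max")
  expect_equal(max(hm), 1)
  expect_equal(higher_order(matrix(0, 3, 3), 5), matrix(0, 3, 3))
  a <- make_series(4, 1, seed = 2)$matrices[[1]]
  expect_equal(higher_order(a, order = 1, rescale = "none"), a)  # diag already 0
  expect_error(higher_order(path, order = 0), ">= 1")
})

test_that("series construction satisfies its structural invariants", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 20, n_timepoints = 6,
                                        n_critical = 2, seed = 11))
  s <- build_series(ds$expr, ds$ppin)
  expect_s3_class(s, "network_series")
  expect_equal(length(s$matrices), 6L)
  n <- length(s$protein_ids)  # proteins isolated in the scaffold drop out
  expect_gte(n, 15L)
  ppi <- adjacency_matrix(ds$ppin, s$protein_ids)
  raw <- attr(s, "raw")
  for (t in 1:6) {
    m <- s$matrices[[t]]
    expect_equal(m, t(m))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(diag(m), setNames(rep(0, n), s$protein_ids))
    # mask conservation holds before the higher-order transform
    expect_true(all(raw$matrices[[t]][ppi == 0] == 0))
  }
  log <- attr(s, "log")
  expect_equal(nrow(log), 6L)
  expect_true(all(log$active >= 0 & log$active <= n))
})

test_that("disjoint expression and interactome is an error", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 10, seed = 1))
  other <- make_expr(list(c(1, 2), c(3, 4)), ids = c("X1", "X2"))
  expect_error(build_series(other, ds$ppin), "empty protein intersection")
})

test_that("always-active, perfectly co-expressed genes recover rescaled Ppi^2", {
  # identical small fluctuations around a shared baseline, zero replicate
  # mean deviation at every timepoint: g_t = mu for all t, and the
  # eq1_literal threshold sits below mu when sigma < 1, so every protein is
  # active everywhere and all pairwise correlations are exactly 1
  t_n <- 4; reps <- 2; n <- 5
  e <- matrix(c(0.1, -0.1, 0.2, -0.2, 0.15, -0.15, 0.05, -0.05),
              t_n, reps, byrow = TRUE)
  ex <- make_expr(rep(list(5 + e), n))
  set.seed(21)
  edges <- generate_static_ppin(synthetic_spec(n_proteins = n, n_critical = 0, seed = 3))
  # rename the synthetic proteins to the expression ids
  edges2 <- edge_list(sub("P0*", "G0", edges[, 1]), sub("P0*", "G0", edges[, 2]))
  s <- build_series(ex, edges2, form = "eq1_literal")
  ppi <- adjacency_matrix(edges2, s$protein_ids)
  expect_equal(unname(s$matrices[[2]]),
               unname(higher_order(ppi, 2, "max")), tolerance = 1e-12)
})

test_that("raising alpha never increases the active-protein count", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 30, n_timepoints = 6,
                                        seed = 4))
  counts <- sapply(c(0.5, 1, 1.5, 2, 3), function(a) {
    s <- build_series(ds$expr, ds$ppin, alpha = a)
    sum(attr(s, "log")$active)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("circular window equals building on a cyclically shifted series", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 15, n_timepoints = 5,
                                        n_critical = 0, seed = 8))
  ex <- ds$expr
  # shift the time axis by one: timepoint t of the shifted series is t+1
  shifted <- ex
  shifted$values <- ex$values[, c(2:5, 1), , drop = FALSE]
  coe1 <- windowed_coexpression(ex, 1)
  coe2 <- windowed_coexpression(shifted, 5)
  expect_equal(coe1, coe2, tolerance = 1e-12)
})
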