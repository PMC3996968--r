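test_that("energy matches direct arithmetic", {
  p <- structure(list(w = matrix(0, 2, 3), b = numeric(3), d = numeric(2)),
                 class = "rbm_params")
  expect_equal(rbm_energy(p, c(1, 0, 1), c(1, 1)), 0)

  p1 <- structure(list(w = matrix(1, 1, 1), b = 0, d = 0),
                  class = "rbm_params")
  expect_equal(rbm_energy(p1, 1, 1), 1)

  p2 <- make_rbm(3, 2, seed = 4)
  v <- c(1, 0, 1); h <- c(0, 1)
  expect_equal(rbm_energy(p2, v, h), oracle_energy(p2$w, p2$b, p2$d, v, h))
})

test_that("conditional activations are sigmoids of the net input", {
  p <- structure(list(w = matrix(0, 2, 3), b = numeric(3), d = numeric(2)),
                 class = "rbm_params")
  expect_equal(prob_h_given_v(p, c(1, 1, 0)), c(0.5, 0.5))
  expect_equal(prob_v_given_h(p, c(1, 0)), c(0.5, 0.5, 0.5))
  # saturation
  p$d <- c(30, -30)
  ph <- prob_h_given_v(p, c(0, 0, 0))
  expect_equal(ph[1], 1, tolerance = 1e-9)
  expect_equal(ph[2], 0, tolerance = 1e-9)
})

test_that("conditionals match exact enumeration of the joint", {
  p <- make_rbm(3, 2, seed = 12)
  joint <- oracle_joint(p$w, p$b, p$d)
  for (v in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_equal(prob_h_given_v(p, v), oracle_cond_h(joint, v),
                 tolerance = 1e-10)
  }
  for (h in list(c(0, 0), c(1, 0), c(1, 1))) {
    expect_equal(prob_v_given_h(p, h), oracle_cond_v(joint, h),
                 tolerance = 1e-10)
  }
  # matrix form agrees with the vector form
  vs <- rbind(c(1, 0, 0), c(0, 1, 1))
  expect_equal(prob_h_given_v(p, vs)[2, ], prob_h_given_v(p, c(0, 1, 1)))
})

test_that("hidden units are conditionally independent given the visibles", {
  p <- make_rbm(2, 3, seed = 31)
  joint <- oracle_joint(p$w, p$b, p$d)
  v <- c(1, 0)
  marg <- oracle_cond_h(joint, v)
  # joint conditional of each full h state = product of its marginals
  vi <- which(vapply(joint$vs, function(x) all(x == v), logical(1)))
  pv <- joint$p[vi, ] / sum(joint$p[vi, ])
  for (j in seq_along(joint$hs)) {
    h <- joint$hs[[j]]
    expect_equal(pv[j], prod(ifelse(h == 1, marg, 1 - marg)),
                 tolerance = 1e-10)
  }
})

test_that("a CD update is reproducible and a zero rate is a no-op", {
  p <- make_rbm(4, 3, seed = 2)
  batch <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  cfg <- train_config(learning_rate = 0)
  set.seed(5)
  expect_equal(cd_update(p, batch, cfg), p)

  cfg$learning_rate <- 0.1
  set.seed(5); u1 <- cd_update(p, batch, cfg)
  set.seed(5); u2 <- cd_update(p, batch, cfg)
  expect_identical(u1, u2)
  expect_error(cd_update(p, batch * 2, cfg), "\\[0,1\\]")
})

test_that("a CD-1 step matches a scripted replay of the Gibbs chain", {
  # 2 visible, 1 hidden; replay the implementation's documented draw order:
  # one runif per hidden unit to sample h, then a mean-field final visible
  p <- structure(list(w = matrix(c(0.5, -0.3), 1, 2), b = c(0.1, -0.2),
                      d = 0.2), class = "rbm_params")
  v <- c(1, 0)
  cfg <- train_config(cd_k = 1, learning_rate = 0.3)
  set.seed(99)
  upd <- cd_update(p, matrix(v, 1), cfg)

  set.seed(99)
  sig <- function(x) 1 / (1 + exp(-x))
  ph0 <- sig(p$d + sum(p$w[1, ] * v))
  hs <- as.numeric(runif(1) < ph0)
  pv <- sig(p$b + p$w[1, ] * hs)        # mean-field last visible step
  phk <- sig(p$d + sum(p$w[1, ] * pv))
  expect_equal(upd$w[1, ], p$w[1, ] + 0.3 * (ph0 * v - phk * pv))
  expect_equal(upd$b, p$b + 0.3 * (v - pv))
  expect_equal(upd$d, p$d + 0.3 * (ph0 - phk))
})

test_that("training reduces reconstruction error and raises likelihood", {
  pattern <- c(1, 0, 1, 1, 0, 0)
  data <- matrix(pattern, 100, 6, byrow = TRUE)
  cfg <- train_config(epochs = 200, seed = 17)
  set.seed(17)
  init <- rbm_params(6, 4, cfg$init_scale)
  trained <- rbm_train(data, 4, cfg)
  errs <- attr(trained, "recon_error")
  expect_lt(errs[200], 0.5 * reconstruction_rmse(init, data))
  expect_gt(exact_log_likelihood(trained, data),
            exact_log_likelihood(init, data))
})

test_that("zero epochs returns the initial parameters", {
  p <- make_rbm(3, 2, seed = 1)
  out <- rbm_train(matrix(c(1, 0, 1), 1), 2,
                   train_config(epochs = 0, seed = 3), params_init = p)
  expect_equal(out$w, p$w)
  expect_equal(attr(out, "recon_error"), numeric(0))
})

test_that("training is bit-identical under a fixed seed", {
  data <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 0))
  cfg <- train_config(epochs = 15, seed = 42)
  t1 <- rbm_train(data, 2, cfg)
  t2 <- rbm_train(data, 2, cfg)
  expect_identical(t1$w, t2$w)
  expect_identical(t1$b, t2$b)
  expect_identical(t1$d, t2$d)
})

test_that("exact likelihood machinery normalizes and matches hand-computed Z", {
  # zero parameters: uniform over 2^2 visible states
  p0 <- structure(list(w = matrix(0, 1, 2), b = numeric(2), d = 0),
                  class = "rbm_params")
  expect_equal(as.numeric(exact_log_likelihood(p0, c(1, 0))), log(1 / 4),
               tolerance = 1e-12)

  # single visible, single hidden: Z = 1 + e^b + e^d + e^(w+b+d)
  w <- 0.5; b <- -0.2; d <- 0.3
  p1 <- structure(list(w = matrix(w, 1, 1), b = b, d = d),
                  class = "rbm_params")
  z <- 1 + exp(b) + exp(d) + exp(w + b + d)
  expect_equal(as.numeric(exact_log_likelihood(p1, matrix(1))),
               log((exp(b) + exp(w + b + d)) / z), tolerance = 1e-12)
  expect_equal(attr(exact_log_likelihood(p1, matrix(1)), "log_z"), log(z),
               tolerance = 1e-12)

  # P(v) sums to one over all visible states
  p <- make_rbm(3, 2, seed = 77)
  vs <- as.matrix(expand.grid(rep(list(c(0, 1)), 3)))
  pv <- vapply(seq_len(nrow(vs)), function(i)
    exp(as.numeric(exact_log_likelihood(p, vs[i, , drop = FALSE]))),
    numeric(1))
  expect_equal(sum(pv), 1, tolerance = 1e-10)
  expect_error(exact_log_likelihood(make_rbm(15, 10), c(1)), "infeasible")
})

test_that("training on a point mass raises that point's exact likelihood", {
  for (s in 1:3) {
    data <- matrix(c(1, 1, 0, 0), 20, 4, byrow = TRUE)
    cfg <- train_config(epochs = 60, seed = s)
    set.seed(s)
    init <- rbm_params(4, 3, cfg$init_scale)
    trained <- rbm_train(data, 3, cfg)
    expect_gt(exact_log_likelihood(trained, data[1, , drop = FALSE]),
              exact_log_likelihood(init, data[1, , drop = FALSE]))
  }
})
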