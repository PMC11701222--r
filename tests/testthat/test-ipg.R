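test_that("initialisation builds one-vs-rest prompt sets", {
  seeds <- data.frame(row = rep(1:5, 3), col = rep(1:3, each = 5),
                      category = rep(1:3, each = 5))
  class(seeds) <- c("seed_labels", "data.frame")
  st <- ipg_initialize(seeds, D = 6)
  for (i in 1:3) {
    p <- st$prompts[[i]]
    expect_equal(sum(p$polarity == "foreground"), 5L)
    expect_equal(sum(p$polarity == "background"), 10L)
    fg <- p[p$polarity == "foreground", ]
    expect_true(all(fg$col == i))
  }
  expect_equal(nrow(st$ledger), 0L)
  expect_identical(unclass(st$projection), diag(6))

  one <- seeds[seeds$category == 1L, ]
  expect_error(ipg_initialize(one, 6), "K >= 2")
  dup <- seeds
  dup$row[6] <- dup$row[1]; dup$col[6] <- dup$col[1]
  expect_error(ipg_initialize(dup, 6), "more than one category")
})

test_that("the zero-noise loop emits only correct labels and is deterministic", {
  sc <- tiny_scene(seed = 2, noise_sd = 0)
  seg <- tiny_backend(sc, flip_rate = 0)
  seeds <- sample_seed_labels(sc$truth, per_class = 3, seed = 2)
  cfg <- ipg_config(iterations = 6, seed = 2)
  fit <- ipg(sc$cube, seeds, seg, cfg)
  fit2 <- ipg(sc$cube, seeds, seg, cfg)
  expect_identical(fit$ledger, fit2$ledger)
  # one pseudo-label per class per iteration on a clean separable scene
  expect_equal(nrow(fit$ledger), 6L * 3L)
  expect_equal(pseudo_precision(fit, sc$truth), 1)
  # the voted map agrees with truth wherever assigned
  assigned <- fit$voted$labels > 0L
  expect_true(all(unclass(fit$voted$labels)[assigned] == unclass(sc$truth)[assigned]))
})

test_that("ledger entries always satisfied the gate and stay disjoint", {
  sc <- tiny_scene(seed = 14, noise_sd = 0.04, H = 32, W = 32, C = 12)
  seg <- tiny_backend(sc, flip_rate = 0.15)
  seeds <- sample_seed_labels(sc$truth, per_class = 5, seed = 14)
  cfg <- ipg_config(iterations = 10, seed = 14)
  fit <- ipg(sc$cube, seeds, seg, cfg)
  thr <- cfg$thresholds
  expect_true(all(fit$ledger$p >= thr$tau_h))
  expect_true(all(fit$ledger$u <= thr$kappa_h))
  # no pixel holds two categories; pseudo pixels disjoint from seeds
  expect_false(anyDuplicated(paste(fit$ledger$row, fit$ledger$col)) > 0)
  expect_false(any(paste(fit$ledger$row, fit$ledger$col) %in%
                     paste(seeds$row, seeds$col)))
  # bound: at most selections_per_class per category per iteration
  expect_lte(nrow(fit$ledger), 10L * 3L)
  per_iter <- table(fit$ledger$iteration, fit$ledger$category)
  expect_true(all(per_iter <= 1L))
})

test_that("prompt sets grow monotonically by gated admissions", {
  sc <- tiny_scene(seed = 4, noise_sd = 0.03)
  seg <- tiny_backend(sc, flip_rate = 0.1)
  seeds <- sample_seed_labels(sc$truth, per_class = 3, seed = 4)
  groups <- lapply(decompose_bands(sc$cube), normalize_group)
  cfg <- ipg_config(iterations = 1, seed = 4)
  st <- ipg_initialize(seeds, dim(embed_features(seg))[3])
  sizes <- sapply(st$prompts, nrow)
  for (t in 1:5) {
    st <- ipg_iterate(st, seg, groups, cfg)
    new_sizes <- sapply(st$prompts, nrow)
    expect_true(all(new_sizes >= sizes))
    expect_true(all(new_sizes - sizes <= cfg$selections_per_class))
    sizes <- new_sizes
  }
})

test_that("the confidence gate protects precision under mask noise", {
  gated <- numeric(10); ungated <- numeric(10)
  for (s in 1:10) {
    sc <- tiny_scene(seed = 100 + s, noise_sd = 0.06, H = 28, W = 28, C = 10)
    seg <- tiny_backend(sc, flip_rate = 0.1)
    seeds <- sample_seed_labels(sc$truth, per_class = 4, seed = s)
    fit_g <- ipg(sc$cube, seeds, seg, ipg_config(iterations = 8, seed = s))
    fit_u <- ipg(sc$cube, seeds, seg,
                 ipg_config(iterations = 8, seed = s,
                            thresholds = thresholds(tau_h = 1e-6, tau_l = 0,
                                                    kappa_h = Inf)))
    gated[s] <- pseudo_precision(fit_g, sc$truth)
    ungated[s] <- pseudo_precision(fit_u, sc$truth)
  }
  expect_gte(mean(gated, na.rm = TRUE), mean(ungated, na.rm = TRUE))
})
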