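seed_prompts_for <- function(scene, k, n = 3, bg_k = NULL) {
  own <- which(scene$truth == k, arr.ind = TRUE)[seq_len(n), , drop = FALSE]
  p <- point_prompts(own[, 1], own[, 2], "foreground")
  if (!is.null(bg_k)) {
    oth <- which(scene$truth == bg_k, arr.ind = TRUE)[seq_len(n), , drop = FALSE]
    p <- rbind(p, point_prompts(oth[, 1], oth[, 2], "background"))
  }
  p
}

test_that("noise-free oracle masks equal the prompted region exactly", {
  sc <- tiny_scene(seed = 2)
  seg <- tiny_backend(sc, flip_rate = 0)
  img <- normalize_group(decompose_bands(sc$cube)[[1]])
  for (k in 1:3) {
    res <- segment(seg, img, seed_prompts_for(sc, k, bg_k = (k %% 3) + 1))
    expect_identical(res$mask, unclass(sc$truth) == k)
    expect_identical(res$mask, res$score >= 0.5)
    expect_true(all(res$score >= 0 & res$score <= 1))
  }
})

test_that("flip noise hits the expected fraction of the boundary band", {
  sc <- tiny_scene(seed = 7, H = 48, W = 48, K = 2, C = 6)
  img <- normalize_group(decompose_bands(sc$cube)[[1]])
  region <- unclass(sc$truth) == 1L
  elig <- ipghsi:::boundary_band(region, 3L)
  seg <- tiny_backend(sc, flip_rate = 0.5, band_width = 3)
  res <- segment(seg, img, seed_prompts_for(sc, 1), group = 1L)
  flipped <- sum(res$mask[elig] != region[elig])
  n <- sum(elig)
  # binomial(n, 0.5): allow 4 standard deviations
  expect_lt(abs(flipped - 0.5 * n), 4 * sqrt(n * 0.25))
  # outside the eligibility band the mask is exact
  expect_identical(res$mask[!elig], region[!elig])
})

test_that("prompt validation and order invariance hold", {
  sc <- tiny_scene(seed = 2)
  seg <- tiny_backend(sc, flip_rate = 0.3)
  img <- normalize_group(decompose_bands(sc$cube)[[1]])
  p <- seed_prompts_for(sc, 2, n = 4, bg_k = 1)
  expect_error(segment(seg, img, p[p$polarity == "background", ]), "foreground")
  bad <- point_prompts(999L, 1L)
  expect_error(segment(seg, img, bad), "bounds")
  # single foreground prompt, no background, is valid
  expect_s3_class(segment(seg, img, p[1, ]), "segmentation")
  # permuting prompts within polarity changes nothing
  perm <- p[c(4, 2, 3, 1, 8, 6, 7, 5), ]
  expect_identical(segment(seg, img, p, group = 3L)$mask,
                   segment(seg, img, perm, group = 3L)$mask)
})

test_that("oracle embeddings are deterministic class signatures plus noise", {
  sc <- tiny_scene(seed = 9, noise_sd = 0)
  seg <- tiny_backend(sc)
  e1 <- embed_features(seg)
  e2 <- embed_features(seg)
  expect_identical(e1, e2)
  expect_identical(attr(e1, "source"), "oracle")
  # zero noise: same-class pixels share one vector
  px <- which(sc$truth == 2L)[1:4]
  em <- matrix(e1, length(sc$truth), dim(e1)[3])
  for (i in 2:4) expect_equal(em[px[1], ], em[px[i], ])
  # cross-class cosine stays below the configured separation bound
  qx <- which(sc$truth == 3L)[1]
  expect_lte(cosine_sim(em[px[1], ], em[qx, ]),
             cos(sc$spec$theta_min * pi / 180) + 1e-12)
})

test_that("projection steps update only as the gradient dictates", {
  A <- prompt_projection(4)
  expect_identical(unclass(projection_step(A, matrix(0, 4, 4), 0.1)), diag(4))
  expect_identical(unclass(projection_step(A, matrix(1, 4, 4), 0)), diag(4))
  expect_warning(out <- projection_step(A, matrix(NaN, 4, 4), 0.1), "non-finite")
  expect_identical(unclass(out), diag(4))
  # quadratic toy loss L(A) = 0.5 ||A - B||^2: gradient steps move A
  # monotonically toward the minimiser B for small learning rates
  B <- matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15), 4, 4)
  A <- prompt_projection(4)
  d_prev <- sqrt(sum((unclass(A) - B)^2))
  for (i in 1:20) {
    A <- projection_step(A, unclass(A) - B, 0.1)
    d <- sqrt(sum((unclass(A) - B)^2))
    expect_lt(d, d_prev)
    d_prev <- d
  }
})
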