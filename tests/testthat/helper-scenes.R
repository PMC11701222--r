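# small scene fixtures, generated in code at test time

tiny_scene <- function(seed = 2, noise_sd = 0, H = 24, W = 24, C = 8, K = 3,
                       theta_min = 40) {
  generate_scene(scene_spec(H = H, W = W, C = C, K = K, noise_sd = noise_sd,
                            theta_min = theta_min, min_region = 2L, seed = seed))
}

tiny_backend <- function(scene, flip_rate = 0, band_width = 3L, dilate = 0L) {
  oracle_segmenter(export_oracle(scene, flip_rate = flip_rate,
                                 band_width = band_width, dilate = dilate))
}

# independent brute-force voting oracle: plain loops per pixel
brute_vote <- function(stack, min_votes = 1L) {
  d <- dim(stack)
  G <- d[1]; K <- d[2]; H <- d[3]; W <- d[4]
  tal <- array(0L, c(K, H, W))
  lab <- matrix(0L, H, W)
  marg <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    counts <- integer(K)
    for (i in seq_len(K)) for (j in seq_len(G)) {
      if (stack[j, i, r, c]) counts[i] <- counts[i] + 1L
    }
    tal[, r, c] <- counts
    best <- which.max(counts)            # first max = smallest index
    if (counts[best] >= min_votes) lab[r, c] <- best
    marg[r, c] <- counts[best] - if (K > 1L) max(counts[-best]) else 0L
  }
  list(tally = tal, labels = lab, margin = marg)
}

# independent brute-force metrics in exact rational arithmetic; counts are
# small integers so all products below stay exactly representable
brute_metrics <- function(cm) {
  K <- nrow(cm)
  tp <- diag(cm)
  tot <- rowSums(cm)
  fp <- colSums(cm) - tp
  n <- sum(cm)
  oa <- list(num = sum(tp), den = n)
  pe <- list(num = sum(tot * (tp + fp)), den = n^2)
  # kappa = (oa - pe) / (1 - pe) as one exact ratio
  kap_num <- oa$num * pe$den - pe$num * oa$den
  kap_den <- oa$den * (pe$den - pe$num)
  list(oa = oa$num / oa$den,
       aa = mean(tp / tot),
       pe = pe$num / pe$den,
       kappa = if (kap_den == 0) NA_real_ else kap_num / kap_den)
}

random_confusion <- function(K, max_count = 60L) {
  matrix(sample.int(max_count + 1L, K * K, replace = TRUE) - 1L, K, K)
}
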