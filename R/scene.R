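#' Specify a synthetic hyperspectral scene
#'
#' The generator emulates the structure that makes the iterative
#' pseudo-labelling strategy work on real agricultural and urban scenes:
#' spatially contiguous class regions, smooth per-class spectral signature
#' curves across bands (so adjacent three-band groups look similar), and
#' additive Gaussian sensor noise. Class separability is controlled by a
#' minimum pairwise angular separation between signatures.
#'
#' @param H,W Scene height and width in pixels.
#' @param C Number of spectral bands (>= 3).
#' @param K Number of classes (>= 2).
#' @param region_model `"blobs"` (random 4-connected region growing, the
#'   default) or `"voronoi"` (nearest-site partition).
#' @param theta_min Minimum pairwise angle between class signatures, in
#'   degrees; larger means more separable classes.
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian noise, on
#'   the scale of the signatures (whose peak value is 1).
#' @param min_region Minimum pixel count per class region.
#' @param seed Integer seed; the scene is a pure function of its spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(H = 64L, W = 64L, C = 24L, K = 4L,
                       region_model = c("blobs", "voronoi"),
                       theta_min = 30, noise_sd = 0.05,
                       min_region = 16L, seed = 1L) {
  region_model <- match.arg(region_model)
  stopifnot(H >= 1, W >= 1, C >= 3, K >= 2, theta_min > 0, noise_sd >= 0,
            min_region >= 1, H * W >= K * min_region)
  structure(list(H = as.integer(H), W = as.integer(W), C = as.integer(C),
                 K = as.integer(K), region_model = region_model,
                 theta_min = theta_min, noise_sd = noise_sd,
                 min_region = as.integer(min_region), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic hyperspectral scene
#'
#' Produces a cube whose every pixel spectrum equals its class signature
#' plus i.i.d. Gaussian noise, together with the ground-truth label raster
#' and the signature matrix. Deterministic for a given spec.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene` with elements `cube`
#'   ([hsi_cube()]), `truth` ([label_map()]), `signatures` (`K x C`
#'   matrix) and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(H = 16, W = 16, C = 8, K = 3, seed = 7))
#' table(sc$truth)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(derive_seed(spec$seed, "scene"), {
    truth <- grow_regions(spec)
    sig <- draw_signatures(spec$K, spec$C, spec$theta_min)
    cube <- array(sig[as.vector(truth), ], c(spec$H, spec$W, spec$C))
    if (spec$noise_sd > 0) {
      cube <- cube + stats::rnorm(length(cube), sd = spec$noise_sd)
    }
    structure(list(cube = hsi_cube(cube),
                   truth = label_map(truth, spec$K),
                   signatures = sig, spec = spec),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<synthetic_scene> %dx%d, %d bands, %d classes (%s regions), noise sd %.3g\n",
              s$H, s$W, s$C, s$K, s$region_model, s$noise_sd))
  invisible(x)
}

# K contiguous regions covering the grid
grow_regions <- function(spec, max_tries = 25L) {
  for (try in seq_len(max_tries)) {
    m <- if (spec$region_model == "voronoi") {
      voronoi_regions(spec$H, spec$W, spec$K)
    } else {
      blob_regions(spec$H, spec$W, spec$K)
    }
    if (min(tabulate(m, spec$K)) >= spec$min_region) return(m)
  }
  stop("could not place ", spec$K, " regions of >= ", spec$min_region,
       " pixels in ", max_tries, " attempts")
}

voronoi_regions <- function(H, W, K) {
  sites <- cbind(stats::runif(K, 1, H), stats::runif(K, 1, W))
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- sapply(seq_len(K), function(k) (rr - sites[k, 1])^2 + (cc - sites[k, 2])^2)
  matrix(max.col(-d2, ties.method = "first"), H, W)
}

# multi-source random flood fill: unassigned pixels adopt the class of a
# uniformly chosen assigned 4-neighbour, sweep by sweep; every region stays
# 4-connected to its seed by construction
blob_regions <- function(H, W, K) {
  m <- matrix(0L, H, W)
  seeds <- sample.int(H * W, K)
  m[seeds] <- seq_len(K)
  while (any(m == 0L)) {
    nb <- list(shift_matrix(m, 1L, 0L, 0L), shift_matrix(m, -1L, 0L, 0L),
               shift_matrix(m, 0L, 1L, 0L), shift_matrix(m, 0L, -1L, 0L))
    cand <- which(m == 0L & (nb[[1]] > 0L | nb[[2]] > 0L | nb[[3]] > 0L | nb[[4]] > 0L))
    if (!length(cand)) break
    pick <- matrix(c(nb[[1]][cand], nb[[2]][cand], nb[[3]][cand], nb[[4]][cand]),
                   ncol = 4L)
    chosen <- apply(pick, 1L, function(v) {
      v <- v[v > 0L]
      v[sample.int(length(v), 1L)]
    })
    m[cand] <- as.integer(chosen)
  }
  m
}

# smooth per-class signatures: mixtures of band-indexed Gaussian bumps with
# a small baseline, rescaled to peak 1; rejection sampling enforces the
# pairwise angular separation
draw_signatures <- function(K, C, theta_min, max_tries = 500L) {
  cos_max <- cos(theta_min * pi / 180)
  bands <- seq_len(C)
  draw_one <- function() {
    nb <- sample(2:4, 1L)
    mu <- stats::runif(nb, 1, C)
    sdv <- stats::runif(nb, C / 24, C / 8)
    amp <- stats::runif(nb, 0.4, 1)
    s <- 0.05 + colSums(amp * exp(-outer(mu, bands, "-")^2 / (2 * sdv^2)))
    s / max(s)
  }
  sig <- t(replicate(K, draw_one()))
  cosm <- function(S) {
    Sn <- S / sqrt(rowSums(S^2))
    cc <- Sn %*% t(Sn)
    diag(cc) <- 0
    cc
  }
  tries <- 0L
  repeat {
    cc <- cosm(sig)
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[worst[1], worst[2]] <= cos_max) break
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not draw ", K, " signatures with pairwise separation >= ",
           theta_min, " degrees over ", C, " bands")
    }
    sig[worst[1], ] <- draw_one()
  }
  dimnames(sig) <- list(paste0("class", seq_len(K)), paste0("band", seq_len(C)))
  sig
}

#' Package a scene's oracle knowledge for the synthetic segmenter
#'
#' The oracle segmenter backend derives its masks from the known ground
#' truth, corrupted by a controllable noise model: independent per-pixel
#' label flips at rate `flip_rate` inside a band of `band_width` pixels
#' around region boundaries (where real promptable segmenters actually
#' err), plus optional whole-mask dilation. Pixel embeddings are the
#' observed spectra, i.e. class signature plus the scene's Gaussian noise.
#'
#' @param scene A [synthetic_scene()] from [generate_scene()].
#' @param flip_rate Per-pixel flip probability inside the boundary band.
#' @param band_width Width (4-connected steps) of the flip-eligible band on
#'   either side of a region boundary.
#' @param dilate Whole-mask dilation steps applied after flipping.
#' @return A list of class `oracle_bundle`.
#' @export
export_oracle <- function(scene, flip_rate = 0.15, band_width = 3L, dilate = 0L) {
  stopifnot(inherits(scene, "synthetic_scene"),
            flip_rate >= 0, flip_rate <= 1, band_width >= 0, dilate >= 0)
  structure(list(truth = scene$truth,
                 embeddings = unclass(scene$cube),
                 signatures = scene$signatures,
                 flip_rate = flip_rate,
                 band_width = as.integer(band_width),
                 dilate = as.integer(dilate),
                 n_groups = scene$spec$C - 2L,
                 seed = scene$spec$seed),
            class = "oracle_bundle")
}

#' Write or read an oracle bundle as plain files
#'
#' The bundle is a directory of text artefacts: the label raster and
#' signatures as CSV, the embedding cube as long CSV, and the noise
#' parameters as YAML. `read_oracle_bundle()` restores a value-identical
#' bundle.
#'
#' @param bundle An `oracle_bundle`.
#' @param dir Directory to write to / read from.
#' @export
write_oracle_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(bundle$truth, file.path(dir, "truth.csv"))
  write_cube(hsi_cube(bundle$embeddings), file.path(dir, "embeddings.csv"))
  utils::write.csv(bundle$signatures, file.path(dir, "signatures.csv"))
  yaml::write_yaml(bundle[c("flip_rate", "band_width", "dilate", "n_groups", "seed")],
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

#' @rdname write_oracle_bundle
#' @export
read_oracle_bundle <- function(dir) {
  p <- yaml::read_yaml(file.path(dir, "params.yaml"))
  sig <- as.matrix(utils::read.csv(file.path(dir, "signatures.csv"), row.names = 1))
  colnames(sig) <- paste0("band", seq_len(ncol(sig)))
  structure(list(truth = read_labels(file.path(dir, "truth.csv")),
                 embeddings = unclass(read_cube(file.path(dir, "embeddings.csv"))),
                 signatures = sig,
                 flip_rate = p$flip_rate, band_width = as.integer(p$band_width),
                 dilate = as.integer(p$dilate), n_groups = as.integer(p$n_groups),
                 seed = as.integer(p$seed)),
            class = "oracle_bundle")
}
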