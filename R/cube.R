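#' Hyperspectral cube objects
#'
#' An `hsi_cube` is an `H x W x C` numeric array of reflectance values with
#' at least three spectral bands. All values must be finite; a single NaN or
#' Inf in any band is a validation error naming that band, since downstream
#' stages (band-group rendering, cosine similarities, the classifier) have
#' no meaningful treatment for missing radiance.
#'
#' @param values Numeric 3-D array indexed (row, col, band).
#' @return An object of class `hsi_cube` (the validated array with
#'   dimensions recorded).
#' @examples
#' cube <- hsi_cube(array(runif(4 * 5 * 6), dim = c(4, 5, 6)))
#' dim(cube)
#' @export
hsi_cube <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("a hyperspectral cube must be a 3-D numeric array (row, col, band)")
  }
  if (!is.numeric(values)) stop("cube values must be numeric")
  d <- dim(values)
  if (d[3] < 3L) stop("a cube needs at least 3 spectral bands, got ", d[3])
  bad <- which(apply(values, 3, function(b) any(!is.finite(b))))
  if (length(bad)) {
    stop("non-finite values in band(s) ", paste(bad, collapse = ", "))
  }
  structure(values, class = c("hsi_cube", "array"))
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Label maps
#'
#' A label raster companion to a cube: integers in `0..K`, where 0 marks an
#' unlabelled pixel. Ground-truth rasters must contain at least one nonzero
#' label.
#'
#' @param labels Integer matrix (row, col).
#' @param n_classes Number of categories `K`; defaults to `max(labels)`.
#' @return Integer matrix of class `label_map` with attribute `n_classes`.
#' @export
label_map <- function(labels, n_classes = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels != round(labels)) || any(labels < 0)) {
    stop("labels must be nonnegative integers (0 = unlabelled)")
  }
  storage.mode(labels) <- "integer"
  if (is.null(n_classes)) n_classes <- max(labels)
  if (any(labels > n_classes)) stop("label exceeds n_classes")
  structure(labels, class = c("label_map", "matrix"), n_classes = as.integer(n_classes))
}

#' Decompose a cube into overlapping three-band groups
#'
#' Every three adjacent spectral bands form one three-channel image, so a
#' `C`-band cube yields exactly `C - 2` groups; group `j` holds bands
#' `(j, j + 1, j + 2)` (1-based) and shares two bands with group `j + 1`.
#' This sliding decomposition is what lets an RGB-native promptable
#' segmenter consume a hyperspectral cube, and the two-band overlap is the
#' redundancy the spectral-voting fusion later exploits.
#'
#' @param cube An [hsi_cube()] (or plain 3-D array) with `C >= 3` bands.
#' @return A list of class `band_groups`; element `j` is an `H x W x 3`
#'   array of the raw (unnormalised) band values.
#' @examples
#' cube <- hsi_cube(array(rnorm(6 * 6 * 5), dim = c(6, 6, 5)))
#' length(decompose_bands(cube))  # 3
#' @export
decompose_bands <- function(cube) {
  d <- dim(cube)
  if (is.null(d) || length(d) != 3L) stop("cube must be a 3-D array")
  C <- d[3]
  if (C < 3L) stop("band decomposition needs C >= 3, got C = ", C)
  groups <- lapply(seq_len(C - 2L), function(j) cube[, , j:(j + 2L), drop = FALSE])
  structure(groups, class = "band_groups", bands = C)
}

#' Render a three-band slice into the segmenter's display range
#'
#' Each channel is independently min-max scaled to `[0, 255]`. A constant
#' channel (zero dynamic range) maps to 0 everywhere. Band groups are fed
#' to a natural-image segmenter, which expects 8-bit-like display values;
#' per-channel min-max is the simplest reproducible mapping. A global
#' percentile stretch is available for scenes with heavy outliers.
#'
#' @param bands3 `H x W x 3` numeric array.
#' @param method `"minmax"` (default) or `"percentile"`.
#' @param probs Lower/upper clip quantiles for the percentile stretch.
#' @return `H x W x 3` array with values in `[0, 255]`.
#' @export
normalize_group <- function(bands3, method = c("minmax", "percentile"),
                            probs = c(0.02, 0.98)) {
  method <- match.arg(method)
  d <- dim(bands3)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 array")
  if (any(!is.finite(bands3))) stop("non-finite values in band group")
  out <- bands3
  for (ch in 1:3) {
    v <- bands3[, , ch]
    rng <- if (method == "minmax") range(v) else stats::quantile(v, probs, names = FALSE)
    if (rng[2] <= rng[1]) {
      out[, , ch] <- 0
    } else {
      out[, , ch] <- pmin(pmax((v - rng[1]) / (rng[2] - rng[1]), 0), 1) * 255
    }
  }
  out
}

#' Read and write hyperspectral cubes
#'
#' Two on-disk dialects are supported: multi-band 32-bit float TIFF (via the
#' \pkg{tiff} package) and a portable long-format CSV with columns
#' `row,col,band,value`. TIFF is compact and fast; CSV is plain text and
#' diff-able, convenient for small synthetic scenes and fixtures.
#'
#' @param path File path.
#' @param dialect `"tiff"` or `"csv"`; inferred from the extension when
#'   `NULL`.
#' @return `read_cube()` returns an [hsi_cube()]; `write_cube()` returns
#'   `path` invisibly.
#' @export
read_cube <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- dialect %||% infer_dialect(path)
  values <- switch(dialect,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required for dialect = \"tiff\"")
      }
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      arr <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
      side <- paste0(path, ".scale")
      aff <- if (file.exists(side)) {
        as.numeric(strsplit(readLines(side, n = 1L), " ")[[1]])
      } else c(0, 1)
      arr * aff[2] + aff[1]
    },
    csv = {
      df <- utils::read.csv(path)
      need <- c("row", "col", "band", "value")
      if (!all(need %in% names(df))) {
        stop("cube CSV must have columns row, col, band, value")
      }
      H <- max(df$row); W <- max(df$col); C <- max(df$band)
      if (nrow(df) != H * W * C) stop("cube CSV is not a complete grid")
      a <- array(NA_real_, c(H, W, C))
      a[cbind(df$row, df$col, df$band)] <- df$value
      a
    },
    stop("unknown cube dialect: ", dialect)
  )
  hsi_cube(values)
}

#' @rdname read_cube
#' @param cube Cube to write.
#' @export
write_cube <- function(cube, path, dialect = NULL) {
  dialect <- dialect %||% infer_dialect(path)
  d <- dim(cube)
  switch(dialect,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required for dialect = \"tiff\"")
      }
      # writeTIFF stores [0,1] floats; bands go out as grayscale pages and an
      # affine offset/scale side-car restores physical units
      lo <- min(cube); hi <- max(cube)
      sc <- max(hi - lo, 1e-12)
      pages <- lapply(seq_len(d[3]), function(b) (unclass(cube)[, , b] - lo) / sc)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
      writeLines(paste(format(lo, digits = 17), format(sc, digits = 17)),
                 paste0(path, ".scale"))
    },
    csv = {
      idx <- arrayInd(seq_len(prod(d)), d)
      df <- data.frame(row = idx[, 1], col = idx[, 2], band = idx[, 3],
                       value = as.vector(unclass(cube)))
      utils::write.csv(df, path, row.names = FALSE)
    },
    stop("unknown cube dialect: ", dialect)
  )
  invisible(path)
}

infer_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tif = , tiff = "tiff", csv = "csv",
         stop("cannot infer cube dialect from extension '.", ext, "'"))
}

attr_default <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write label rasters
#'
#' Label maps are stored either as a dense integer CSV grid (one row of the
#' file per raster row, no header) or as a sparse `row,col,label` CSV with
#' header (unlisted pixels are unlabelled).
#'
#' @param path File path.
#' @param shape `c(H, W)` of the raster, required for the sparse format.
#' @param sparse Write `row,col,label` triples instead of a dense grid.
#' @return `read_labels()` returns a [label_map()].
#' @export
read_labels <- function(path, shape = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^\"?row\"?,\"?col\"?,\"?label\"?", first)) {
    df <- utils::read.csv(path)
    if (is.null(shape)) stop("sparse label CSV needs an explicit shape")
    m <- matrix(0L, shape[1], shape[2])
    m[cbind(df$row, df$col)] <- as.integer(df$label)
    label_map(m)
  } else {
    m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    label_map(m)
  }
}

#' @rdname read_labels
#' @param labels A [label_map()] or integer matrix.
#' @export
write_labels <- function(labels, path, sparse = FALSE) {
  if (sparse) {
    idx <- which(labels != 0L, arr.ind = TRUE)
    df <- data.frame(row = idx[, 1], col = idx[, 2], label = labels[idx])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.table(unclass(labels), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Sample seed labels from a ground-truth raster
#'
#' Draws `per_class` labelled pixels per category, uniformly at random
#' without replacement, reproducibly for a given seed. These few points per
#' class (five in the reference setting) are the only supervision the
#' iterative pseudo-labelling starts from.
#'
#' @param gt Ground-truth [label_map()].
#' @param per_class Seeds per category.
#' @param seed Integer RNG seed.
#' @return A `data.frame` of class `seed_labels` with columns
#'   `row`, `col`, `category`.
#' @export
sample_seed_labels <- function(gt, per_class = 5L, seed = 1L) {
  K <- attr(gt, "n_classes") %||% max(gt)
  if (K < 1L) stop("ground truth has no labelled classes")
  counts <- tabulate(gt[gt > 0L], nbins = K)
  short <- which(counts < per_class)
  if (length(short)) {
    stop("category ", paste(short, collapse = ", "), " has fewer than ",
         per_class, " labelled pixels")
  }
  rows <- with_seed(derive_seed(seed, "seeds"), {
    lapply(seq_len(K), function(k) {
      idx <- which(gt == k, arr.ind = TRUE)
      take <- idx[sample.int(nrow(idx), per_class), , drop = FALSE]
      data.frame(row = take[, 1], col = take[, 2], category = k)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("seed_labels", "data.frame")
  out
}
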