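#' Synthetic morphotype image specification
#'
#' Describes a generated dataset of labelled grayscale images emulating
#' four visually distinct benthic habitat classes: strap-like leaves
#' (oriented sinusoidal gratings), oval leaves (elliptical blobs on a dark
#' ground), branched stems (recursive line segments) and background
#' texture (low-frequency noise with speckle). Image dimensions must be
#' divisible by the patch-grid rows/columns so grid slicing is exact.
#'
#' @param n_classes Number of classes (2..4, default 4; classes are taken
#'   in the order strap, oval, branch, background).
#' @param per_class Images per class.
#' @param image_size `(height, width)` in pixels.
#' @param rows,cols Patch grid (default 6 x 6).
#' @param noise_sd Additive pixel noise standard deviation.
#' @param seed Generation seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_classes = 4L, per_class = 25L,
                           image_size = c(48L, 48L), rows = 6L, cols = 6L,
                           noise_sd = 0.05, seed = 1L) {
  stopifnot(n_classes >= 2L, n_classes <= 4L, per_class >= 1L,
            length(image_size) == 2L, rows >= 1L, cols >= 1L, noise_sd >= 0)
  if (image_size[1L] %% rows != 0L || image_size[2L] %% cols != 0L) {
    stop("image height/width must be divisible by rows/cols")
  }
  structure(list(n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class),
                 image_size = as.integer(image_size),
                 rows = as.integer(rows), cols = as.integer(cols),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 class_names = c("strap", "oval", "branch", "background")[
                   seq_len(n_classes)]),
            class = "synthetic_spec")
}

texture_strap <- function(h, w) {
  theta <- stats::runif(1L, 0, pi)
  freq <- stats::runif(1L, 3, 6) / min(h, w)
  phase <- stats::runif(1L, 0, 2 * pi)
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  0.5 + 0.38 * sin(2 * pi * freq * (r * cos(theta) + c * sin(theta)) + phase)
}

texture_oval <- function(h, w) {
  img <- matrix(0.25, h, w)
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  # one blob per image quadrant (so every patch sees leaf material) plus
  # a few extra anywhere
  centers <- rbind(
    cbind(stats::runif(4L, c(0.05, 0.05, 0.55, 0.55) * h,
                       c(0.45, 0.45, 0.95, 0.95) * h),
          stats::runif(4L, c(0.05, 0.55, 0.05, 0.55) * w,
                       c(0.45, 0.95, 0.45, 0.95) * w)),
    cbind(stats::runif(2L, 0.2 * h, 0.8 * h),
          stats::runif(2L, 0.2 * w, 0.8 * w)))
  for (b in seq_len(nrow(centers))) {
    a1 <- stats::runif(1L, 0.14, 0.24) * min(h, w)
    a2 <- a1 * stats::runif(1L, 0.6, 1.0)  # near-round
    ang <- stats::runif(1L, 0, pi)
    u <- (r - centers[b, 1L]) * cos(ang) + (c - centers[b, 2L]) * sin(ang)
    v <- -(r - centers[b, 1L]) * sin(ang) + (c - centers[b, 2L]) * cos(ang)
    img[(u / a1)^2 + (v / a2)^2 <= 1] <- 0.9
  }
  img
}

draw_segment <- function(img, r0, c0, r1, c1, value) {
  n <- max(2L, ceiling(2 * max(abs(r1 - r0), abs(c1 - c0))))
  t <- seq(0, 1, length.out = n)
  rr <- round(r0 + t * (r1 - r0))
  cc <- round(c0 + t * (c1 - c0))
  ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  img[cbind(rr[ok], cc[ok])] <- value
  img
}

texture_branch <- function(h, w) {
  img <- matrix(0.05, h, w)
  # two stems rooted in the lower half (one per horizontal half, so all
  # patches see branch material), each with two children per segment
  roots <- stats::runif(2L, c(0.1, 0.55) * w, c(0.45, 0.9) * w)
  for (root_c in roots) {
    segs <- list(list(r = h, c = root_c,
                      ang = -pi / 2 + stats::runif(1L, -0.2, 0.2),
                      len = stats::runif(1L, 0.3, 0.4) * h))
    for (depth in 1:4) {
      nxt <- list()
      for (s in segs) {
        r1 <- s$r + s$len * sin(s$ang)
        c1 <- s$c + s$len * cos(s$ang)
        img <- draw_segment(img, s$r, s$c, r1, c1, 0.95)
        if (depth < 4L) {
          for (dang in stats::runif(2L, 0.3, 0.8) * c(-1, 1)) {
            nxt[[length(nxt) + 1L]] <- list(r = r1, c = c1,
                                            ang = s$ang + dang,
                                            len = s$len * 0.7)
          }
        }
      }
      segs <- nxt
      if (length(segs) == 0L) break
    }
  }
  img
}

texture_background <- function(h, w) {
  # low-frequency field: bilinear upsample of a coarse random grid
  gh <- max(2L, ceiling(h / 8)); gw <- max(2L, ceiling(w / 8))
  coarse <- matrix(stats::runif(gh * gw, 0.3, 0.7), gh, gw)
  ri <- seq(1, gh, length.out = h)
  ci <- seq(1, gw, length.out = w)
  r0 <- pmin(floor(ri), gh - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), gw - 1L); fc <- ci - c0
  img <- matrix(0, h, w)
  for (dr in 0:1) for (dc in 0:1) {
    wr <- if (dr == 0) 1 - fr else fr
    wc <- if (dc == 0) 1 - fc else fc
    img <- img + (wr %o% wc) * coarse[r0 + dr, c0 + dc]
  }
  # speckle
  n_spk <- ceiling(0.02 * h * w)
  img[cbind(sample.int(h, n_spk, replace = TRUE),
            sample.int(w, n_spk, replace = TRUE))] <-
    stats::runif(n_spk, 0.85, 1)
  img
}

#' Generate a labelled synthetic morphotype dataset
#'
#' Draws each class from its parametric texture family, adds pixel noise
#' and clamps to `[0, 1]`. Generation is deterministic under the seed
#' carried by `spec`. By default `per_class` images are generated per class; `n_images`
#' overrides the total, distributing images across classes as evenly as
#' possible (remainders go to the later classes).
#'
#' @param spec A [synthetic_spec()].
#' @param n_images Optional total image count override.
#' @return A `morphotype_dataset`: list of `images` (H x W matrices in
#'   `[0, 1]`), integer `labels` in `1..n_classes`, and `class_names`.
#' @export
generate_dataset <- function(spec, n_images = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- spec$n_classes
  if (is.null(n_images)) {
    labels <- rep(seq_len(k), each = spec$per_class)
  } else {
    base <- n_images %/% k
    counts <- rep(base, k) + c(rep(0L, k - n_images %% k),
                               rep(1L, n_images %% k))
    labels <- rep(seq_len(k), times = counts)
  }
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  gens <- list(texture_strap, texture_oval, texture_branch,
               texture_background)
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    img <- gens[[labels[i]]](h, w)
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
  }
  structure(list(images = images, labels = labels,
                 class_names = spec$class_names, spec = spec),
            class = "morphotype_dataset")
}

#' @export
print.morphotype_dataset <- function(x, ...) {
  h <- nrow(x$images[[1L]]); w <- ncol(x$images[[1L]])
  cat(sprintf("morphotype_dataset: %d images of %dx%d px, %d classes (%s)\n",
              length(x$images), h, w, length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  print(table(factor(x$labels, labels = x$class_names)))
  invisible(x)
}

#' Slice an image into a grid of patches
#'
#' Divides an image into `rows x cols` equal, disjoint patches in
#' row-major order (top-left patch first). Dimensions must be divisible by
#' the grid; reassembling the patches in provenance order reconstructs the
#' image exactly.
#'
#' @param image H x W matrix (grayscale) or H x W x C array.
#' @param rows,cols Grid dimensions.
#' @return A `patch_set`: list of `patches` plus a `provenance` data frame
#'   (`parent`, `row`, `col`).
#' @export
slice_grid <- function(image, rows = 6L, cols = 6L) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h %% rows != 0L || w %% cols != 0L) {
    stop(sprintf("image %dx%d is not divisible by a %dx%d grid", h, w, rows, cols))
  }
  ph <- h %/% rows; pw <- w %/% cols
  patches <- vector("list", rows * cols)
  prov <- data.frame(parent = rep(1L, rows * cols),
                     row = rep(seq_len(rows), each = cols),
                     col = rep(seq_len(cols), times = rows))
  idx <- 1L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      ri <- ((r - 1L) * ph + 1L):(r * ph)
      ci <- ((cc - 1L) * pw + 1L):(cc * pw)
      patches[[idx]] <- if (length(dim(image)) == 3L)
        image[ri, ci, , drop = FALSE] else image[ri, ci, drop = FALSE]
      idx <- idx + 1L
    }
  }
  structure(list(patches = patches, provenance = prov), class = "patch_set")
}

#' Slice every image of a dataset, inheriting labels
#'
#' Applies [slice_grid()] to each image; every patch inherits its parent
#' image's class label (whole-image labelling). The result is itself a
#' `morphotype_dataset` (of patches) carrying a provenance table.
#'
#' @param dataset A `morphotype_dataset`.
#' @param rows,cols Grid dimensions.
#' @return A `morphotype_dataset` of `n_images * rows * cols` patches with
#'   a `provenance` element.
#' @export
slice_dataset <- function(dataset, rows = 6L, cols = 6L) {
  stopifnot(inherits(dataset, "morphotype_dataset"))
  per_image <- vector("list", length(dataset$images))
  prov <- vector("list", length(dataset$images))
  for (i in seq_along(dataset$images)) {
    ps <- slice_grid(dataset$images[[i]], rows, cols)
    ps$provenance$parent <- i
    prov[[i]] <- ps$provenance
    per_image[[i]] <- ps$patches
  }
  structure(list(images = unlist(per_image, recursive = FALSE),
                 labels = rep(dataset$labels, each = rows * cols),
                 class_names = dataset$class_names,
                 provenance = do.call(rbind, prov)),
            class = "morphotype_dataset")
}

#' Default class colour palette
#'
#' Four distinct colours for patch overlays (blue, yellow, purple,
#' maroon), one per morphotype class.
#'
#' @return Character vector of hex colours.
#' @export
morphotype_palette <- function() {
  c("#1F4FD8", "#FFD500", "#8E44AD", "#800000")
}

#' Tint an image with per-patch class colours
#'
#' Overlays each grid patch with its class colour at the given opacity,
#' returning an RGB array of the same spatial dimensions with a
#' `legend` attribute mapping class index to colour.
#'
#' @param image H x W grayscale matrix in `[0, 1]`.
#' @param patch_labels `rows x cols` integer matrix of class labels.
#' @param palette Colour per class (length >= max label).
#' @param alpha Tint opacity in `[0, 1]`.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
overlay <- function(image, patch_labels, palette = morphotype_palette(),
                    alpha = 0.45) {
  stopifnot(is.matrix(image), is.matrix(patch_labels))
  rows <- nrow(patch_labels); cols <- ncol(patch_labels)
  if (max(patch_labels) > length(palette)) {
    stop("palette has fewer colours than classes")
  }
  h <- nrow(image); w <- ncol(image)
  if (h %% rows != 0L || w %% cols != 0L) {
    stop("image dimensions not divisible by the label grid")
  }
  ph <- h %/% rows; pw <- w %/% cols
  rgb <- grDevices::col2rgb(palette) / 255
  out <- array(0, dim = c(h, w, 3L))
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      ri <- ((r - 1L) * ph + 1L):(r * ph)
      ci <- ((cc - 1L) * pw + 1L):(cc * pw)
      col3 <- rgb[, patch_labels[r, cc]]
      for (ch in 1:3) {
        out[ri, ci, ch] <- (1 - alpha) * image[ri, ci] + alpha * col3[ch]
      }
    }
  }
  attr(out, "legend") <- stats::setNames(palette[seq_len(max(patch_labels))],
                                         seq_len(max(patch_labels)))
  out
}

#' Write / read a dataset as PNG files plus a CSV manifest
#'
#' `write_dataset()` writes one PNG per image and a `manifest.csv` with
#' columns `filename,label` (plus provenance columns when present);
#' `read_dataset()` inverts it, converting RGB PNGs to grayscale by the
#' Rec. 601 luma weights.
#'
#' @param dataset A `morphotype_dataset`.
#' @param dir Output (or input) directory.
#' @return `write_dataset()`: the manifest data frame, invisibly;
#'   `read_dataset()`: a `morphotype_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "morphotype_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("img%05d.png", seq_along(dataset$images))
  for (i in seq_along(dataset$images)) {
    png::writePNG(dataset$images[[i]], file.path(dir, fn[i]))
  }
  manifest <- data.frame(filename = fn, label = dataset$labels,
                         class = dataset$class_names[dataset$labels])
  if (!is.null(dataset$provenance)) manifest <- cbind(manifest, dataset$provenance)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(manifest$filename, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) {
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    }
    img
  })
  class_names <- if ("class" %in% names(manifest)) {
    unique(manifest$class[order(manifest$label)])
  } else {
    paste0("class", sort(unique(manifest$label)))
  }
  structure(list(images = images, labels = as.integer(manifest$label),
                 class_names = class_names),
            class = "morphotype_dataset")
}
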