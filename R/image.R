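.luminance <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# chromatic excess-green index: 2g - r - b on (r, g, b) = RGB / sum,
# range [-1, 2]; 0 where the pixel is black
.exg <- function(img) {
  tot <- img[, , 1L] + img[, , 2L] + img[, , 3L]
  num <- 2 * img[, , 2L] - img[, , 1L] - img[, , 3L]
  out <- matrix(0, nrow(num), ncol(num))
  nz <- tot > 0
  out[nz] <- num[nz] / tot[nz]
  out
}

.to_ebi <- function(x) {
  if (length(dim(x)) == 3L)
    EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
  else EBImage::Image(t(x))
}

.from_ebi <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) aperm(d, c(2L, 1L, 3L)) else t(d)
}

#' Preprocess and segment a plant image
#'
#' Resizes to the working size (long side, aspect preserved; images
#' already at or below the working size are left alone), applies light
#' Gaussian smoothing, and segments the plant from the background by
#' thresholding the chromatic excess-green index (ExG = 2g - r - b) with
#' Otsu's method, keeping the largest connected foreground component.
#' An HSV hue-band mode is available as an alternative.
#'
#' @param img RGB array (height x width x 3, values in \[0, 1\]) or an
#'   `EBImage` colour image.
#' @param working_size target long-side length in pixels.
#' @param blur_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @param method `"exg"` (default) or `"hsv"` (hue band
#'   `hue_range`, saturation above `min_saturation`).
#' @param hue_range green hue interval in degrees (hsv mode).
#' @param min_saturation minimum saturation (hsv mode).
#' @return List: smoothed `image` (array), logical `mask`, the `exg`
#'   map, the `threshold` used and the foreground pixel count.
#' @export
preprocess_segment <- function(img, working_size = 512L, blur_sigma = 1,
                               method = c("exg", "hsv"),
                               hue_range = c(60, 180),
                               min_saturation = 0.15) {
  method <- match.arg(method)
  if (inherits(img, "Image")) img <- .from_ebi(img)
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("'img' must be an RGB image (height x width x 3)")
  long <- max(dim(img)[1:2])
  if (long > working_size) {
    f <- working_size / long
    e <- EBImage::resize(.to_ebi(img), w = round(dim(img)[2L] * f))
    img <- .from_ebi(e)
  }
  if (blur_sigma > 0)
    img <- .from_ebi(EBImage::gblur(.to_ebi(img), sigma = blur_sigma))
  img <- pmin(pmax(img, 0), 1)
  exg <- .exg(img)
  if (method == "exg") {
    scaled <- (exg + 1) / 3  # ExG in [-1, 2] -> [0, 1] for Otsu
    th <- EBImage::otsu(.to_ebi(scaled))
    mask <- scaled > th
    threshold <- th * 3 - 1
  } else {
    mx <- pmax(img[, , 1L], img[, , 2L], img[, , 3L])
    mn <- pmin(img[, , 1L], img[, , 2L], img[, , 3L])
    delta <- mx - mn
    hue <- matrix(0, nrow(mx), ncol(mx))
    gi <- delta > 0 & mx == img[, , 2L]
    hue[gi] <- 60 * (2 + (img[, , 3L][gi] - img[, , 1L][gi]) / delta[gi])
    ri <- delta > 0 & mx == img[, , 1L] & !gi
    hue[ri] <- (60 * ((img[, , 2L][ri] - img[, , 3L][ri]) / delta[ri])) %% 360
    bi <- delta > 0 & mx == img[, , 3L] & !gi & !ri
    hue[bi] <- 60 * (4 + (img[, , 1L][bi] - img[, , 2L][bi]) / delta[bi])
    sat <- ifelse(mx > 0, delta / mx, 0)
    mask <- hue >= hue_range[1L] & hue <= hue_range[2L] &
      sat >= min_saturation
    threshold <- NA_real_
  }
  if (!any(mask))
    stop("empty segmentation: no foreground pixels above threshold")
  lab <- .from_ebi(EBImage::bwlabel(.to_ebi(mask)))
  tab <- table(lab[lab > 0])
  mask <- lab == as.integer(names(tab)[which.max(tab)])
  list(image = img, mask = mask, exg = exg, threshold = threshold,
       foreground = sum(mask))
}

#' Grey-level co-occurrence texture features
#'
#' GLCM over 8 quantised grey levels (fixed equal-width bins on
#' \[0, 1\]), displacement 1, the four directions 0/45/90/135 degrees
#' accumulated symmetrically and averaged; only pixel pairs fully inside
#' the mask count.  Returns contrast `sum (i-j)^2 p_ij` and entropy
#' `-sum p log2 p` (plus entropy normalised by its maximum,
#' `log2(levels^2)`).  A constant region has a single occupied cell, so
#' contrast and entropy are exactly 0.
#'
#' @param gray numeric matrix in \[0, 1\] (e.g. luminance).
#' @param mask logical matrix; `NULL` uses the whole image.
#' @param levels number of grey levels.
#' @return Named vector: `contrast`, `entropy`, `entropy_norm`.
#' @export
glcm_features <- function(gray, mask = NULL, levels = 8L) {
  stopifnot(is.matrix(gray))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  q <- pmin(floor(gray * levels) + 1L, levels)
  q[!mask] <- NA_integer_
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  P <- matrix(0, levels, levels)
  used <- 0L
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    r1 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
    c1 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1L], c1 + off[2L], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    M <- matrix(0, levels, levels)
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    M <- M + tab + t(tab)  # symmetric accumulation
    P <- P + M / sum(M)
    used <- used + 1L
  }
  if (used == 0L) stop("mask too small for co-occurrence pairs")
  P <- P / used
  ij <- outer(seq_len(levels), seq_len(levels), "-")
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  c(contrast = sum(ij^2 * P),
    entropy = entropy,
    entropy_norm = entropy / log2(levels^2))
}

.erode1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
}

#' Extract the six canonical traits from a segmented plant image
#'
#' Measures, over the segmentation mask:
#' * **LC** — mean chromatic excess-green index, rescaled from
#'   \[-1, 2\] to \[0, 1\];
#' * **LA** — foreground area as a fraction of the canvas;
#' * **TU** — 1 minus the normalised co-occurrence entropy of the
#'   foreground luminance ([glcm_features()]);
#' * **VP** — density of strong second-derivative (ridge-like) luminance
#'   response inside the leaf, a venation-visibility proxy;
#' * **ES** — mean luminance gradient magnitude along the mask boundary,
#'   rescaled to \[0, 1\];
#' * **WI** — 1 minus the ratio of leaf area to its convex-hull area, a
#'   compactness-loss (wilting/curling) proxy.
#'
#' VP, ES and WI have no standard operational definition; the proxies
#' here are explicit, deterministic and monotone in the qualitative
#' property they track, and can be swapped via `extractors`.
#'
#' @param img RGB array (height x width x 3 in \[0, 1\]).
#' @param mask logical segmentation mask of the same height/width.
#' @param plant_id,zone_id,acre_id identifiers for the output record.
#' @param extractors optional named list of replacement trait extractor
#'   functions `(img, mask, lum, exg) -> scalar`.
#' @return One-row trait table data frame.
#' @export
extract_traits <- function(img, mask, plant_id = "plant", zone_id = "Z01",
                           acre_id = "A1", extractors = list()) {
  if (length(dim(img)) != 3L) stop("'img' must be an RGB array")
  if (!is.logical(mask) || !all(dim(mask) == dim(img)[1:2]))
    stop("'mask' must be a logical matrix matching the image")
  if (!any(mask)) stop("empty mask: no foreground pixels")
  lum <- .luminance(img)
  exg <- .exg(img)
  defaults <- list(
    LC = function(img, mask, lum, exg) (mean(exg[mask]) + 1) / 3,
    LA = function(img, mask, lum, exg) sum(mask) / length(mask),
    TU = function(img, mask, lum, exg)
      1 - unname(glcm_features(lum, mask)["entropy_norm"]),
    VP = function(img, mask, lum, exg) {
      core <- .erode1(mask)
      if (!any(core)) return(0)
      lap <- matrix(0, nrow(lum), ncol(lum))
      nr <- nrow(lum); nc <- ncol(lum)
      lap[2:(nr - 1L), 2:(nc - 1L)] <-
        abs(lum[1:(nr - 2L), 2:(nc - 1L)] + lum[3:nr, 2:(nc - 1L)] +
            lum[2:(nr - 1L), 1:(nc - 2L)] + lum[2:(nr - 1L), 3:nc] -
            4 * lum[2:(nr - 1L), 2:(nc - 1L)])
      mean(lap[core] > 0.05)
    },
    ES = function(img, mask, lum, exg) {
      boundary <- mask & !.erode1(mask)
      if (!any(boundary)) return(0)
      nr <- nrow(lum); nc <- ncol(lum)
      gx <- gy <- matrix(0, nr, nc)
      gy[2:(nr - 1L), ] <- (lum[3:nr, ] - lum[1:(nr - 2L), ]) / 2
      gx[, 2:(nc - 1L)] <- (lum[, 3:nc] - lum[, 1:(nc - 2L)]) / 2
      min(1, mean(sqrt(gx[boundary]^2 + gy[boundary]^2)) / sqrt(0.5))
    },
    WI = function(img, mask, lum, exg) {
      pts <- which(mask, arr.ind = TRUE)
      hull <- grDevices::chull(pts[, 2L], pts[, 1L])
      hx <- pts[hull, 2L]; hy <- pts[hull, 1L]
      # shoelace area + half-perimeter + 1: pixel count of a digitised hull
      area <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
      per <- sum(sqrt(diff(c(hx, hx[1L]))^2 + diff(c(hy, hy[1L]))^2))
      hull_px <- area + per / 2 + 1
      max(0, 1 - sum(mask) / max(hull_px, sum(mask)))
    })
  fns <- utils::modifyList(defaults, extractors)
  vals <- vapply(trait_codes(), function(code)
    fns[[code]](img, mask, lum, exg), numeric(1))
  out <- data.frame(plant_id = plant_id, zone_id = zone_id, acre_id = acre_id,
                    t(vals), stringsAsFactors = FALSE)
  names(out)[4:9] <- names(vals)
  out
}

#' Extract traits from a directory of plant images
#'
#' Runs [preprocess_segment()] and [extract_traits()] over every PNG
#' (and TIFF) image in a directory and binds the records into a trait
#' table.  Identifiers are parsed from file names of the form
#' `<acre>_<zone>_<plant>.png` when possible, else the file stem is used
#' as the plant id.
#'
#' @param path directory of images.
#' @param ... passed to [preprocess_segment()].
#' @param verbose log one line per image to stderr.
#' @return Trait table data frame.
#' @export
extract_traits_dir <- function(path, ..., verbose = TRUE) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) stop("no PNG/TIFF images found under '", path, "'")
  rows <- lapply(files, function(f) {
    img <- .read_image(f)
    seg <- preprocess_segment(img, ...)
    stem <- sub("\\.[^.]+$", "", basename(f))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1L]]
    rec <- extract_traits(seg$image, seg$mask,
                          plant_id = stem,
                          zone_id = if (length(parts) >= 3L) parts[2L] else "Z01",
                          acre_id = if (length(parts) >= 3L) parts[1L] else "A1")
    if (verbose)
      message(sprintf("%s: %d fg px, ExG threshold %.3f",
                      basename(f), seg$foreground, seg$threshold))
    rec
  })
  do.call(rbind, rows)
}

.read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE) &&
      requireNamespace("png", quietly = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    return(a[, , 1:3, drop = FALSE])
  }
  .from_ebi(EBImage::readImage(path))
}
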