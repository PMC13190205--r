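#' Default condition profiles for the synthetic field generator
#'
#' Per-condition mean intensities for the six canonical traits and the
#' severity-scaled noise levels.  Healthy and Severe means are the
#' reference healthy/stress trait anchors; Mild means are the per-trait
#' midpoints (no mild anchor is available).  Noise standard deviations
#' grow with severity (0.05 / 0.10 / 0.16) so that within-zone
#' similarity falls as stress increases.
#'
#' @return List with a 3 x 6 `means` matrix (rows Healthy/Mild/Severe)
#'   and a named `sds` vector.
#' @examples
#' default_profiles()$means["Healthy", "LC"]  # 0.92
#' @export
default_profiles <- function() {
  healthy <- c(LC = 0.92, LA = 0.88, TU = 0.90, VP = 0.85, ES = 0.87, WI = 0.12)
  severe <- c(LC = 0.45, LA = 0.41, TU = 0.39, VP = 0.72, ES = 0.36, WI = 0.91)
  means <- rbind(Healthy = healthy,
                 Mild = (healthy + severe) / 2,
                 Severe = severe)
  list(means = means,
       sds = c(Healthy = 0.05, Mild = 0.10, Severe = 0.16))
}

validate_profiles <- function(profiles) {
  if (!is.list(profiles) || !all(c("means", "sds") %in% names(profiles)))
    stop("'profiles' must be a list with 'means' and 'sds'")
  if (!is.matrix(profiles$means) ||
      !identical(rownames(profiles$means), condition_levels()))
    stop("'profiles$means' must have rows Healthy, Mild, Severe")
  if (any(profiles$means < 0 | profiles$means > 1))
    stop("profile means must lie in [0, 1]")
  if (any(profiles$sds < 0)) stop("noise sds must be >= 0")
  invisible(profiles)
}

#' Field experimental design
#'
#' @param n_acres,zones_per_acre,plants_per_zone layout counts (defaults
#'   3 x 10 x 3, i.e. 90 plants).
#' @param proportions named Healthy/Mild/Severe zone proportions per
#'   acre (must sum to 1); each acre receives at least one zone of every
#'   class when it has enough zones.
#' @param assignment optional explicit condition per zone: a character
#'   matrix (`n_acres` x `zones_per_acre`) overriding `proportions`.
#' @return Object of class `pgk_design`.
#' @export
field_design <- function(n_acres = 3L, zones_per_acre = 10L,
                         plants_per_zone = 3L,
                         proportions = c(Healthy = 0.6, Mild = 0.2,
                                         Severe = 0.2),
                         assignment = NULL) {
  if (any(c(n_acres, zones_per_acre, plants_per_zone) < 1L))
    stop("all design counts must be >= 1")
  if (is.null(assignment)) {
    if (abs(sum(proportions) - 1) > 1e-8)
      stop("'proportions' must sum to 1")
    if (!identical(sort(names(proportions)), sort(condition_levels())))
      stop("'proportions' must be named Healthy, Mild, Severe")
  } else {
    if (!is.matrix(assignment) ||
        !all(dim(assignment) == c(n_acres, zones_per_acre)) ||
        !all(assignment %in% condition_levels()))
      stop("'assignment' must be an n_acres x zones_per_acre matrix of condition labels")
  }
  structure(list(n_acres = as.integer(n_acres),
                 zones_per_acre = as.integer(zones_per_acre),
                 plants_per_zone = as.integer(plants_per_zone),
                 proportions = proportions,
                 assignment = assignment),
            class = "pgk_design")
}

# largest-remainder apportionment of zone counts, forcing >= 1 per class
# when the acre has room for it
.zone_counts <- function(props, zones) {
  lv <- condition_levels()
  target <- props[lv] * zones
  cnt <- floor(target)
  rem <- target - cnt
  while (sum(cnt) < zones) {
    k <- which.max(rem)
    cnt[k] <- cnt[k] + 1L
    rem[k] <- -1
  }
  if (zones >= length(lv)) {
    for (k in which(cnt == 0L)) {
      donor <- which.max(cnt)
      cnt[donor] <- cnt[donor] - 1L
      cnt[k] <- 1L
    }
  }
  cnt
}

#' Generate a synthetic multi-acre field trait table
#'
#' Emulates the reference field design: each zone is assigned a
#' condition class; every plant's trait vector is its condition mean
#' plus independent Gaussian perturbations with the condition's noise
#' standard deviation, truncated to \[0, 1\].  Fully reproducible from
#' the seed; the default design yields 90 records (3 acres x 10 zones x
#' 3 plants).
#'
#' @param design a [field_design()].
#' @param profiles condition profiles (see [default_profiles()]).
#' @param seed RNG seed (an integer; `NULL` leaves the RNG state alone).
#' @return Labelled trait table: `plant_id`, `zone_id`, `acre_id`, the
#'   six trait columns and `condition`.
#' @examples
#' rec <- generate_field(seed = 42)
#' nrow(rec)  # 90
#' @export
generate_field <- function(design = field_design(),
                           profiles = default_profiles(),
                           seed = NULL) {
  stopifnot(inherits(design, "pgk_design"))
  validate_profiles(profiles)
  if (!is.null(seed)) set.seed(seed)
  codes <- colnames(profiles$means)
  rows <- vector("list", design$n_acres * design$zones_per_acre)
  ri <- 0L
  for (a in seq_len(design$n_acres)) {
    conds <- if (!is.null(design$assignment)) design$assignment[a, ]
    else {
      cnt <- .zone_counts(design$proportions, design$zones_per_acre)
      sample(rep(condition_levels(), times = cnt))
    }
    for (z in seq_len(design$zones_per_acre)) {
      cond <- conds[z]
      mu <- profiles$means[cond, ]
      sdv <- profiles$sds[cond]
      vals <- matrix(stats::rnorm(design$plants_per_zone * length(codes),
                                  mean = rep(mu, each = design$plants_per_zone),
                                  sd = sdv),
                     nrow = design$plants_per_zone)
      vals <- pmin(pmax(vals, 0), 1)
      colnames(vals) <- codes
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        plant_id = sprintf("A%d_Z%02d_P%d", a, z,
                           seq_len(design$plants_per_zone)),
        zone_id = sprintf("Z%02d", z),
        acre_id = sprintf("A%d", a),
        vals,
        condition = cond,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a synthetic leaf image with known ground truth
#'
#' Draws an elliptical "leaf" of known area and colour on a dark
#' background, with optional additive Gaussian pixel noise — a fixture
#' whose segmentation mask and trait values are known analytically.
#'
#' @param size canvas `c(height, width)` in pixels (>= 64 each).
#' @param radius disk radius, or `c(ry, rx)` semi-axes, in pixels.
#' @param center leaf centre `c(row, col)`; canvas centre by default.
#' @param colour leaf RGB colour in \[0, 1\].
#' @param background background grey level.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param seed RNG seed for the noise.
#' @return List: `image` (height x width x 3 array in \[0, 1\]), logical
#'   `mask`, and `truth` (area in pixels and as a canvas fraction, the
#'   leaf colour, its excess-green index and the noise level).
#' @export
synthetic_leaf_image <- function(size = c(256L, 256L), radius = 50,
                                 center = NULL,
                                 colour = c(0.20, 0.70, 0.25),
                                 background = 0.05, noise_sd = 0,
                                 seed = NULL) {
  if (any(size < 64L)) stop("canvas must be at least 64 x 64")
  if (length(radius) == 1L) radius <- c(radius, radius)
  if (any(radius <= 0)) stop("degenerate leaf shape: radius must be > 0")
  if (is.null(center)) center <- (size + 1) / 2
  if (!is.null(seed)) set.seed(seed)
  rr <- matrix(seq_len(size[1L]), size[1L], size[2L])
  cc <- matrix(seq_len(size[2L]), size[1L], size[2L], byrow = TRUE)
  mask <- ((rr - center[1L]) / radius[1L])^2 +
    ((cc - center[2L]) / radius[2L])^2 <= 1
  if (!any(mask)) stop("degenerate leaf shape: zero area on canvas")
  img <- array(background, c(size, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- colour[ch]
    img[, , ch] <- plane
  }
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)
  tot <- sum(colour)
  exg <- if (tot > 0) (2 * colour[2L] - colour[1L] - colour[3L]) / tot else 0
  list(image = img, mask = mask,
       truth = list(area_px = sum(mask),
                    area_fraction = sum(mask) / prod(size),
                    colour = colour, exg = exg, noise_sd = noise_sd))
}
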