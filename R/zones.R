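#' Mean pairwise similarity among the plants of one zone
#'
#' Computes the mean of the C(n,2) off-diagonal kernel values between
#' the zone's plant graphs — the within-zone consistency score used for
#' health staging.  Healthy zones score high (coherent trait-interaction
#' patterns), stressed zones low.
#'
#' @param graphs list of >= 2 `pgk_graph` objects (one per plant of the
#'   zone).
#' @param sigma RBF bandwidth of the perceptual graph kernel used for
#'   staging (default 0.85, the calibrated staging bandwidth).
#' @param kernel kernel type passed to [gram_matrix()].
#' @param ... further arguments to [gram_matrix()].
#' @return Scalar mean pairwise similarity.
#' @export
zone_similarity <- function(graphs, sigma = 0.85, kernel = "pgk", ...) {
  if (length(graphs) < 2L)
    stop("zone similarity needs at least 2 plants")
  K <- gram_matrix(graphs, kernel = kernel, sigma = sigma, ...)$K
  mean(K[upper.tri(K)])
}

#' Stage a zone from its similarity score
#'
#' Three-way staging by thresholding the mean within-zone similarity:
#' `similarity >= t_healthy` is Healthy, `>= t_mild` Mild Stress,
#' otherwise Severe Stress (boundaries inclusive).  Defaults (0.80,
#' 0.60) are the round-value pair separating the reference staging
#' table.
#'
#' @param similarity numeric vector of zone similarity scores.
#' @param thresholds `c(t_healthy, t_mild)` with `t_healthy > t_mild`.
#' @return Character vector over
#'   `{"Healthy", "Mild Stress", "Severe Stress"}`.
#' @examples
#' classify_zone(c(0.91, 0.72, 0.42))
#' @export
classify_zone <- function(similarity, thresholds = c(0.80, 0.60)) {
  if (length(thresholds) != 2L || !(thresholds[1L] > thresholds[2L]))
    stop("'thresholds' must be c(t_healthy, t_mild) with t_healthy > t_mild")
  ifelse(similarity >= thresholds[1L], "Healthy",
         ifelse(similarity >= thresholds[2L], "Mild Stress", "Severe Stress"))
}

#' Zone-level similarity report for a whole field
#'
#' Runs the full staging pipeline on a trait table: perceptual encoding
#' (normalisation fitted on the supplied records unless a model is
#' given), per-plant deviation graphs, mean pairwise within-zone PGK
#' similarity, and three-way staging.
#'
#' @param records trait table covering >= 2 plants per zone.
#' @param epsilon edge-pruning threshold.
#' @param sigma staging kernel bandwidth.
#' @param stage_thresholds staging cuts passed to [classify_zone()].
#' @param state_thresholds perceptual-state cuts.
#' @param norm optional pre-fitted `pgk_norm`; `"identity"` skips
#'   normalisation (records already on the intensity scale).
#' @param traits trait registry.
#' @return Data frame of class `pgk_zone_report` with one row per
#'   (acre, zone): `acre_id`, `zone_id`, `similarity`, `status` and, when
#'   present in the input, the zone's true `condition`.
#' @export
zone_report <- function(records, epsilon = 0.05, sigma = 0.85,
                        stage_thresholds = c(0.80, 0.60),
                        state_thresholds = c(1 / 3, 2 / 3),
                        norm = NULL, traits = pgk_traits()) {
  validate_trait_records(records, traits)
  P <- if (identical(norm, "identity")) {
    x <- trait_matrix(records, traits)
    if (any(x < 0 | x > 1))
      stop("identity normalisation requires values already in [0, 1]")
    x
  } else {
    if (is.null(norm)) norm <- fit_normalization(records, traits)
    predict(norm, records)
  }
  key <- paste(records$acre_id, records$zone_id, sep = "\r")
  zones <- unique(key)
  sim <- numeric(length(zones))
  cond <- rep(NA_character_, length(zones))
  for (zi in seq_along(zones)) {
    rows <- which(key == zones[zi])
    graphs <- build_graphs(P[rows, , drop = FALSE], epsilon = epsilon,
                           thresholds = state_thresholds)
    sim[zi] <- zone_similarity(graphs, sigma = sigma)
    if ("condition" %in% names(records))
      cond[zi] <- records$condition[rows[1L]]
  }
  out <- data.frame(
    acre_id = sub("\r.*$", "", zones),
    zone_id = sub("^.*\r", "", zones),
    similarity = sim,
    status = classify_zone(sim, stage_thresholds),
    stringsAsFactors = FALSE)
  if ("condition" %in% names(records)) out$condition <- cond
  attr(out, "thresholds") <- stage_thresholds
  attr(out, "sigma") <- sigma
  class(out) <- c("pgk_zone_report", "data.frame")
  out
}

#' Field-level status grid
#'
#' Arranges zone reports into an acre-by-zone grid of health statuses
#' and similarities plus a per-acre summary.
#'
#' @param zones data frame with columns `acre_id`, `zone_id`,
#'   `similarity`, `status` (e.g. a [zone_report()]); each (acre, zone)
#'   may appear once.
#' @return Object of class `pgk_field_report`: `status` and `similarity`
#'   grids (acres x zones) and a `summary` table of status counts per
#'   acre.
#' @export
field_report <- function(zones) {
  if (nrow(zones) == 0L)
    return(structure(list(status = matrix(character(0), 0, 0),
                          similarity = matrix(numeric(0), 0, 0),
                          summary = data.frame()),
                     class = "pgk_field_report"))
  key <- paste(zones$acre_id, zones$zone_id)
  if (anyDuplicated(key))
    stop("duplicate zone in field report: ", key[duplicated(key)][1L])
  acres <- sort(unique(zones$acre_id))
  zids <- unique(zones$zone_id[order(zones$zone_id)])
  grid_s <- matrix(NA_character_, length(acres), length(zids),
                   dimnames = list(acres, zids))
  grid_v <- matrix(NA_real_, length(acres), length(zids),
                   dimnames = list(acres, zids))
  for (i in seq_len(nrow(zones))) {
    grid_s[zones$acre_id[i], zones$zone_id[i]] <- zones$status[i]
    grid_v[zones$acre_id[i], zones$zone_id[i]] <- zones$similarity[i]
  }
  counts <- table(factor(zones$acre_id, levels = acres),
                  factor(zones$status,
                         levels = c("Healthy", "Mild Stress", "Severe Stress")))
  structure(list(status = grid_s, similarity = grid_v,
                 summary = as.data.frame.matrix(counts)),
            class = "pgk_field_report")
}

#' @export
print.pgk_field_report <- function(x, ...) {
  if (nrow(x$status) == 0L) {
    cat("Field report: no zones\n")
    return(invisible(x))
  }
  cat("Field report (acre x zone status grid):\n")
  print(x$status, quote = FALSE)
  cat("\nStatus counts per acre:\n")
  print(x$summary)
  invisible(x)
}

#' @method plot pgk_field_report
#' @export
plot.pgk_field_report <- function(x, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotting a field report requires the 'pheatmap' package")
  pheatmap::pheatmap(x$similarity, cluster_rows = FALSE, cluster_cols = FALSE,
                     display_numbers = x$status,
                     main = "Zone similarity and health status", ...)
  invisible(x)
}
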