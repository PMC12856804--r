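# Data preparation for habitat (presence/pseudoabsence) models: background
# point generation, covariate transforms, collinearity screening, grouped
# fold assignment and AUC scoring. Smoother fitting itself is left to
# standard GAM machinery and is out of scope here.

#' Generate pseudoabsences within the maximum foraging distance
#'
#' Draws `ratio` background points per presence, uniformly *by area* on the
#' spherical cap of radius `max_range_km` centred on the colony: the
#' cosine of the angular distance is uniform on [cos(theta_max), 1], and
#' the bearing uniform on [0, 360).
#'
#' @param presences Tibble of presence fixes (`lat`, `lon`, optionally
#'   `bird_id`).
#' @param colony One-row colony tibble (`lat`, `lon`).
#' @param max_range_km Cap radius: the maximum foraging distance.
#' @param ratio Pseudoabsences per presence.
#' @param seed Integer seed.
#' @return Tibble with `lat`, `lon`, `label` (`"presence"` /
#'   `"pseudoabsence"`) and `bird_id` (NA for pseudoabsences).
#' @export
pseudoabsences <- function(presences, colony, max_range_km, ratio = 3,
                           seed = 1) {
  stopifnot(nrow(presences) >= 1, max_range_km > 0, ratio >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_abs <- ratio * nrow(presences)
  theta_max <- max_range_km / EARTH_RADIUS_KM
  u <- stats::runif(n_abs, cos(theta_max), 1)
  d_km <- acos(u) * EARTH_RADIUS_KM
  brg <- stats::runif(n_abs, 0, 360)
  pts <- destination_point(colony$lon, colony$lat, brg, d_km)
  pres <- presences |>
    dplyr::mutate(label = "presence",
                  bird_id = if ("bird_id" %in% names(presences))
                    .data$bird_id else NA_character_) |>
    dplyr::select("lat", "lon", "label", "bird_id")
  dplyr::bind_rows(
    pres,
    tibble::tibble(lat = pts$lat, lon = pts$lon, label = "pseudoabsence",
                   bird_id = NA_character_)
  )
}

#' Spread-improving covariate transforms
#'
#' Applies log10 to eddy kinetic energy and chlorophyll a and a square root
#' to the SD of sea-surface temperature (their raw distributions are
#' strongly right-skewed). Non-positive values in a log10 target are an
#' error, listing the offending rows.
#'
#' @param points Tibble containing the covariate columns.
#' @param log10_vars,sqrt_vars Character vectors of column names.
#' @return `points` with the named columns transformed.
#' @export
transform_covariates <- function(points,
                                 log10_vars = c("eke", "chla"),
                                 sqrt_vars = "sst_sd") {
  for (v in intersect(log10_vars, names(points))) {
    bad <- which(points[[v]] <= 0)
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "Non-positive values in log10 target '", v, "' at rows: ",
        paste(utils::head(bad, 10), collapse = ", ")))
    }
    points[[v]] <- log10(points[[v]])
  }
  for (v in intersect(sqrt_vars, names(points))) {
    if (any(points[[v]] < 0)) {
      rlang::abort(paste0("Negative values in sqrt target '", v, "'."))
    }
    points[[v]] <- sqrt(points[[v]])
  }
  points
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlation; covariates are visited in order of
#' predictive rank and kept only if |r| with every already-kept covariate
#' is at or below the threshold, so within any correlated pair the
#' higher-ranked covariate survives. Rank-priority processing makes the
#' result independent of column order.
#'
#' @param covariates Data frame of numeric covariate columns.
#' @param predictive_rank Character vector of covariate names, best first.
#' @param r_threshold Absolute correlation above which a pair conflicts.
#' @return Character vector of kept covariate names (in rank order).
#' @export
collinearity_filter <- function(covariates, predictive_rank,
                                r_threshold = 0.6) {
  stopifnot(all(predictive_rank %in% names(covariates)))
  r <- stats::cor(as.data.frame(covariates)[predictive_rank])
  kept <- character(0)
  for (v in predictive_rank) {
    if (all(abs(r[v, kept]) <= r_threshold)) kept <- c(kept, v)
  }
  kept
}

#' Grouped cross-validation folds by bird
#'
#' Assigns each bird (and all its points) to one of `k` folds, so
#' validation is between individuals rather than between autocorrelated
#' points of one bird.
#'
#' @param points Tibble with a `bird_id` column (NA ids, e.g.
#'   pseudoabsences, are spread evenly across folds).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return `points` with an integer `fold` column.
#' @export
bird_folds <- function(points, k = 5, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- unique(points$bird_id[!is.na(points$bird_id)])
  fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
  fold <- fold_of[points$bird_id]
  nas <- is.na(fold)
  fold[nas] <- sample(rep_len(seq_len(k), sum(nas)))
  dplyr::mutate(points, fold = as.integer(fold))
}

#' Rank-based AUC with a performance band
#'
#' Tie-averaged Mann-Whitney estimator of the area under the ROC curve:
#' the probability a random presence is scored above a random absence.
#' The band labels follow the conventional cut-points 0.5-0.7 poor,
#' 0.7-0.9 reasonable, >0.9 very good.
#'
#' @param labels Logical or 0/1 vector (TRUE/1 = presence), or a character
#'   vector with `"presence"` entries.
#' @param scores Numeric prediction scores.
#' @return One-row tibble: `auc`, `band`, `n_pos`, `n_neg`.
#' @export
auc_score <- function(labels, scores) {
  if (is.character(labels)) labels <- labels == "presence"
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("AUC needs both presences and absences.")
  }
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  band <- if (auc > 0.9) "very good"
  else if (auc > 0.7) "reasonable"
  else if (auc >= 0.5) "poor"
  else "worse than chance"
  tibble::tibble(auc = auc, band = band, n_pos = n_pos, n_neg = n_neg)
}
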