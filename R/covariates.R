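# Building the model-ready use-availability table: covariate extraction at
# used and available points, pooled standardization, dummy land-cover coding,
# collinearity screening, and survival interactions.

#' Default continuous covariate names
#' @export
continuous_covariates <- function() {
  c("dist_habitation", "dist_road", "dist_forest_road", "ndvi")
}

#' Build the use-availability table
#'
#' One row per used (GPS relocation) or available (random) point, with all
#' landscape covariates attached, land cover expanded to six indicators, the
#' litter-survival flag (constant within bear-year), and pooled-standardized
#' continuous covariates. Raw covariate values are retained under `raw_*`
#' names for habitat-use summaries.
#'
#' @param bear_years Retained, truncated [bear_year_record()]s with fates.
#' @param availability Named list of availability point matrices (from
#'   [sample_study_availability()]), matched per bear-year.
#' @param landscape A [landscape_stack()].
#' @param standardize Standardize continuous covariates (default TRUE).
#' @return A tibble of class `use_avail_table` with attribute
#'   `standardization` (tibble: `name`, `mean`, `sd` on the raw km / NDVI
#'   scale).
#' @export
build_use_avail_table <- function(bear_years, availability, landscape,
                                  standardize = TRUE) {
  fates <- vapply(bear_years, function(b) b$fate, "")
  if (length(unique(fates[fates %in% c("survived", "lost")])) < 2)
    stop("survival has no variation: need both successful and unsuccessful bear-years")
  rows <- lapply(bear_years, function(b) {
    key <- paste0(b$bear_id, "/", b$year)
    used <- cbind(b$relocations$x, b$relocations$y)
    avail <- availability[[key]]
    if (is.null(avail) || nrow(avail) != nrow(used))
      stop("availability for ", key, " is missing or not matched 1:1")
    ex <- extract_at_points(landscape, rbind(used, avail))
    ex$is_used <- rep(c(1, 0), c(nrow(used), nrow(avail)))
    ex$bear_id <- b$bear_id
    ex$year <- b$year
    ex$survival <- as.numeric(b$fate == "survived")
    ex
  })
  tab <- do.call(rbind, rows)
  cont <- intersect(continuous_covariates(), names(tab))
  for (nm in cont) tab[[paste0("raw_", nm)]] <- tab[[nm]]
  tab <- tab[, c("is_used", "bear_id", "year", "survival", cont,
                 landcover_indicator_classes(), "landcover",
                 paste0("raw_", cont), "x", "y")]
  class(tab) <- c("use_avail_table", class(tab))
  if (standardize) tab <- standardize_covariates(tab, cont)$table
  tab
}

#' Standardize continuous covariates
#'
#' Centres and scales the named columns to pooled mean 0 and variance 1
#' (denominator n - 1), across used and available rows of all bear-years
#' jointly, recording the raw-scale parameters so estimates can be
#' back-transformed and new data projected onto the same scale.
#'
#' @param table A use-availability table (or any data frame).
#' @param names Columns to standardize.
#' @return List with `table` (transformed, attribute `standardization` set)
#'   and `standardization` (tibble: `name`, `mean`, `sd`).
#' @export
standardize_covariates <- function(table, names = continuous_covariates()) {
  names <- intersect(names, colnames(table))
  mu <- vapply(names, function(nm) mean(table[[nm]]), 0)
  sd <- vapply(names, function(nm) stats::sd(table[[nm]]), 0)
  if (any(sd == 0))
    stop("zero variance in: ", paste(names[sd == 0], collapse = ", "))
  for (nm in names) table[[nm]] <- (table[[nm]] - mu[[nm]]) / sd[[nm]]
  std <- tibble::tibble(name = names, mean = unname(mu), sd = unname(sd))
  attr(table, "standardization") <- std
  list(table = table, standardization = std)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from an ordinary least-squares regression of
#' predictor `j` on the remaining predictors. Values at or above 3 are
#' flagged as collinear; exactly collinear predictors report `Inf`.
#'
#' @param table Data frame holding the predictors.
#' @param predictors Character vector of at least two column names.
#' @return Named numeric vector of VIFs with attribute `flagged` (names with
#'   VIF >= 3).
#' @export
compute_vif <- function(table, predictors) {
  stopifnot(length(predictors) >= 2)
  X <- as.data.frame(table[, predictors, drop = FALSE])
  out <- vapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, p), response = p),
                     data = X)
    # exact collinearity triggers a harmless "perfect fit" note in summary()
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  attr(out, "flagged") <- names(out)[out >= 3]
  out
}

#' Append survival-interaction columns
#'
#' For each named covariate, appends `<name>_x_survival` equal to the
#' elementwise product of the covariate and the 0/1 survival flag.
#'
#' @param table Use-availability table with a `survival` column.
#' @param terms Covariate names to interact.
#' @return The table with the interaction columns appended.
#' @export
add_survival_interactions <- function(table, terms) {
  if (!"survival" %in% colnames(table)) stop("no `survival` column")
  missing <- setdiff(terms, colnames(table))
  if (length(missing))
    stop("unknown term(s): ", paste(missing, collapse = ", "))
  for (t in terms)
    table[[paste0(t, "_x_survival")]] <- table[[t]] * table$survival
  table
}

is_distance_term <- function(terms) {
  startsWith(terms, "dist_") | startsWith(terms, "raw_dist_")
}

#' Reverse the sign of distance estimates for reporting
#'
#' Models are fitted on the distance scale, where a negative coefficient on a
#' `dist_` covariate means proximity is selected. For reporting, the signs of
#' distance main effects and their survival interactions are flipped so that
#' positive values read as "selection for" the feature. Standard errors,
#' variance components, likelihood and AICc are untouched; applying the
#' transform twice returns the original fit.
#'
#' @param fit An `rsf_fit` (see [fit_rsf()]).
#' @return A reporting copy of the fit with distance signs reversed and
#'   `sign_reversed` toggled.
#' @export
reverse_distance_signs <- function(fit) {
  flip <- is_distance_term(sub("_x_survival$", "", names(fit$beta)))
  fit$beta[flip] <- -fit$beta[flip]
  fit$sign_reversed <- !isTRUE(fit$sign_reversed)
  fit
}
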