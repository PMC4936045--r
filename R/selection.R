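# Candidate model set, AICc ranking and per-interaction importance by
# systematic exclusion.

#' Build the default candidate model set
#'
#' Fifteen biologically motivated specifications built from three thematic
#' term groups — anthropogenic (`dist_habitation`, `dist_road`,
#' `dist_forest_road`), land cover (the six indicators) and vegetation
#' (`ndvi`):
#' the all-terms model with survival interactions on all terms (the full
#' model), on the anthropogenic terms only, on the land-cover terms only, and
#' with none; each thematic group and each pairwise group union with and
#' without survival interactions on its terms; and the intercept-only null.
#' Terms failing a supplied VIF screen are removed before the set is built.
#'
#' @param groups Named list of character vectors defining the thematic term
#'   groups (defaults above).
#' @param vif Optional named VIF vector (from [compute_vif()]); terms with
#'   VIF >= `vif_cutoff` are dropped from every spec.
#' @param vif_cutoff Collinearity cutoff (default 3).
#' @param random_factors Passed to every [model_spec()].
#' @param specs Optional list of [model_spec()]s overriding the default set
#'   entirely.
#' @return An object of class `candidate_set` (list of `model_spec`s).
#' @export
build_candidate_set <- function(groups = list(
                                  anthropogenic = c("dist_habitation",
                                                    "dist_road",
                                                    "dist_forest_road"),
                                  landcover = landcover_indicator_classes(),
                                  vegetation = "ndvi"),
                                vif = NULL, vif_cutoff = 3,
                                random_factors = c("bear_id", "year"),
                                specs = NULL) {
  if (is.null(specs)) {
    if (!is.null(vif)) {
      drop <- names(vif)[vif >= vif_cutoff]
      groups <- lapply(groups, setdiff, y = drop)
      groups <- groups[vapply(groups, length, 0L) > 0]
    }
    all_terms <- unname(unlist(groups))
    ms <- function(fixed, inter, label)
      model_spec(fixed, inter, random_factors = random_factors, label = label)
    specs <- list(
      ms(all_terms, all_terms, "full: all terms x survival"),
      ms(all_terms, groups$anthropogenic, "all terms, anthropogenic x survival"),
      ms(all_terms, groups$landcover, "all terms, landcover x survival"),
      ms(all_terms, character(), "all terms, no interactions"),
      ms(groups$anthropogenic, groups$anthropogenic, "anthropogenic x survival"),
      ms(groups$anthropogenic, character(), "anthropogenic"),
      ms(groups$landcover, groups$landcover, "landcover x survival"),
      ms(groups$landcover, character(), "landcover"),
      ms(groups$vegetation, groups$vegetation, "vegetation x survival"),
      ms(groups$vegetation, character(), "vegetation"),
      ms(c(groups$anthropogenic, groups$vegetation),
         c(groups$anthropogenic, groups$vegetation),
         "anthropogenic + vegetation x survival"),
      ms(c(groups$anthropogenic, groups$vegetation), character(),
         "anthropogenic + vegetation"),
      ms(c(groups$landcover, groups$vegetation),
         c(groups$landcover, groups$vegetation),
         "landcover + vegetation x survival"),
      ms(c(groups$landcover, groups$vegetation), character(),
         "landcover + vegetation"),
      ms(character(), character(), "null (intercept only)"))
  }
  sig <- vapply(specs, function(s)
    paste(paste(sort(s$fixed_terms), collapse = ","), "|",
          paste(sort(s$interaction_terms), collapse = ",")), "")
  if (anyDuplicated(sig))
    stop("duplicate model specifications in the candidate set")
  structure(specs, class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> of", length(x), "models\n")
  for (s in x) cat("  -", s$label, "\n")
  invisible(x)
}

#' Rank candidate models by AICc
#'
#' Fits every specification with [fit_rsf()], computes AICc differences and
#' Akaike weights, and sorts ascending by AICc. Models with `delta_aicc >= 4`
#' are flagged inconclusive; fit failures are logged and excluded from the
#' ranking rather than aborting it.
#'
#' @param table A use-availability table.
#' @param cset A [build_candidate_set()] result (or list of `model_spec`s).
#' @param ... Passed to [fit_rsf()].
#' @return Tibble of class `selection_table` (`label`, `k`, `loglik`, `aicc`,
#'   `delta_aicc`, `weight`, `inconclusive`), with attributes `fits` (named
#'   list of `rsf_fit`s) and `failures` (tibble of label/reason).
#' @export
rank_models <- function(table, cset, ...) {
  fits <- list(); fails <- list()
  for (s in cset) {
    res <- tryCatch(fit_rsf(table, s, ...), error = function(e) e)
    if (inherits(res, "error"))
      fails[[length(fails) + 1L]] <- tibble::tibble(label = s$label,
                                                    reason = conditionMessage(res))
    else fits[[s$label]] <- res
  }
  if (!length(fits)) stop("all candidate model fits failed")
  tab <- tibble::tibble(
    label = names(fits),
    k = unname(vapply(fits, function(f) f$k, 0L)),
    loglik = unname(vapply(fits, function(f) f$loglik, 0)),
    aicc = unname(vapply(fits, function(f) f$aicc, 0)))
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$weight <- akaike_weights(tab$aicc)
  tab$inconclusive <- tab$delta_aicc >= 4
  class(tab) <- c("selection_table", class(tab))
  attr(tab, "fits") <- fits
  attr(tab, "failures") <- if (length(fails)) do.call(rbind, fails)
                           else tibble::tibble(label = character(),
                                               reason = character())
  tab
}

#' Per-interaction importance by systematic exclusion
#'
#' For each survival interaction in the reference model, refits the model
#' without that interaction (keeping the covariate's main effect) and records
#' `delta_aicc_diff = AICc(full) - AICc(reduced)`; negative values support
#' keeping the interaction. `reported_importance` is the sign-reversed value
#' (high = important), and a term is conclusive when it reaches 4.
#'
#' @param table A use-availability table.
#' @param best_spec The reference [model_spec()] (must contain at least one
#'   interaction).
#' @param full_fit Optional pre-computed fit of `best_spec`.
#' @param ... Passed to [fit_rsf()].
#' @return Tibble of class `importance_table`, sorted by
#'   `reported_importance` descending: `term`, `estimate`, `se`,
#'   `delta_aicc_diff`, `reported_importance`, `conclusive`, `evaluable`.
#' @export
interaction_importance <- function(table, best_spec, full_fit = NULL, ...) {
  if (!length(best_spec$interaction_terms))
    stop("the reference model contains no survival interactions")
  if (is.null(full_fit)) full_fit <- fit_rsf(table, best_spec, ...)
  rows <- lapply(best_spec$interaction_terms, function(term) {
    red_spec <- model_spec(best_spec$fixed_terms,
                           setdiff(best_spec$interaction_terms, term),
                           random_factors = best_spec$random_factors,
                           include_survival_main = TRUE,
                           label = paste0("full minus ", term, " x survival"))
    red <- tryCatch(fit_rsf(table, red_spec, ...), error = function(e) NULL)
    coefn <- paste0(term, "_x_survival")
    est <- unname(full_fit$beta[coefn])
    se <- unname(full_fit$se[names(full_fit$beta) == coefn])
    if (is.null(red))
      tibble::tibble(term = term, estimate = est, se = se,
                     delta_aicc_diff = NA_real_,
                     reported_importance = NA_real_,
                     conclusive = NA, evaluable = FALSE)
    else
      tibble::tibble(term = term, estimate = est, se = se,
                     delta_aicc_diff = full_fit$aicc - red$aicc,
                     reported_importance = -(full_fit$aicc - red$aicc),
                     conclusive = -(full_fit$aicc - red$aicc) >= 4,
                     evaluable = TRUE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$reported_importance), ]
  class(tab) <- c("importance_table", class(tab))
  attr(tab, "full_fit") <- full_fit
  tab
}
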