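# Paper-style outputs: per-group coefficient estimates with 95% intervals,
# interaction-importance bars, and habitat-use summaries.

#' Per-group coefficient report
#'
#' Unsuccessful mothers' selection is given by the landscape main effects of
#' the fitted model; successful mothers' by main effect + survival
#' interaction, with the standard error of the sum taken from the joint
#' coefficient covariance. Distance signs are reversed for display so that
#' positive values read "selection for". Intervals are `beta +/- 1.96 se`.
#'
#' @param fit A converged `rsf_fit`.
#' @param z Interval half-width multiplier in standard errors (default the
#'   conventional 1.96).
#' @return List with `table` (tibble: `term`, `group`, `estimate`, `se`,
#'   `lower`, `upper`, on the reporting scale) and `plot` (ggplot).
#' @export
report_coefficients <- function(fit, z = 1.96) {
  if (!fit$converged) warning("reporting a fit that did not converge")
  zc <- z
  terms <- names(fit$beta)
  mains <- setdiff(terms, c("(Intercept)", "survival",
                            grep("_x_survival$", terms, value = TRUE)))
  rows <- lapply(mains, function(m) {
    i <- match(m, terms)
    int <- paste0(m, "_x_survival")
    j <- match(int, terms)
    est_u <- fit$beta[[i]]; se_u <- sqrt(fit$vcov[i, i])
    if (!is.na(j)) {
      est_s <- fit$beta[[i]] + fit$beta[[j]]
      se_s <- sqrt(fit$vcov[i, i] + fit$vcov[j, j] + 2 * fit$vcov[i, j])
    } else {
      est_s <- est_u; se_s <- se_u
    }
    sgn <- if (is_distance_term(m)) -1 else 1
    tibble::tibble(term = m,
                   group = c("unsuccessful", "successful"),
                   estimate = sgn * c(est_u, est_s),
                   se = c(se_u, se_s))
  })
  tab <- do.call(rbind, rows)
  tab$lower <- tab$estimate - zc * tab$se
  tab$upper <- tab$estimate + zc * tab$se
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term,
                                         colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_colour_manual(values = c(successful = "black",
                                            unsuccessful = "grey50")) +
    ggplot2::labs(x = "selection coefficient (sign-reversed distances)",
                  y = NULL, colour = "litter fate") +
    ggplot2::theme_minimal()
  list(table = tab, plot = p)
}

#' Interaction-importance report
#'
#' Bar chart of `reported_importance` (sign-reversed AICc change on removing
#' each survival interaction), sorted descending, with the conclusiveness
#' threshold at 4.
#'
#' @param imp An `importance_table` from [interaction_importance()].
#' @return List with `table` and `plot`.
#' @export
report_importance <- function(imp) {
  stopifnot(nrow(imp) > 0)
  tab <- imp[order(-imp$reported_importance), ]
  tab$term <- factor(tab$term, levels = rev(tab$term))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$reported_importance,
                                         y = .data$term)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_vline(xintercept = 4, linetype = 2) +
    ggplot2::labs(x = expression(-Delta * AICc[diff]), y = NULL) +
    ggplot2::theme_minimal()
  list(table = tab, plot = p)
}

#' Habitat-use summaries
#'
#' Raw-scale medians of the continuous covariates and land-cover class
#' proportions, per litter-fate group and response class (used vs available).
#'
#' @param table A use-availability table carrying `raw_*` columns.
#' @return Tibble with one row per group x response class; median columns
#'   (`median_*`, raw scale) and one proportion column per land-cover class.
#' @export
use_summaries <- function(table) {
  stopifnot(nrow(table) > 0)
  raw <- grep("^raw_", colnames(table), value = TRUE)
  cells <- expand.grid(survival = c(0, 1), is_used = c(1, 0))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$survival == cells$survival[i] &
                   table$is_used == cells$is_used[i], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    out <- tibble::tibble(
      group = if (cells$survival[i] == 1) "successful" else "unsuccessful",
      class = if (cells$is_used[i] == 1) "used" else "available",
      n = nrow(sub))
    for (r in raw)
      out[[sub("^raw_", "median_", r)]] <- stats::median(sub[[r]])
    for (cl in landcover_classes())
      out[[paste0("prop_", cl)]] <- mean(sub$landcover == cl)
    out
  })
  do.call(rbind, rows)
}
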