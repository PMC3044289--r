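# Pharmacological re-scoring.
#
# combined_i = E_total_i + sum over channels I of E(I)_pharma_i,
# E(I)_pharma_i = sum_j max(W_j, 0) * e_ij(I):
# the docked energy plus the compound's energy at pharmacologically
# preferred residue groups, weighted by the preference.  Negative
# preferences are clamped to zero so anti-conserved contacts are neither
# rewarded nor punished.  Lower scores are better.

#' Pharmacological score of screening compounds
#'
#' @param decomp an `energy_decomposition` covering one pose per compound
#'   (use `pose_policy = "best"` in [batch_decompose()]).
#' @param prefs a `preference_table` covering the channels to use; a table
#'   holding several channels (stacked rows with a `type` column) applies
#'   each channel's preferences to its own energies.  Channels absent from
#'   `prefs` contribute 0.
#' @return a `pharma_scores` tibble: `compound_id`, `pose_index`,
#'   `E_total`, `E_pharma_E`, `E_pharma_H`, `E_pharma_V`, `combined`.
#' @export
score_compounds <- function(decomp, prefs) {
  dd <- tibble::as_tibble(decomp)
  if (anyDuplicated(dplyr::distinct(dd, .data$compound_id,
                                    .data$pose_index)$compound_id)) {
    abort("decomposition has several poses per compound; keep one per compound before scoring")
  }
  pw <- tibble::as_tibble(prefs)[, c("type", "group", "w")]
  unknown <- setdiff(unique(pw$group), unique(dd$label))
  if (length(unknown) > 0) {
    abort(paste0("preference groups not present in the decomposition: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  scored <- dd |>
    dplyr::left_join(pw, by = c("type" = "type", "label" = "group")) |>
    dplyr::mutate(w = dplyr::coalesce(.data$w, 0),
                  contrib = pmax(.data$w, 0) * .data$energy)
  per_channel <- scored |>
    dplyr::group_by(.data$compound_id, .data$pose_index, .data$total,
                    .data$type) |>
    dplyr::summarise(pharma = sum(.data$contrib), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type", values_from = "pharma",
                       names_prefix = "E_pharma_",
                       values_fill = 0)
  for (col in c("E_pharma_E", "E_pharma_H", "E_pharma_V")) {
    if (!col %in% names(per_channel)) per_channel[[col]] <- 0
  }
  out <- per_channel |>
    dplyr::rename(E_total = "total") |>
    dplyr::mutate(combined = .data$E_total + .data$E_pharma_E +
                    .data$E_pharma_H + .data$E_pharma_V) |>
    dplyr::select("compound_id", "pose_index", "E_total", "E_pharma_E",
                  "E_pharma_H", "E_pharma_V", "combined")
  structure(out, class = c("pharma_scores", class(out)))
}

#' Rank compounds by energy and by pharmacological score
#'
#' Adds two 1-based rankings, both ascending (lower = better): `rank_energy`
#' by docked total energy and `rank_pharma` by the combined pharmacological
#' score.  Ties are broken lexicographically by compound id, so ranks are
#' always distinct.
#'
#' @param scores a `pharma_scores` tibble (see [score_compounds()]).
#' @return `scores` with `rank_energy` and `rank_pharma` columns, ordered
#'   by `rank_pharma`.
#' @export
rank_compounds <- function(scores) {
  if (nrow(scores) == 0) abort("no scores to rank")
  s <- tibble::as_tibble(scores)
  ord_e <- order(s$E_total, s$compound_id)
  ord_p <- order(s$combined, s$compound_id)
  s$rank_energy <- integer(nrow(s)); s$rank_pharma <- integer(nrow(s))
  s$rank_energy[ord_e] <- seq_len(nrow(s))
  s$rank_pharma[ord_p] <- seq_len(nrow(s))
  s <- dplyr::arrange(s, .data$rank_pharma)
  structure(s, class = c("pharma_scores", class(s)))
}

#' One-row summary of a score table
#' @param x a `pharma_scores` tibble.
#' @param ... ignored.
#' @return one-row tibble with compound count and score ranges.
#' @method glance pharma_scores
#' @export
glance.pharma_scores <- function(x, ...) {
  tibble::tibble(n_compounds = nrow(x),
                 best_energy = min(x$E_total),
                 best_combined = min(x$combined),
                 mean_pharma_term = mean(x$E_pharma_E + x$E_pharma_H +
                                           x$E_pharma_V))
}

#' Energy rank vs pharmacological rank scatter
#'
#' @param object a ranked `pharma_scores` tibble (see [rank_compounds()]).
#' @param highlight optional character vector of compound ids (e.g. known
#'   actives) drawn in colour.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot pharma_scores
#' @export
autoplot.pharma_scores <- function(object, highlight = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!all(c("rank_energy", "rank_pharma") %in% names(df))) {
    df <- rank_compounds(df)
  }
  df$highlight <- df$compound_id %in% (highlight %||% character())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_energy,
                                   y = .data$rank_pharma,
                                   colour = .data$highlight)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "energy rank", y = "pharmacological rank") +
    ggplot2::theme_minimal()
}
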