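#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.tier_palette <- c(high = "#c0392b", moderate = "#e67e22", low = "#f1c40f",
                   unresolved = "grey70")

#' Plot a patient's per-medication contributions
#'
#' Bar chart of points per medication, coloured by risk tier, with the
#' patient total in the title. Unresolved medications are shown at zero.
#'
#' @param object An `mrf_patient_score`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrf_patient_score
#' @export
autoplot.mrf_patient_score <- function(object, ...) {
  e <- tidy(object)
  e$tier_shown <- ifelse(is.na(e$tier), "unresolved", e$tier)
  e$tier_shown <- factor(e$tier_shown, levels = names(.tier_palette))
  ggplot2::ggplot(e, ggplot2::aes(
    x = stats::reorder(.data$raw_name, .data$contribution),
    y = .data$contribution, fill = .data$tier_shown
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = .tier_palette, drop = FALSE,
                               name = "risk tier") +
    ggplot2::labs(
      title = sprintf("MRF score: %d point%s", object$total,
                      if (object$total == 1L) "" else "s"),
      subtitle = if (isTRUE(object$referral_flag)) {
        "referral advised (high- or moderate-risk medication present)"
      } else "no referral trigger",
      x = NULL, y = "points contributed"
    )
}

#' Plot a Delphi round's item statistics and verdicts
#'
#' Shows each item's median with its interquartile range (P25-P75) and the
#' verdict colour-coded, with the inclusion gate (P25 >= 4) marked as a
#' dashed line.
#'
#' @param object An `mrf_round_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrf_round_result
#' @export
autoplot.mrf_round_result <- function(object, ...) {
  d <- object$decisions
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$item_id, .data$median),
    colour = .data$verdict
  )) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                            linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 2) +
    ggplot2::geom_hline(yintercept = 4, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(retain = "#27ae60",
                                            modify = "#e67e22",
                                            exclude = "#c0392b"), drop = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::ylim(1, 5) +
    ggplot2::labs(
      title = sprintf("Delphi round %d of %d%s", object$round_number,
                      object$max_rounds, if (object$final_round) " (final)" else ""),
      x = NULL, y = "Likert response (median, P25-P75)",
      caption = "dashed line: inclusion gate (median and P25 at or above 4)"
    )
}
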