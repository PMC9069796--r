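#' Define a rating-scale instrument
#'
#' An instrument bundles the fixed facts about a questionnaire: its item
#' labels, the ordered response categories, which items are reverse-keyed,
#' and the classical point maps used to turn category codes into 0-3 scores.
#' Defaults describe the 26-item Eating Attitudes Test (EAT-26): six
#' frequency categories from "Never" (code 1) to "Always" (code 6), items
#' 1-25 keyed forward (Always = 3, Usually = 2, Often = 1, else 0), item 26
#' reverse-keyed with the mirrored map, and a referral cutoff of 20 on the
#' total score.
#'
#' Category codes run low-to-high endorsement throughout the package:
#' code 1 is always the first label ("Never"), code `n_categories` the last.
#'
#' @param item_ids Character vector of item labels, in instrument order.
#' @param n_categories Number of ordered response categories (>= 2).
#' @param category_labels Category labels, low to high endorsement; length
#'   must equal `n_categories`.
#' @param reverse_items Character vector of reverse-keyed item ids.
#' @param score_map_forward Integer points awarded to each category code for
#'   forward-keyed items.
#' @param score_map_reverse Points for reverse-keyed items; defaults to the
#'   mirror of the forward map.
#' @param referral_cutoff Total score at or above which the referral flag is
#'   raised.
#' @return An object of class `"instrument"`.
#' @examples
#' inst <- eat26_instrument()
#' inst$score_map_forward  # 0 0 0 1 2 3
#' @export
instrument <- function(item_ids = paste0("Q", 1:26),
                       n_categories = 6L,
                       category_labels = c("Never", "Rarely", "Sometimes",
                                           "Often", "Usually", "Always"),
                       reverse_items = "Q26",
                       score_map_forward = c(0L, 0L, 0L, 1L, 2L, 3L),
                       score_map_reverse = rev(score_map_forward),
                       referral_cutoff = 20L) {
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("an instrument needs at least 2 categories", call. = FALSE)
  if (length(category_labels) != n_categories)
    stop("length(category_labels) must equal n_categories", call. = FALSE)
  if (anyDuplicated(item_ids)) stop("duplicate item ids", call. = FALSE)
  if (!all(reverse_items %in% item_ids))
    stop("reverse_items must be a subset of item_ids", call. = FALSE)
  for (map in list(forward = score_map_forward, reverse = score_map_reverse)) {
    if (length(map) != n_categories)
      stop("score maps must assign points to every category", call. = FALSE)
    if (any(map != as.integer(map)) || any(map < 0) || any(map > 3))
      stop("score points must be non-negative integers <= 3", call. = FALSE)
  }
  structure(list(
    item_ids = as.character(item_ids),
    n_categories = n_categories,
    category_labels = as.character(category_labels),
    reverse_items = as.character(reverse_items),
    score_map_forward = as.integer(score_map_forward),
    score_map_reverse = as.integer(score_map_reverse),
    referral_cutoff = as.integer(referral_cutoff)
  ), class = "instrument")
}

#' @rdname instrument
#' @export
eat26_instrument <- function() instrument()

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument> %d items, %d categories (%s ... %s)\n",
              length(x$item_ids), x$n_categories,
              x$category_labels[1], x$category_labels[x$n_categories]))
  if (length(x$reverse_items))
    cat("  reverse-keyed:", paste(x$reverse_items, collapse = ", "), "\n")
  cat("  referral cutoff:", x$referral_cutoff, "\n")
  invisible(x)
}
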