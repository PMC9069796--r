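#' Classical EAT-26 scoring
#'
#' Applies the instrument's 0-3 point maps to a six-category response matrix
#' and sums the item points. Forward-keyed items score Always = 3,
#' Usually = 2, Often = 1 and Sometimes/Rarely/Never = 0; reverse-keyed items
#' (item 26 on the EAT-26) use the mirrored map. A person with any missing
#' scored cell gets an undefined total (`NA`) and is flagged incomplete
#' rather than imputed.
#'
#' @param rm A [response_matrix()] on the instrument's category scale.
#' @param inst An [instrument()]; must match `rm$n_categories`.
#' @return A data frame with one row per person: `person_id`, `total`,
#'   `referral_flag` (`total >= referral_cutoff`), `complete`, then one
#'   point column per item.
#' @export
score_eat26 <- function(rm, inst = eat26_instrument()) {
  if (rm$n_categories != inst$n_categories)
    stop("response matrix has ", rm$n_categories,
         " categories; instrument defines ", inst$n_categories, call. = FALSE)
  if (!all(inst$item_ids %in% rm$items))
    stop("response matrix lacks instrument item(s): ",
         paste(setdiff(inst$item_ids, rm$items), collapse = ", "), call. = FALSE)
  pts <- sapply(inst$item_ids, function(it) {
    map <- if (it %in% inst$reverse_items) inst$score_map_reverse else inst$score_map_forward
    map[rm$X[, it]]
  })
  if (nrow(rm$X) == 1L) pts <- matrix(pts, nrow = 1L)
  colnames(pts) <- inst$item_ids
  complete <- !apply(is.na(pts), 1L, any)
  total <- ifelse(complete, rowSums(pts), NA_integer_)
  out <- data.frame(person_id = rm$persons,
                    total = total,
                    referral_flag = total >= inst$referral_cutoff,
                    complete = complete,
                    check.names = FALSE)
  cbind(out, as.data.frame(pts, check.names = FALSE))
}

#' Recode a response matrix for Rasch calibration
#'
#' `"six_category"` keeps the raw six Likert categories (the default used in
#' the calibration workflow). `"scored_four_category"` collapses codes
#' through the classical 0-3 point maps into four ordered categories
#' (points + 1), offered for sensitivity analysis: on forward items the
#' three lowest-frequency codes collapse to category 1.
#'
#' @param rm A [response_matrix()].
#' @param mode `"six_category"` or `"scored_four_category"`.
#' @param inst The [instrument()] supplying the point maps.
#' @return A [response_matrix()]; unchanged for `"six_category"`.
#' @export
collapse_for_rasch <- function(rm, mode = c("six_category", "scored_four_category"),
                               inst = eat26_instrument()) {
  mode <- match.arg(mode)
  if (mode == "six_category") return(rm)
  if (rm$n_categories != inst$n_categories)
    stop("collapse requires a matrix on the instrument's category scale",
         call. = FALSE)
  X <- rm$X
  for (it in intersect(rm$items, inst$item_ids)) {
    map <- if (it %in% inst$reverse_items) inst$score_map_reverse else inst$score_map_forward
    X[, it] <- map[rm$X[, it]] + 1L
  }
  m_new <- max(inst$score_map_forward, inst$score_map_reverse) + 1L
  response_matrix(X, m_new, persons = rm$persons, items = rm$items,
                  covariates = rm$covariates)
}
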