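#' Wright item-person map
#'
#' Bins non-extreme person measures and item difficulties on a common
#' logit scale and renders the classic monospace map: persons as `#`
#' blocks (one `#` per `persons_per_symbol` persons, `.` for a remainder)
#' on the left, item labels on the right, with `M` at each facet's mean
#' and `S` / `T` at one and two standard deviations.
#'
#' @param fit An [fit_jmle()] result.
#' @param bin_width Bin width in logits (default 0.1).
#' @param persons_per_symbol Persons represented by one `#`; defaults to
#'   `ceiling(n / 50)`.
#' @return An object of class `"wright_map"`: `bins` (data frame of bin
#'   centers, person counts, item labels, marker columns) and `text`
#'   (character vector of rendered lines, top = high logits). Printed via
#'   `cat(text)`.
#' @export
wright_map <- function(fit, bin_width = 0.1, persons_per_symbol = NULL) {
  stopifnot(inherits(fit, "rsm_fit"), bin_width > 0)
  pm <- fit$measure[fit$active_persons]
  di <- fit$difficulty[fit$active_items]
  lo <- floor(min(c(pm, di)) / bin_width) * bin_width
  hi <- ceiling(max(c(pm, di)) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE), 1L),
                             length(centers))
  pcount <- tabulate(bin_of(pm), nbins = length(centers))
  ibins <- bin_of(di)
  ilab <- vapply(seq_along(centers), function(b)
    paste(names(di)[ibins == b], collapse = " "), character(1))
  unit <- persons_per_symbol %||% max(1L, ceiling(length(pm) / 50))
  marker <- function(x, b) {
    mk <- rep("", length(centers))
    mu <- mean(x); s <- stats::sd(x)
    put <- function(v, ch) {
      i <- bin_of(v)
      mk[i] <<- if (nzchar(mk[i])) paste0(mk[i], ch) else ch
    }
    put(mu, "M")
    put(mu - s, "S"); put(mu + s, "S")
    put(mu - 2 * s, "T"); put(mu + 2 * s, "T")
    mk
  }
  pmark <- marker(pm, bin_of)
  imark <- marker(di, bin_of)
  bins <- data.frame(center = centers, persons = pcount,
                     person_marker = pmark, item_marker = imark,
                     items = ilab)
  glyph <- function(cnt) {
    paste0(strrep("#", cnt %/% unit), if (cnt %% unit) "." else "")
  }
  width <- max(nchar(vapply(pcount, glyph, character(1))), 6L)
  lines <- vapply(rev(seq_along(centers)), function(b) {
    sprintf("%7.2f %*s %2s|%-2s %s", centers[b], width, glyph(pcount[b]),
            pmark[b], imark[b], ilab[b])
  }, character(1))
  header <- sprintf("%7s %*s   |   (each '#' = %d person%s)", "logit",
                    width, "persons", unit, if (unit > 1) "s" else "")
  structure(list(bins = bins, bin_width = bin_width,
                 persons_per_symbol = unit,
                 n_persons = length(pm), n_items = length(di),
                 text = c(header, lines)),
            class = "wright_map")
}

#' @export
print.wright_map <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
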