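#' Clinical interval schemes
#'
#' PD-L1 TPS reporting uses three clinical categories (<1\%, 1-49\%,
#' >=50\%), but scores close to the 1\% and 50\% cut-offs are the known
#' clusters of inter-observer disagreement. The routing scheme therefore
#' partitions \[0, 100\] into five bands: scores in the two "unconfident"
#' bands around the cut-offs must be reviewed and manually scored by the
#' reporting pathologist; the rest are auto-reported pending confirmation.
#'
#' Bands are half-open `[lo, hi)`, with the last band closed at 100.
#'
#' @param edges strictly increasing breakpoints inside (0, 100); the
#'   default `c(1, 5, 40, 60)` yields bands \[0,1), \[1,5), \[5,40),
#'   \[40,60), \[60,100\].
#' @param labels band labels, one more than `edges`.
#' @param review logical per band: does the band require manual review?
#' @return an object of class `interval_scheme`.
#' @export
interval_scheme <- function(edges = c(1, 5, 40, 60),
                            labels = c("confident_negative",
                                       "unconfident_low",
                                       "confident_mid",
                                       "unconfident_high",
                                       "confident_positive"),
                            review = c(FALSE, TRUE, FALSE, TRUE, FALSE)) {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 100)) {
    stop("band edges must be strictly increasing and inside (0, 100)",
         call. = FALSE)
  }
  if (length(labels) != length(edges) + 1L ||
      length(review) != length(labels)) {
    stop("need one label and one review flag per band (edges + 1)",
         call. = FALSE)
  }
  structure(
    list(edges = edges, labels = labels, review = as.logical(review),
         actions = ifelse(review, "manual_review_required",
                          "auto_report_pending_confirmation")),
    class = "interval_scheme"
  )
}

#' @rdname interval_scheme
#' @export
default_scheme <- function() interval_scheme()

#' @export
print.interval_scheme <- function(x, ...) {
  lo <- c(0, x$edges); hi <- c(x$edges, 100)
  for (i in seq_along(x$labels)) {
    cat(sprintf("  [%g, %g%s  %-20s %s\n", lo[i], hi[i],
                if (i == length(x$labels)) "]" else ")",
                x$labels[i], x$actions[i]))
  }
  invisible(x)
}

#' Clinical TPS category
#'
#' The three reporting categories for NSCLC PD-L1, with cut-offs at 1 and
#' 50: `<1%` (negative), `1-49%` (low expression), `>=50%` (high).
#'
#' @param tps score(s) in \[0, 100\].
#' @return character vector of categories.
#' @export
clinical_category <- function(tps) {
  if (any(tps < 0 | tps > 100, na.rm = TRUE)) {
    stop("TPS must lie in [0, 100]", call. = FALSE)
  }
  ifelse(tps < 1, "<1%", ifelse(tps < 50, "1-49%", ">=50%"))
}

#' Assign a TPS score to its routing band
#'
#' Looks up the band of `tps` under the half-open convention, derives the
#' clinical category (always from the cut-offs 1 and 50, independent of the
#' band edges), and attaches the band's action.
#'
#' @param tps a single score in \[0, 100\].
#' @param scheme an [interval_scheme()] (default [default_scheme()]).
#' @return an object of class `interval_decision` with fields
#'   `tps_percent`, `band`, `category`, `action`.
#' @export
assign_interval <- function(tps, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "interval_scheme"), length(tps) == 1L)
  if (is.na(tps) || tps < 0 || tps > 100) {
    stop("TPS must be a single value in [0, 100]", call. = FALSE)
  }
  band_idx <- findInterval(tps, scheme$edges) + 1L
  structure(
    list(tps_percent = as.numeric(tps),
         band = scheme$labels[band_idx],
         category = clinical_category(tps),
         action = scheme$actions[band_idx]),
    class = "interval_decision"
  )
}

#' @export
print.interval_decision <- function(x, ...) {
  cat(sprintf("TPS %.2f%% -> band %s, clinical category %s\n  action: %s\n",
              x$tps_percent, x$band, x$category, x$action))
  invisible(x)
}

#' Finalise a case under the human-in-the-loop workflow
#'
#' Confident-band cases are finalised with the algorithm's score (pending
#' pathologist confirmation); unconfident-band cases are blocked until a
#' pathologist supplies the score manually. The finalised record carries a
#' provenance flag.
#'
#' @param decision an [assign_interval()] decision.
#' @param pathologist_score optional manually entered score in \[0, 100\];
#'   mandatory to finalise a case whose action is `manual_review_required`.
#' @return a list with `status` ("finalized" or "pending_review"),
#'   `final_score`, `final_category`, `provenance` (one of "algorithm",
#'   "pathologist_confirmed", "pathologist_overridden") and the original
#'   `decision`.
#' @export
route_case <- function(decision, pathologist_score = NULL) {
  stopifnot(inherits(decision, "interval_decision"))
  if (!is.null(pathologist_score)) {
    if (pathologist_score < 0 || pathologist_score > 100) {
      stop("pathologist score must lie in [0, 100]", call. = FALSE)
    }
  }
  if (identical(decision$action, "manual_review_required") &&
      is.null(pathologist_score)) {
    return(list(status = "pending_review", final_score = NA_real_,
                final_category = NA_character_, provenance = NA_character_,
                decision = decision))
  }
  final <- if (is.null(pathologist_score)) decision$tps_percent
           else as.numeric(pathologist_score)
  provenance <- if (is.null(pathologist_score)) {
    "algorithm"
  } else if (isTRUE(all.equal(final, decision$tps_percent))) {
    "pathologist_confirmed"
  } else {
    "pathologist_overridden"
  }
  list(status = "finalized", final_score = final,
       final_category = clinical_category(final),
       provenance = provenance, decision = decision)
}
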