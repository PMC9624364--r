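#' Flag changes between control and treated groups
#'
#' Builds a summary-of-findings table: for each (region, sex, metric) cell
#' with a control (`ct`) and treated (`sr`) value, a change flag is emitted:
#' `"appeared"` when the control value is exactly zero and the treated value
#' positive, `"disappeared"` in the symmetric case, `"up"`/`"down"` when the
#' relative change `(sr - ct)/|ct|` reaches `min_rel_change`, and
#' `"unchanged"` otherwise. Cells with a missing group are flagged
#' `"missing"`. The values are carried verbatim into the output.
#'
#' @param x Data.frame with columns `region`, `sex`, `metric`, `ct`, `sr`.
#' @param min_rel_change Relative-change threshold for `"up"`/`"down"`
#'   (default 0.1, i.e. 10%); recorded in the output.
#' @return `x` with added columns `rel_change`, `flag` and `threshold`.
#' @export
compare_groups <- function(x, min_rel_change = 0.1) {
  req <- c("region", "sex", "metric", "ct", "sr")
  stopifnot(all(req %in% names(x)))
  ct <- x$ct; sr <- x$sr
  rel <- ifelse(!is.na(ct) & ct != 0, (sr - ct) / abs(ct), NA_real_)
  flag <- rep("unchanged", nrow(x))
  flag[!is.na(rel) & rel >= min_rel_change] <- "up"
  flag[!is.na(rel) & rel <= -min_rel_change] <- "down"
  flag[!is.na(ct) & !is.na(sr) & ct == 0 & sr > 0] <- "appeared"
  flag[!is.na(ct) & !is.na(sr) & sr == 0 & ct > 0] <- "disappeared"
  flag[is.na(ct) | is.na(sr)] <- "missing"
  x$rel_change <- rel
  x$flag <- flag
  x$threshold <- min_rel_change
  x
}

#' Select high-confidence predicted target genes
#'
#' Retains prediction rows with score strictly greater than `score_cutoff`
#' (default 80, the conventional high-confidence threshold of target
#' prediction scores on a 0-100 scale) and returns the deduplicated,
#' case-normalised set of target gene symbols. Rows with scores outside
#' \[0, 100\] are rejected with a warning.
#'
#' @param predictions Data.frame with columns `gene` and `score` (an
#'   optional `fragment_id` column identifies the predicting fragment).
#' @param score_cutoff Strict lower bound on retained scores (default 80).
#' @return Sorted character vector of unique upper-cased gene symbols.
#' @export
filter_targets <- function(predictions, score_cutoff = 80) {
  stopifnot(all(c("gene", "score") %in% names(predictions)))
  bad <- is.na(predictions$score) | predictions$score < 0 |
    predictions$score > 100
  if (any(bad)) {
    warning(sum(bad), " prediction row(s) with score outside [0, 100] ",
            "rejected")
    predictions <- predictions[!bad, , drop = FALSE]
  }
  keep <- predictions$score > score_cutoff
  sort(unique(toupper(predictions$gene[keep])), method = "radix")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate correction: the i-th smallest p-value is
#' multiplied by m/i and a running minimum from the largest rank downward
#' enforces monotonicity. Order-preserving with the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter pathway records at a Benjamini-Hochberg cutoff
#'
#' Retains records whose BH-adjusted p-value is strictly below `alpha`
#' (default 0.05). When the table carries only raw p-values
#' (`p` column, no `adjusted_p`), the adjustment is computed with
#' [bh_adjust()] first.
#'
#' @param records Data.frame with a `term` column and either `adjusted_p`
#'   or raw `p`.
#' @param alpha Strict upper bound on the adjusted p-value (default 0.05).
#' @return The retained rows of `records`, with an `adjusted_p` column.
#' @export
filter_pathways <- function(records, alpha = 0.05) {
  stopifnot("term" %in% names(records))
  if (is.null(records$adjusted_p)) {
    if (is.null(records$p))
      stop("records must carry an adjusted_p or a raw p column")
    records$adjusted_p <- bh_adjust(records$p)
  }
  records[records$adjusted_p < alpha, , drop = FALSE]
}

#' Venn region counts and memberships for named sets
#'
#' Computes every disjoint overlap region of 2 or more named sets: for each
#' non-empty subset of set names, the elements belonging to exactly those
#' sets. Disjoint region counts sum to the size of the union.
#'
#' @param sets Named list of at least two vectors (coerced to character and
#'   deduplicated).
#' @return Data.frame with columns `region` (set names joined by `&`), `n`
#'   and `members` (`;`-separated, sorted).
#' @export
venn_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  k <- length(sets)
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pattern <- as.logical(combos[i, ])
    inside <- if (length(universe))
      apply(membership, 1L, function(m) all(m == pattern)) else logical(0)
    members <- universe[inside]
    data.frame(region = paste(names(sets)[pattern], collapse = "&"),
               n = length(members),
               members = paste(members, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
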