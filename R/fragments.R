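#' Call non-coding RNA fragments (ncRFs) from read assignments
#'
#' An assigned read is an ncRF when its insert is at most
#' `max_fragment_length` nt (default 27); reads of at least
#' `min_precursor_length` nt (default 29) are full-length precursor reads.
#' The single length in between (28 nt) satisfies neither definition and is
#' tallied separately under the role `"gap"`. Fragments are categorised by
#' the precursor terminus they map to: 5' when the start offset is within
#' `end_tolerance` nt of the precursor start, 3' when the end is within
#' `end_tolerance` nt of the precursor 3' terminus (5' wins when both hold),
#' internal otherwise. Precursors with fewer than `min_reads` total mapped
#' reads in the pool are dropped entirely.
#'
#' @param assignments Output of [assign_reads()] (or [classify_reads()]).
#' @param end_tolerance Offset window (nt) for calling a fragment 5' or 3'
#'   terminal; default 2, must be non-negative.
#' @param min_reads Minimum total mapped reads for a precursor to be
#'   retained (default 5).
#' @param max_fragment_length Largest insert length counted as a fragment
#'   (default 27 nt).
#' @param min_precursor_length Smallest insert length counted as a
#'   full-length precursor read (default 29 nt).
#' @param pool_id Identifier carried into the output.
#' @return List of class `ncrf_fragments`: `pool_id`, `precursors`
#'   (data.frame `precursor_id`, `class`, `family`, `length`, `n_total`,
#'   `n_fragment`, `n_5prime`, `n_3prime`, `n_internal`, `n_gap`,
#'   `n_precursor`), `reads` (retained reads with `role` in
#'   `c("fragment","gap","precursor")` and `end_category`), and `params`.
#' @export
call_fragments <- function(assignments, end_tolerance = 2L, min_reads = 5L,
                           max_fragment_length = 27L,
                           min_precursor_length = 29L, pool_id = "pool") {
  if (end_tolerance < 0L) stop("end_tolerance must be non-negative")
  if (min_reads < 1L) stop("min_reads must be at least 1")
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  counts <- table(a$precursor_id)
  keep_ids <- names(counts)[counts >= min_reads]
  a <- a[a$precursor_id %in% keep_ids, , drop = FALSE]

  role <- ifelse(a$insert_length <= max_fragment_length, "fragment",
                 ifelse(a$insert_length >= min_precursor_length,
                        "precursor", "gap"))
  is_frag <- role == "fragment"
  five <- is_frag & a$start <= end_tolerance
  three <- is_frag & !five & (a$precursor_length - a$end) <= end_tolerance
  end_category <- rep(NA_character_, nrow(a))
  end_category[five] <- "5prime"
  end_category[three] <- "3prime"
  end_category[is_frag & !five & !three] <- "internal"

  reads <- cbind(a, role = role, end_category = end_category,
                 stringsAsFactors = FALSE)
  agg <- function(flag) {
    tab <- table(factor(a$precursor_id[flag], levels = keep_ids))
    as.integer(tab)
  }
  ord <- sort(keep_ids, method = "radix")
  reidx <- match(ord, keep_ids)
  first <- match(keep_ids, a$precursor_id)
  precursors <- data.frame(
    precursor_id = keep_ids,
    class = a$class[first],
    family = a$family[first],
    length = a$precursor_length[first],
    n_total = as.integer(table(factor(a$precursor_id, levels = keep_ids))),
    n_fragment = agg(is_frag),
    n_5prime = agg(five),
    n_3prime = agg(three),
    n_internal = agg(is_frag & !five & !three),
    n_gap = agg(role == "gap"),
    n_precursor = agg(role == "precursor"),
    stringsAsFactors = FALSE)
  precursors <- precursors[reidx, , drop = FALSE]
  rownames(precursors) <- NULL
  structure(list(pool_id = pool_id, precursors = precursors, reads = reads,
                 params = list(end_tolerance = end_tolerance,
                               min_reads = min_reads,
                               max_fragment_length = max_fragment_length,
                               min_precursor_length = min_precursor_length)),
            class = "ncrf_fragments")
}

#' Fragment-to-precursor enrichment ratios
#'
#' For each qualifying precursor (or family aggregate) the enrichment is the
#' number of fragment reads (inserts of at most 27 nt) divided by the number
#' of full-length precursor reads (inserts of at least 29 nt). A ratio of 1
#' means one fragment per full-length read. When the denominator is zero the
#' ratio is reported as missing (`NA`) with `defined = FALSE`; the row is
#' retained. Family aggregation (e.g. all copies of tRNA isoacceptor GlyGCC,
#' or a snoRNA id) sums numerators and denominators over members before
#' dividing.
#'
#' @param frags An `ncrf_fragments` object from [call_fragments()].
#' @param by `"precursor"` (default) or `"family"`.
#' @return Data.frame with columns `precursor_id` (or `family`), `class`,
#'   `n_fragment`, `n_precursor`, `ratio`, `defined`.
#' @export
enrichment <- function(frags, by = c("precursor", "family")) {
  stopifnot(inherits(frags, "ncrf_fragments"))
  by <- match.arg(by)
  p <- frags$precursors
  if (by == "family") {
    key <- paste(p$class, p$family, sep = "\r")
    n_fragment <- tapply(p$n_fragment, key, sum)
    n_precursor <- tapply(p$n_precursor, key, sum)
    keys <- names(n_fragment)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(
      family = vapply(parts, `[`, character(1), 2L),
      class = vapply(parts, `[`, character(1), 1L),
      n_fragment = as.integer(n_fragment),
      n_precursor = as.integer(n_precursor),
      stringsAsFactors = FALSE)
    out <- out[order(out$class, out$family, method = "radix"), , drop = FALSE]
  } else {
    out <- data.frame(precursor_id = p$precursor_id, class = p$class,
                      n_fragment = p$n_fragment, n_precursor = p$n_precursor,
                      stringsAsFactors = FALSE)
  }
  out$ratio <- ifelse(out$n_precursor > 0,
                      out$n_fragment / out$n_precursor, NA_real_)
  out$defined <- out$n_precursor > 0
  rownames(out) <- NULL
  out
}

#' Positional distribution of fragment reads along precursors
#'
#' Each precursor, regardless of its length L, is divided into `n_bins`
#' (default 10) equal-sized bins; bin b (1-based) covers positions
#' `[floor((b-1)L/n), floor(bL/n))` in 0-based coordinates. Every fragment
#' read is counted once, in the bin containing its start position, and
#' counts are summed over all precursors of a class. Proportions are the bin
#' counts divided by the class's total; a class without fragments yields an
#' all-zero distribution flagged `empty`.
#'
#' @param frags An `ncrf_fragments` object.
#' @param n_bins Number of bins (default 10).
#' @param classes Optional classes to report; defaults to all classes
#'   present among the retained precursors.
#' @return Data.frame with columns `class`, `bin`, `count`, `proportion`,
#'   `empty`.
#' @export
bin_distribution <- function(frags, n_bins = 10L, classes = NULL) {
  stopifnot(inherits(frags, "ncrf_fragments"))
  r <- frags$reads[frags$reads$role == "fragment", , drop = FALSE]
  if (is.null(classes))
    classes <- sort(unique(frags$precursors$class), method = "radix")
  bin <- integer(nrow(r))
  if (nrow(r)) {
    for (L in unique(r$precursor_length)) {
      edges <- floor((0:n_bins) * L / n_bins)
      idx <- which(r$precursor_length == L)
      bin[idx] <- findInterval(r$start[idx], edges,
                               rightmost.closed = FALSE)
    }
  }
  out <- do.call(rbind, lapply(classes, function(cl) {
    b <- bin[r$class == cl]
    count <- as.integer(table(factor(b, levels = seq_len(n_bins))))
    total <- sum(count)
    data.frame(class = cl, bin = seq_len(n_bins), count = count,
               proportion = if (total > 0) count / total else rep(0, n_bins),
               empty = total == 0L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Prorate counts across pools to a reference pool's library size
#'
#' Sequencing depth differs between pools, so fragment counts are rescaled
#' by the ratio of the reference pool's total to each pool's total before
#' cross-pool comparison: pool counts are multiplied by
#' `pool_totals[reference_pool] / pool_totals[pool]`. The reference pool is
#' unchanged (factor exactly 1). The totals are normally total assigned
#' reads per pool; passing per-pool fragment totals instead prorates by
#' ncRF reads only.
#'
#' @param counts Data.frame with a `pool` column and the count column named
#'   by `value_col`.
#' @param pool_totals Named numeric vector of per-pool totals; every pool in
#'   `counts` must be present with a positive total.
#' @param reference_pool Name of the reference pool.
#' @param value_col Column of `counts` to rescale (default `"count"`).
#' @return `counts` with an added `<value_col>_prorated` column; the
#'   per-pool scale factors are attached as attribute `"factors"`.
#' @export
prorate <- function(counts, pool_totals, reference_pool,
                    value_col = "count") {
  stopifnot(is.data.frame(counts), "pool" %in% names(counts),
            value_col %in% names(counts))
  if (!reference_pool %in% names(pool_totals))
    stop("reference pool ", reference_pool, " missing from pool_totals")
  pools <- unique(counts$pool)
  missing <- setdiff(pools, names(pool_totals))
  if (length(missing))
    stop("pool_totals missing for pool(s): ", paste(missing, collapse = ", "))
  if (any(pool_totals[pools] <= 0))
    stop("pool(s) with zero assigned reads cannot be prorated")
  factors <- pool_totals[[reference_pool]] / pool_totals[pools]
  names(factors) <- pools
  counts[[paste0(value_col, "_prorated")]] <-
    counts[[value_col]] * factors[counts$pool]
  attr(counts, "factors") <- factors
  counts
}

#' 5' versus 3' end-bias summary of fragment reads
#'
#' For each class (and each precursor) reports the fraction of terminal
#' fragments mapping to the 5' end versus the 3' end; internal fragments are
#' excluded from the denominator. Classes or precursors without any
#' end-assigned fragment are retained with `informative = FALSE` and `NA`
#' fractions.
#'
#' @param frags An `ncrf_fragments` object.
#' @return List with data.frames `classes` (`class`, `n_5prime`,
#'   `n_3prime`, `frac_5prime`, `frac_3prime`, `informative`) and
#'   `precursors` (same columns keyed by `precursor_id` plus `class`).
#' @export
end_fraction_summary <- function(frags) {
  stopifnot(inherits(frags, "ncrf_fragments"))
  p <- frags$precursors
  .summarise <- function(n5, n3) {
    tot <- n5 + n3
    data.frame(n_5prime = n5, n_3prime = n3,
               frac_5prime = ifelse(tot > 0, n5 / tot, NA_real_),
               frac_3prime = ifelse(tot > 0, n3 / tot, NA_real_),
               informative = tot > 0)
  }
  cls <- sort(unique(p$class), method = "radix")
  n5c <- vapply(cls, function(cl) sum(p$n_5prime[p$class == cl]), integer(1))
  n3c <- vapply(cls, function(cl) sum(p$n_3prime[p$class == cl]), integer(1))
  classes <- cbind(data.frame(class = cls, stringsAsFactors = FALSE),
                   .summarise(n5c, n3c))
  precursors <- cbind(
    data.frame(precursor_id = p$precursor_id, class = p$class,
               stringsAsFactors = FALSE),
    .summarise(p$n_5prime, p$n_3prime))
  rownames(classes) <- rownames(precursors) <- NULL
  list(classes = classes, precursors = precursors)
}
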