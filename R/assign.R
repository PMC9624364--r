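#' Trim the leading adaptor (and trailing padding) from raw reads
#'
#' Raw library reads are 36 nt: a 7-nt adaptor followed by the ncRNA insert,
#' padded back to 36 nt when the insert is shorter than 29 nt. If the first
#' `nchar(adaptor)` bases match the adaptor with at most `max_mismatch`
#' mismatches the adaptor is removed; otherwise the read is returned
#' unchanged and flagged as untrimmed. Trimmed reads then have 3' padding
#' removed by two rules: a trailing run of the sentinel base `N` is
#' stripped, and a trailing segment of at least `pad_prefix` nt that exactly
#' continues the adaptor sequence (cyclically) from its start is stripped.
#' Both rules are anchored at the read end, so a chance adaptor-like k-mer
#' inside the insert is never mistaken for padding.
#'
#' @param sequences Character vector of raw read sequences (each at least as
#'   long as the adaptor).
#' @param adaptor Adaptor sequence (7 nt by default in this design).
#' @param max_mismatch Maximum mismatches tolerated in the leading adaptor
#'   match (default 1).
#' @param pad_prefix Minimum length of a trailing adaptor-continuation
#'   segment recognised as padding (default 5).
#' @return Data.frame with columns `sequence` (trimmed insert) and
#'   `trimmed` (logical flag).
#' @export
trim_adaptor <- function(sequences, adaptor, max_mismatch = 1L,
                         pad_prefix = 5L) {
  k <- nchar(adaptor)
  if (any(nchar(sequences) < k))
    stop("all reads must be at least as long as the adaptor (", k, " nt)")
  a_chars <- strsplit(adaptor, "")[[1L]]
  mm <- integer(length(sequences))
  for (i in seq_len(k))
    mm <- mm + (substr(sequences, i, i) != a_chars[i])
  trimmed <- mm <= max_mismatch
  out <- ifelse(trimmed, substr(sequences, k + 1L, nchar(sequences)),
                sequences)
  # sentinel padding: strip the trailing N run
  out[trimmed] <- sub("N+$", "", out[trimmed])
  # adaptor-continuation padding: strip the longest read-end segment (of at
  # least pad_prefix nt) equal to the start of the cycled adaptor
  max_pad <- max(nchar(out[trimmed]), 0L)
  cycle <- strrep(adaptor, ceiling(max_pad / k) + 1L)
  idx <- which(trimmed)
  for (t in seq(from = max_pad, by = -1L, length.out =
                  max(max_pad - pad_prefix + 1L, 0L))) {
    if (!length(idx)) break
    len <- nchar(out[idx])
    hit <- len > t &
      substr(out[idx], len - t + 1L, len) == substr(cycle, 1L, t)
    if (any(hit)) {
      j <- idx[hit]
      out[j] <- substr(out[j], 1L, nchar(out[j]) - t)
      idx <- idx[!hit]
    }
  }
  data.frame(sequence = out, trimmed = trimmed, stringsAsFactors = FALSE)
}

# Mismatch counts of `ins_i` (integer-coded insert) against `prec_i` at
# every ungapped offset; returns integer(0) when the insert is longer than
# the precursor.
#' @noRd
.mismatch_profile <- function(ins_i, prec_i) {
  l <- length(ins_i)
  n_off <- length(prec_i) - l + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (i in seq_len(l))
    mm <- mm + (prec_i[i:(i + n_off - 1L)] != ins_i[i])
  mm
}

# Best-hit assignment of one insert. Scans every precursor for ungapped
# sense-strand occurrences with <= max_mismatch mismatches, keeps the
# minimum-mismatch stratum and breaks ties by class priority, then smallest
# start, then lexicographic precursor id ("-v 2 --best" semantics made
# deterministic).
#' @noRd
.assign_one <- function(ins_i, prec_ints, prec_ids, prec_rank, max_mismatch) {
  best_mm <- max_mismatch + 1L
  hit_j <- integer(0); hit_start <- integer(0); hit_mm <- integer(0)
  for (j in seq_along(prec_ints)) {
    mm <- .mismatch_profile(ins_i, prec_ints[[j]])
    idx <- which(mm <= max_mismatch)
    if (length(idx)) {
      hit_j <- c(hit_j, rep.int(j, length(idx)))
      hit_start <- c(hit_start, idx - 1L)
      hit_mm <- c(hit_mm, mm[idx])
    }
  }
  if (!length(hit_j)) return(NULL)
  best <- min(hit_mm)
  keep <- hit_mm == best
  hit_j <- hit_j[keep]; hit_start <- hit_start[keep]
  ord <- order(prec_rank[hit_j], hit_start,
               prec_ids[hit_j], method = "radix")
  list(j = hit_j[ord[1L]], start = hit_start[ord[1L]], mismatches = best)
}

#' Assign trimmed reads to ncRNA precursors
#'
#' Re-implements the classic short-read policy of reporting, for each read,
#' a best ungapped sense-strand hit with at most `max_mismatch` (default 2)
#' mismatches, as popularised by `bowtie -v 2 --best`. Among equally good
#' hits the winner is chosen deterministically: first by ncRNA class
#' priority, then by smallest start offset, then by lexicographic precursor
#' id. Reads shorter than `min_length` nt are discarded (status
#' `"too_short"`) and reads without any qualifying hit are `"unassigned"`.
#'
#' @param reads Character vector of insert sequences, or a data.frame with
#'   `read_id` and `sequence` columns.
#' @param reference Named character vector of precursor sequences, or an
#'   `ncrf_reference`.
#' @param annotation Annotation data.frame (`precursor_id`, `class`,
#'   optional `family`); defaults to the reference's own annotation when an
#'   `ncrf_reference` is supplied.
#' @param max_mismatch Maximum mismatches tolerated (default 2).
#' @param min_length Minimum insert length retained (default 15 nt).
#' @param class_priority Class order used for multi-hit tie-breaks; see
#'   [default_class_priority()].
#' @return Data.frame with one row per input read: `read_id`, `sequence`,
#'   `status` (`assigned`/`unassigned`/`too_short`), `precursor_id`,
#'   `class`, `family`, `precursor_length`, `start` (0-based), `end`
#'   (exclusive), `mismatches`, `insert_length`.
#' @export
assign_reads <- function(reads, reference, annotation = NULL,
                         max_mismatch = 2L, min_length = 15L,
                         class_priority = default_class_priority()) {
  if (inherits(reference, "ncrf_reference")) {
    if (is.null(annotation)) annotation <- reference$annotation
    reference <- reference$sequences
  }
  if (length(reference) == 0L) stop("empty precursor reference")
  if (is.null(annotation)) stop("an annotation table is required")
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read_%06d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))

  prec_ids <- names(reference)
  ann_idx <- match(prec_ids, annotation$precursor_id)
  if (anyNA(ann_idx))
    stop("precursor(s) missing from annotation: ",
         paste(prec_ids[is.na(ann_idx)], collapse = ", "))
  prec_class <- annotation$class[ann_idx]
  prec_family <- if (!is.null(annotation$family))
    annotation$family[ann_idx] else prec_ids
  prec_rank <- match(prec_class, class_priority)
  prec_rank[is.na(prec_rank)] <- length(class_priority) + 1L
  prec_ints <- lapply(reference, utf8ToInt)
  prec_len <- nchar(reference)

  n <- nrow(reads)
  out <- data.frame(
    read_id = reads$read_id, sequence = reads$sequence,
    status = "unassigned", precursor_id = NA_character_,
    class = NA_character_, family = NA_character_,
    precursor_length = NA_integer_, start = NA_integer_, end = NA_integer_,
    mismatches = NA_integer_, insert_length = nchar(reads$sequence),
    stringsAsFactors = FALSE)
  short <- out$insert_length < min_length
  out$status[short] <- "too_short"

  todo <- which(!short)
  uniq <- unique(reads$sequence[todo])
  res <- vector("list", length(uniq))
  for (u in seq_along(uniq)) {
    # res[u] <- list(...) keeps NULL results as empty slots
    res[u] <- list(.assign_one(utf8ToInt(uniq[u]), prec_ints, prec_ids,
                               prec_rank, as.integer(max_mismatch)))
  }
  map <- match(reads$sequence[todo], uniq)
  for (k in seq_along(todo)) {
    r <- res[[map[k]]]
    if (is.null(r)) next
    i <- todo[k]
    out$status[i] <- "assigned"
    out$precursor_id[i] <- prec_ids[r$j]
    out$class[i] <- prec_class[r$j]
    out$family[i] <- prec_family[r$j]
    out$precursor_length[i] <- prec_len[r$j]
    out$start[i] <- r$start
    out$end[i] <- r$start + out$insert_length[i]
    out$mismatches[i] <- r$mismatches
  }
  out
}

#' Per-class composition, GC and read-size profile of a pool
#'
#' Summarises the assigned reads of one sample/pool: the fraction of reads
#' per ncRNA class (fractions of 1 over all assigned reads), the pooled GC
#' fraction of each class's reads, the insert-size distribution and a
#' five-number size summary per class.
#'
#' @param assignments Output of [assign_reads()].
#' @param pool_id Identifier carried into the output (default `"pool"`).
#' @return List of class `ncrf_class_profile`: `pool_id`, `classes`
#'   (data.frame `class`, `n_reads`, `fraction`, `gc`, `size_min`,
#'   `size_q1`, `size_median`, `size_q3`, `size_max`) and `size_counts`
#'   (data.frame `class`, `length` 15-36, `count`).
#' @export
class_profile <- function(assignments, pool_id = "pool") {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(a) == 0L) stop("no assigned reads in pool ", pool_id)
  total <- nrow(a)
  gc_per_read <- nchar(gsub("[^GC]", "", a$sequence))
  by_class <- split(seq_len(nrow(a)), a$class)
  classes <- sort(names(by_class), method = "radix")
  rows <- lapply(classes, function(cl) {
    idx <- by_class[[cl]]
    len <- a$insert_length[idx]
    q <- stats::quantile(len, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(class = cl, n_reads = length(idx),
               fraction = length(idx) / total,
               gc = sum(gc_per_read[idx]) / sum(nchar(a$sequence[idx])),
               size_min = q[1], size_q1 = q[2], size_median = q[3],
               size_q3 = q[4], size_max = q[5], stringsAsFactors = FALSE)
  })
  size_support <- 15:36
  size_counts <- do.call(rbind, lapply(classes, function(cl) {
    len <- a$insert_length[by_class[[cl]]]
    data.frame(class = cl, length = size_support,
               count = as.integer(table(factor(len, levels = size_support))),
               stringsAsFactors = FALSE)
  }))
  structure(list(pool_id = pool_id,
                 classes = do.call(rbind, rows),
                 size_counts = size_counts),
            class = "ncrf_class_profile")
}

#' Percentage of raw reads assigned to the reference
#'
#' @param n_raw Number of raw reads in the library.
#' @param n_assigned Number of reads assigned to precursors.
#' @return `100 * n_assigned / n_raw`.
#' @export
mapping_rate <- function(n_raw, n_assigned) {
  if (n_raw <= 0L) stop("n_raw must be positive")
  if (n_assigned < 0L || n_assigned > n_raw)
    stop("n_assigned must lie in [0, n_raw]")
  100 * n_assigned / n_raw
}

#' Trim and assign a raw read library in one call
#'
#' Convenience wrapper: runs [trim_adaptor()] then [assign_reads()].
#'
#' @inheritParams assign_reads
#' @param adaptor Leading adaptor sequence.
#' @param ... Passed on to [assign_reads()].
#' @return The assignment data.frame of [assign_reads()], with an extra
#'   logical column `trimmed`.
#' @export
classify_reads <- function(reads, reference, adaptor, annotation = NULL,
                           ...) {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read_%06d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  tr <- trim_adaptor(reads$sequence, adaptor)
  inserts <- data.frame(read_id = reads$read_id, sequence = tr$sequence,
                        stringsAsFactors = FALSE)
  out <- assign_reads(inserts, reference, annotation = annotation, ...)
  out$trimmed <- tr$trimmed
  out
}
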