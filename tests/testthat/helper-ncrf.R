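# Shared fixtures and independent oracles for the test suite.

# Small three-class simulation setup; heavier defaults are exercised in the
# recovery tests only.
tiny_params <- function(seed = 1L, n_reads = 2000L, ...) {
  simulation_params(seed = seed, n_reads = n_reads,
                    class_weights = c("miRNA" = 0.6, "tRNA" = 0.25,
                                      "snoRNA" = 0.15),
                    n_precursors_per_class = 3L, ...)
}

# Hand-built reference with known sequences for constructed-input tests.
toy_reference <- function() {
  seqs <- c(
    mir1 = paste0("ACGTACGTGGCCAAGGTTCCAAGGCCTTAAGGCCAATTGG",
                  "CCAAGGTTCCAAGGCCTTAAGGCCAATTGG"),          # 70 nt, miRNA
    trna1 = paste0("TTGGCCAATTGGCCTTAAGGCCTTGGAACCTTGGCCAATT",
                   "GGCCTTAAGGCCTTGGAACCTTGGCCAATT"),         # 70 nt, tRNA
    sno1 = strrep("GATTACAGAC", 7L))                          # 70 nt, snoRNA
  ann <- data.frame(precursor_id = names(seqs),
                    class = c("miRNA", "tRNA", "snoRNA"),
                    length = nchar(seqs),
                    family = c("mir1", "GlyGCC", "snoRA3"),
                    stringsAsFactors = FALSE)
  structure(list(sequences = seqs, annotation = ann),
            class = "ncrf_reference")
}

# Random ACGT string.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Substitute the bases of `s` at 1-based positions `pos` with different ones.
mutate_seq <- function(s, pos) {
  ch <- strsplit(s, "")[[1L]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
  paste(ch, collapse = "")
}

# Independent oracle for the best-hit matcher: exhaustive position-by-
# position substring scan, kept deliberately naive.
oracle_assign <- function(insert, reference, annotation, max_mismatch = 2L,
                          priority = default_class_priority()) {
  ins <- strsplit(insert, "")[[1L]]
  hits <- NULL
  for (pid in names(reference)) {
    s <- reference[[pid]]
    L <- nchar(s)
    l <- length(ins)
    if (l > L) next
    for (start in 0:(L - l)) {
      mm <- sum(strsplit(substr(s, start + 1L, start + l), "")[[1L]] != ins)
      if (mm <= max_mismatch)
        hits <- rbind(hits, data.frame(precursor_id = pid, start = start,
                                       mm = mm, stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits)) return(NULL)
  hits <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  cls <- annotation$class[match(hits$precursor_id, annotation$precursor_id)]
  rk <- match(cls, priority)
  rk[is.na(rk)] <- length(priority) + 1L
  hits[order(rk, hits$start, hits$precursor_id, method = "radix")[1L], ]
}

# Independent oracle for Benjamini-Hochberg: explicit step-up definition,
# adj_(i) = min over k >= i of min(1, m p_(k) / k), via a double loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(k) min(1, m * sp[k] / k), numeric(1))
    adj[i] <- min(vals)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force Venn oracle: classify every element of the union by its exact
# membership pattern.
venn_oracle <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  pats <- vapply(universe, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(pats)
}

# Constructed assignment rows bypassing the matcher, for threshold tests.
mk_assignments <- function(precursor_id, class, start, insert_length,
                           precursor_length, family = precursor_id) {
  n <- max(length(precursor_id), length(start), length(insert_length))
  precursor_id <- rep_len(precursor_id, n)
  class <- rep_len(class, n)
  start <- rep_len(as.integer(start), n)
  insert_length <- rep_len(as.integer(insert_length), n)
  precursor_length <- rep_len(as.integer(precursor_length), n)
  family <- rep_len(family, n)
  data.frame(read_id = sprintf("c_%04d", seq_len(n)),
             sequence = strrep("A", insert_length),
             status = "assigned",
             precursor_id = precursor_id, class = class, family = family,
             precursor_length = precursor_length,
             start = start, end = start + insert_length,
             mismatches = 0L, insert_length = insert_length,
             stringsAsFactors = FALSE)
}
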