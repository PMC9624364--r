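.family_pools <- list(
  "tRNA" = c("GlyGCC", "GlyCCC", "GluCTC", "LysCTT", "LeuCAG", "ValAAC",
             "ValCAC"),
  "snoRNA" = c("snoRA3", "snoRA24", "snoRA54", "snoRA60", "snoRD20",
               "snoRD47", "snoRD110"),
  "snRNA" = c("U1", "U2", "U5", "U6")
)

#' Generate a synthetic ncRNA precursor reference
#'
#' Draws, for every class in `params$class_weights`,
#' `params$n_precursors_per_class` precursor sequences with lengths uniform
#' on the class length range and bases sampled i.i.d. so that the expected
#' GC fraction equals the class `gc_target`. tRNA precursors are labelled
#' with cycling isoacceptor family keys (GlyGCC, GlyCCC, ...), snoRNA and
#' snRNA with family ids (snoRA3, U1, ...); other classes use the precursor
#' id itself as family, so family-level aggregation degenerates gracefully
#' to per-precursor results.
#'
#' @param params An [simulation_params()] object.
#' @return A list of class `ncrf_reference` with elements `sequences`
#'   (named character vector) and `annotation` (data.frame with columns
#'   `precursor_id`, `class`, `length`, `family`).
#' @export
make_reference <- function(params) {
  stopifnot(inherits(params, "ncrf_sim_params"))
  classes <- names(params$class_weights)
  n_per <- params$n_precursors_per_class
  with_local_seed(params$seed * 131L + 1L, {
    ids <- character(0); cls <- character(0); fams <- character(0)
    seqs <- character(0); lens <- integer(0)
    for (cl in classes) {
      rng <- params$precursor_length_range[[cl]]
      gc <- params$gc_target[[cl]]
      base_prob <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
      pool <- .family_pools[[cl]]
      for (i in seq_len(n_per)) {
        id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", cl), i)
        L <- if (rng[1] == rng[2]) rng[1] else
          sample(seq.int(rng[1], rng[2]), 1L)
        s <- paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                          prob = base_prob), collapse = "")
        fam <- if (is.null(pool)) id else pool[((i - 1L) %% length(pool)) + 1L]
        ids <- c(ids, id); cls <- c(cls, cl); fams <- c(fams, fam)
        seqs <- c(seqs, s); lens <- c(lens, L)
      }
    }
    sequences <- stats::setNames(seqs, ids)
    annotation <- data.frame(precursor_id = ids, class = cls, length = lens,
                             family = fams, stringsAsFactors = FALSE)
    structure(list(sequences = sequences, annotation = annotation),
              class = "ncrf_reference")
  })
}

# Discrete fragment length distribution on 15..27 nt around a mode.
#' @noRd
.fragment_length_probs <- function(mode, sd) {
  support <- 15:27
  w <- stats::dnorm(support, mean = mode, sd = sd)
  w / sum(w)
}

# Apply a group effect to the baseline parameters.
#' @noRd
.apply_group_effect <- function(params, effect) {
  w <- params$class_weights
  if (length(effect$class_weight_mult)) {
    common <- intersect(names(effect$class_weight_mult), names(w))
    w[common] <- w[common] * effect$class_weight_mult[common]
    w <- w / sum(w)
  }
  eb <- params$end_bias
  if (length(effect$end_bias_mult)) {
    common <- intersect(names(effect$end_bias_mult), names(eb))
    eb[common] <- pmin(1, pmax(0, eb[common] * effect$end_bias_mult[common]))
  }
  fm <- params$fragment_length_mode
  if (length(effect$length_mode_shift)) {
    common <- intersect(names(effect$length_mode_shift), names(fm))
    fm[common] <- pmin(27, pmax(15, fm[common] +
                                  effect$length_mode_shift[common]))
  }
  list(class_weights = w, end_bias = eb, fragment_length_mode = fm)
}

#' Simulate one small RNA sequencing sample with ground truth
#'
#' Emits `params$n_reads` raw 36-nt reads. Each read is the 7-nt adaptor
#' followed by an insert drawn from a precursor of a class sampled from the
#' (group-adjusted) class weights: with the class's full-length probability
#' the insert is the precursor's first 29 nt; otherwise it is a fragment of
#' 15-27 nt anchored at the 5' start or ending at the 3' terminus according
#' to the class end bias (or, at rate `internal_rate`, internal). Reads
#' shorter than 36 nt after adaptor + insert are 3'-padded with a sentinel
#' run of `N` marking the insert boundary (true inserts never contain `N`,
#' so trimming can remove the padding exactly). Quality strings are constant
#' high quality (`I`, Phred+33 Q40): the pipeline performs no quality
#' filtering.
#'
#' @param params An [simulation_params()] object.
#' @param reference A reference from [make_reference()] built with the same
#'   class set.
#' @param group Named character vector `c(region=, sex=, treatment=)`. If
#'   the corresponding `REGION_SEX_TREATMENT` key is missing from
#'   `params$group_effects`, baseline parameters are used with a warning.
#' @return A list of class `ncrf_sample`: `reads` (data.frame `read_id`,
#'   `sequence`, `quality`), `truth` (one ground-truth row per read:
#'   `read_id`, `precursor_id`, `class`, `end` in
#'   `c("5prime","3prime","internal","full")`, `insert_length`), `realized`
#'   (realised class proportions and per-class 5' end bias among terminal
#'   fragments), and `group` (the group key).
#' @export
simulate_sample <- function(params, reference,
                            group = c(region = "FC", sex = "M",
                                      treatment = "Ct")) {
  stopifnot(inherits(params, "ncrf_sim_params"),
            inherits(reference, "ncrf_reference"))
  key <- paste(group[["region"]], group[["sex"]], group[["treatment"]],
               sep = "_")
  effects <- params$group_effects
  if (!is.null(effects) && length(effects) && is.null(effects[[key]])) {
    warning("group ", key, " not found in group_effects; ",
            "falling back to baseline parameters")
    effect <- list(class_weight_mult = numeric(0), end_bias_mult = numeric(0),
                   length_mode_shift = numeric(0))
  } else {
    effect <- effects[[key]]
    if (is.null(effect))
      effect <- list(class_weight_mult = numeric(0),
                     end_bias_mult = numeric(0),
                     length_mode_shift = numeric(0))
  }
  adj <- .apply_group_effect(params, effect)
  ann <- reference$annotation
  missing_cls <- setdiff(names(adj$class_weights), ann$class)
  if (length(missing_cls))
    stop("reference lacks precursors for class(es): ",
         paste(missing_cls, collapse = ", "))
  n <- params$n_reads
  adaptor <- params$adaptor
  pad_source <- strrep("N", 36L)  # sentinel padding; true inserts lack N
  seed <- (params$seed * 97L + sum(utf8ToInt(key))) %% 2147483647L
  with_local_seed(seed, {
    classes <- sample(names(adj$class_weights), n, replace = TRUE,
                      prob = adj$class_weights)
    prec_id <- character(n)
    for (cl in unique(classes)) {
      members <- ann$precursor_id[ann$class == cl]
      idx <- which(classes == cl)
      prec_id[idx] <- if (length(members) == 1L) members else
        sample(members, length(idx), replace = TRUE)
    }
    plen <- ann$length[match(prec_id, ann$precursor_id)]
    is_full <- stats::runif(n) < params$full_length_prob[classes]
    frag_len <- integer(n)
    end <- character(n)
    end[is_full] <- "full"
    frag_idx <- which(!is_full)
    for (cl in unique(classes[frag_idx])) {
      idx <- frag_idx[classes[frag_idx] == cl]
      probs <- .fragment_length_probs(adj$fragment_length_mode[[cl]],
                                      params$fragment_length_sd)
      frag_len[idx] <- sample(15:27, length(idx), replace = TRUE, prob = probs)
    }
    u_int <- stats::runif(n)
    u_end <- stats::runif(n)
    is_internal <- !is_full & u_int < params$internal_rate
    end[frag_idx] <- ifelse(is_internal[frag_idx], "internal",
                            ifelse(u_end[frag_idx] <
                                     adj$end_bias[classes[frag_idx]],
                                   "5prime", "3prime"))
    insert_len <- ifelse(is_full, 29L, frag_len)
    start <- integer(n)  # 0-based
    start[end == "full" | end == "5prime"] <- 0L
    three <- end == "3prime"
    start[three] <- plen[three] - insert_len[three]
    internal <- which(end == "internal")
    for (i in internal) {
      hi <- plen[i] - insert_len[i] - 1L
      start[i] <- if (hi < 1L) 0L else sample(seq_len(hi), 1L)
      if (hi < 1L) end[i] <- "5prime"  # too short to host an internal cut
    }
    seqs <- reference$sequences[prec_id]
    inserts <- substr(seqs, start + 1L, start + insert_len)
    raw <- substr(paste0(adaptor, inserts, pad_source), 1L, 36L)
    reads <- data.frame(
      read_id = sprintf("read_%06d", seq_len(n)),
      sequence = unname(raw),
      quality = strrep("I", 36L),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      read_id = reads$read_id,
      precursor_id = prec_id,
      class = classes,
      end = end,
      insert_length = insert_len,
      stringsAsFactors = FALSE)
    realized_fractions <- prop.table(table(truth$class))
    term <- truth$end %in% c("5prime", "3prime")
    realized_bias <- vapply(split(truth$end[term], truth$class[term]),
                            function(e) mean(e == "5prime"), numeric(1))
    structure(list(reads = reads, truth = truth,
                   realized = list(
                     class_fractions = realized_fractions,
                     end_bias = realized_bias),
                   group = key),
              class = "ncrf_sample")
  })
}

#' Write simulated reads as a 4-line FASTQ file
#'
#' @param reads Data.frame with `read_id`, `sequence` and `quality` columns
#'   (e.g. `simulate_sample(...)$reads`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  lines <- character(4L * n)
  lines[seq(1L, length.out = n, by = 4L)] <- paste0("@", reads$read_id)
  lines[seq(2L, length.out = n, by = 4L)] <- reads$sequence
  lines[seq(3L, length.out = n, by = 4L)] <- "+"
  lines[seq(4L, length.out = n, by = 4L)] <- reads$quality
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a synthetic reference as FASTA plus annotation TSV
#'
#' @param reference An `ncrf_reference` from [make_reference()].
#' @param fasta_path Output FASTA path.
#' @param annotation_path Output TSV path (`precursor_id`, `class`,
#'   `length`, `family`).
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, annotation_path) {
  stopifnot(inherits(reference, "ncrf_reference"))
  x <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(x, fasta_path)
  utils::write.table(reference$annotation, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}

#' Write the per-read ground truth of a simulated sample
#'
#' @param sample An `ncrf_sample` from [simulate_sample()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sample, path) {
  stopifnot(inherits(sample, "ncrf_sample"))
  utils::write.table(sample$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
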