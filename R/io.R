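# Uppercase a nucleotide sequence and convert RNA U to DNA T.
#' @noRd
.normalize_seq <- function(x) chartr("U", "T", toupper(x))

#' Read small RNA reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first character of the (optionally
#' gzip-compressed) file: `>` for FASTA, `@` for FASTQ. Sequences are
#' uppercased and `U` is converted to `T`. FASTQ files are validated
#' structurally (4-line records, matching sequence/quality lengths); a
#' malformed or truncated record raises an error naming the file and the
#' record ordinal rather than being dropped silently.
#'
#' @param path Path to a FASTA/FASTQ file, plain or gzipped.
#' @return Data.frame with columns `read_id`, `sequence`, `quality`
#'   (`NA` for FASTA input).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (startsWith(first, ">")) {
    x <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    data.frame(read_id = ids,
               sequence = .normalize_seq(as.character(x)),
               quality = NA_character_,
               stringsAsFactors = FALSE)
  } else if (startsWith(first, "@")) {
    con <- gzfile(path, "rt")
    lines <- readLines(con)
    close(con)
    n <- length(lines)
    if (n %% 4L != 0L)
      stop("malformed FASTQ record ", n %/% 4L + 1L, " in ", path,
           ": truncated record (", n, " lines, not a multiple of 4)")
    hdr <- lines[seq(1L, n, by = 4L)]
    seqs <- lines[seq(2L, n, by = 4L)]
    plus <- lines[seq(3L, n, by = 4L)]
    qual <- lines[seq(4L, n, by = 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                   nchar(seqs) != nchar(qual))
    if (length(bad))
      stop("malformed FASTQ record ", bad[1L], " in ", path)
    data.frame(read_id = sub("\\s.*$", "", substring(hdr, 2L)),
               sequence = .normalize_seq(seqs),
               quality = qual,
               stringsAsFactors = FALSE)
  } else {
    stop("cannot detect read format of ", path,
         " (expected '>' FASTA or '@' FASTQ header)")
  }
}

#' Read a precursor class annotation table
#'
#' Expects a TSV with header columns `precursor_id` and `class`, and
#' optionally `length` and `family`. Class labels outside the declared
#' vocabulary are accepted under `"other"` with a warning. When `family` is
#' absent it defaults to the precursor id (per-precursor aggregation).
#'
#' @param path Path to the annotation TSV.
#' @param classes Allowed class vocabulary; defaults to [ncrf_classes()].
#' @return Data.frame with columns `precursor_id`, `class`, `family` and,
#'   when present in the file, `length`.
#' @export
read_annotation <- function(path, classes = ncrf_classes()) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("precursor_id", "class")
  if (!all(req %in% names(ann)))
    stop("annotation table ", path, " must have columns ",
         paste(req, collapse = ", "))
  if (anyDuplicated(ann$precursor_id))
    stop("duplicated precursor_id in annotation table ", path)
  unknown <- setdiff(unique(ann$class), classes)
  if (length(unknown)) {
    warning("unknown ncRNA class(es) ", paste(unknown, collapse = ", "),
            " in ", path, "; folded into 'other'")
    ann$class[ann$class %in% unknown] <- "other"
  }
  if (is.null(ann$family)) ann$family <- ann$precursor_id
  ann
}

#' Read and validate a sample sheet
#'
#' A TSV with columns `sample_id`, `file`, `region` (FC/HIP/CER), `sex`
#' (M/F), `treatment` (Ct/SR) and `pool_group`. Samples sharing a
#' `pool_group` are biological repeats pooled by [pool_samples()].
#'
#' @param path Path to the sample sheet TSV.
#' @param check_files If `TRUE` (default), require every read file to exist.
#' @return The validated data.frame.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "file", "region", "sex", "treatment", "pool_group")
  if (!all(req %in% names(sheet)))
    stop("sample sheet ", path, " must have columns ",
         paste(req, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet ", path)
  .check_levels <- function(x, allowed, what) {
    bad <- setdiff(unique(x), allowed)
    if (length(bad))
      stop("invalid ", what, " value(s) in ", path, ": ",
           paste(bad, collapse = ", "))
  }
  .check_levels(sheet$region, c("FC", "HIP", "CER"), "region")
  .check_levels(sheet$sex, c("M", "F"), "sex")
  .check_levels(sheet$treatment, c("Ct", "SR"), "treatment")
  if (check_files) {
    missing <- sheet$file[!file.exists(sheet$file)]
    if (length(missing))
      stop("read file(s) not found: ", paste(missing, collapse = ", "))
  }
  sheet
}

#' Pool biological repeats according to a sample sheet
#'
#' Concatenates the read streams of all samples sharing a `pool_group`.
#' Pooling across different regions, sexes or treatments is rejected: a pool
#' must consist of biological repeats of one experimental condition.
#'
#' @param sheet A sample sheet data.frame (see [read_sample_sheet()]).
#' @param reader Function used to read each file; defaults to
#'   [read_reads()].
#' @return Named list keyed by `pool_group`; each element is a list with
#'   `reads` (concatenated read data.frame), `region`, `sex`, `treatment`
#'   and `sample_ids`.
#' @export
pool_samples <- function(sheet, reader = read_reads) {
  req <- c("sample_id", "file", "region", "sex", "treatment", "pool_group")
  stopifnot(all(req %in% names(sheet)), nrow(sheet) >= 1L)
  pools <- split(sheet, sheet$pool_group)
  out <- lapply(pools, function(p) {
    for (col in c("region", "sex", "treatment")) {
      if (length(unique(p[[col]])) != 1L)
        stop("pool_group ", p$pool_group[1L], " mixes ", col, " values (",
             paste(unique(p[[col]]), collapse = ", "),
             "); pools must be biological repeats of one condition")
    }
    reads <- do.call(rbind, lapply(p$file, reader))
    list(reads = reads, region = p$region[1L], sex = p$sex[1L],
         treatment = p$treatment[1L], sample_ids = p$sample_id)
  })
  out[sort(names(out), method = "radix")]
}

# Format a data.frame for deterministic TSV output: doubles at 6 decimals.
#' @noRd
.format_table <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- df[[col]]
      df[[col]] <- ifelse(is.na(v), "NA", sprintf("%.6f", v))
    }
  }
  df
}

#' Write result tables as deterministic TSV files
#'
#' Each element of `results` is written to `<name>.tsv` under `out_dir` with
#' a fixed column order, tab separation and floating-point values at 6
#' decimals, so reruns on identical inputs produce byte-identical files.
#'
#' @param results Named list of data.frames (e.g. `class_profile`,
#'   `fragments`, `bins`, `enrichment`, `comparison`).
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, the vector of file paths written.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir)
  paths <- character(0)
  for (name in sort(names(results), method = "radix")) {
    df <- results[[name]]
    stopifnot(is.data.frame(df))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    ok <- tryCatch({
      utils::write.table(.format_table(df), path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) {
      stop("cannot write ", path, ": ", conditionMessage(e))
    })
    paths <- c(paths, path)
  }
  invisible(paths)
}
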