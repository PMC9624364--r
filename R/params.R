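#' Controlled vocabulary of ncRNA classes
#'
#' The closed (but extensible) set of ncRNA class labels recognised by the
#' annotation reader and the simulator. Labels outside this vocabulary are
#' folded into `"other"` with a warning when an annotation table is read.
#'
#' @return Character vector of class labels.
#' @export
ncrf_classes <- function() {
  c("miRNA", "tRNA", "rRNA", "snoRNA", "snRNA", "ra-ncRNA", "mtRNA",
    "lincRNA", "antisense", "sense-intronic", "processed-transcript",
    "sRNA", "other")
}

#' Default class priority for multi-mapping tie-breaks
#'
#' When a read matches precursors of several classes at the same (minimal)
#' mismatch count, the assignment is resolved deterministically by this
#' priority order: the abundant small-RNA classes first, then remaining
#' classes alphabetically.
#'
#' @param classes Character vector of class labels to order.
#' @return `classes` reordered by priority.
#' @export
default_class_priority <- function(classes = ncrf_classes()) {
  head_order <- c("miRNA", "tRNA", "rRNA", "snoRNA", "snRNA", "mtRNA",
                  "ra-ncRNA")
  rest <- sort(setdiff(classes, head_order), method = "radix")
  c(head_order[head_order %in% classes], rest)
}

#' Default per-group simulation effects
#'
#' Multiplicative shifts applied to the baseline simulation parameters for
#' each (brain region, sex, treatment) cell of the emulated study grid:
#' three regions (FC, HIP, CER) by two sexes (M, F) by control (Ct) versus
#' scatter radiation (SR). Control cells are identity. The SR cells encode
#' the kind of composition shifts reported for irradiated animals: a drop in
#' the miRNA share with a compensating rise of repeat-associated reads in
#' male cerebellum, and miRNA decreases with mtRNA/ra-ncRNA increases in
#' hippocampus of both sexes.
#'
#' Each element may contain `class_weight_mult` (named multipliers on class
#' weights, renormalised afterwards), `end_bias_mult` (multipliers on the
#' 5'-origin probability, clamped to \[0, 1\]) and `length_mode_shift`
#' (additive shift in nt on the fragment length mode, clamped to \[15, 27\]).
#'
#' @return Named list keyed by `"REGION_SEX_TREATMENT"`.
#' @export
default_group_effects <- function() {
  identity_effect <- list(class_weight_mult = numeric(0),
                          end_bias_mult = numeric(0),
                          length_mode_shift = numeric(0))
  eff <- list()
  for (region in c("FC", "HIP", "CER")) {
    for (sex in c("M", "F")) {
      for (treatment in c("Ct", "SR")) {
        eff[[paste(region, sex, treatment, sep = "_")]] <- identity_effect
      }
    }
  }
  eff[["CER_M_SR"]] <- list(
    class_weight_mult = c("miRNA" = 0.93, "ra-ncRNA" = 1.67),
    end_bias_mult = numeric(0),
    length_mode_shift = c("tRNA" = -2, "snRNA" = -2))
  eff[["HIP_M_SR"]] <- list(
    class_weight_mult = c("miRNA" = 0.94, "mtRNA" = 1.67, "ra-ncRNA" = 1.19),
    end_bias_mult = numeric(0),
    length_mode_shift = numeric(0))
  eff[["HIP_F_SR"]] <- list(
    class_weight_mult = c("miRNA" = 0.93, "mtRNA" = 2.0, "ra-ncRNA" = 1.20),
    end_bias_mult = numeric(0),
    length_mode_shift = numeric(0))
  eff
}

.default_sim_classes <- function() {
  list(
    class_weights = c("miRNA" = 0.80, "ra-ncRNA" = 0.11, "tRNA" = 0.04,
                      "rRNA" = 0.02, "snoRNA" = 0.015, "snRNA" = 0.01,
                      "mtRNA" = 0.005),
    precursor_length_range = list(
      "miRNA" = c(60L, 90L), "ra-ncRNA" = c(60L, 120L), "tRNA" = c(70L, 90L),
      "rRNA" = c(100L, 160L), "snoRNA" = c(70L, 150L), "snRNA" = c(100L, 160L),
      "mtRNA" = c(60L, 100L)),
    fragment_length_mode = c("miRNA" = 22, "ra-ncRNA" = 22, "tRNA" = 22,
                             "rRNA" = 21, "snoRNA" = 22, "snRNA" = 23,
                             "mtRNA" = 21),
    full_length_prob = c("miRNA" = 0.2, "ra-ncRNA" = 0.3, "tRNA" = 0.3,
                         "rRNA" = 0.3, "snoRNA" = 0.3, "snRNA" = 0.3,
                         "mtRNA" = 0.3),
    end_bias = c("miRNA" = 0.5, "ra-ncRNA" = 0.9, "tRNA" = 0.95,
                 "rRNA" = 0.5, "snoRNA" = 0.35, "snRNA" = 0.9,
                 "mtRNA" = 0.5),
    gc_target = c("miRNA" = 0.45, "ra-ncRNA" = 0.45, "tRNA" = 0.55,
                  "rRNA" = 0.52, "snoRNA" = 0.42, "snRNA" = 0.48,
                  "mtRNA" = 0.40)
  )
}

#' Simulation parameters for synthetic small RNA libraries
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' parameter object. The defaults emulate a rodent brain small-RNA library:
#' ~80% of reads from miRNA precursors, ~11% repeat-associated ncRNA, minor
#' tRNA/rRNA/snoRNA/snRNA/mtRNA fractions; fragment lengths concentrated
#' near a 22-nt mode on a 15-27 nt support; strong 5' cleavage bias for tRNA,
#' ra-ncRNA and snRNA and mixed ends for rRNA and snoRNA. Raw reads are
#' 36 nt: a 7-nt leading adaptor plus either a full-length 29-nt precursor
#' prefix or a shorter terminal fragment, padded back to 36 nt.
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param n_reads Number of reads per simulated sample.
#' @param class_weights Named proportions per ncRNA class; must sum to 1.
#' @param precursor_length_range Named list of `c(min, max)` precursor
#'   lengths in nt per class; minima must be at least 29 nt so a full-length
#'   29-nt insert always exists.
#' @param fragment_length_mode Named per-class mode (nt) of the fragment
#'   length distribution on 15-27 nt.
#' @param fragment_length_sd Spread (nt) of the discretised fragment length
#'   distribution around its mode.
#' @param full_length_prob Named per-class probability that a read is a
#'   full-length (29-nt) precursor read rather than a fragment.
#' @param end_bias Named per-class probability that a fragment originates
#'   from the 5' end (is 5'-anchored) rather than the 3' terminus.
#' @param gc_target Named per-class expected GC fraction of precursor
#'   sequences.
#' @param internal_rate Probability that a fragment is internal (anchored at
#'   neither terminus); default 0, matching the terminal definition of ncRFs.
#' @param adaptor The leading adaptor sequence (7 nt by default).
#' @param n_precursors_per_class Number of precursors simulated per class.
#' @param group_effects Named list of per-group multiplicative shifts; see
#'   [default_group_effects()].
#' @return An object of class `ncrf_sim_params` (a validated list).
#' @seealso [make_reference()], [simulate_sample()]
#' @export
simulation_params <- function(seed = 1L,
                              n_reads = 10000L,
                              class_weights = NULL,
                              precursor_length_range = NULL,
                              fragment_length_mode = NULL,
                              fragment_length_sd = 1.5,
                              full_length_prob = NULL,
                              end_bias = NULL,
                              gc_target = NULL,
                              internal_rate = 0,
                              adaptor = "CGACGAT",
                              n_precursors_per_class = 4L,
                              group_effects = default_group_effects()) {
  d <- .default_sim_classes()
  if (is.null(class_weights)) class_weights <- d$class_weights
  classes <- names(class_weights)
  if (is.null(classes) || length(classes) == 0L)
    stop("class_weights must be a non-empty named vector")
  fill <- function(x, dflt, what) {
    if (is.null(x)) x <- dflt
    if (is.list(x)) {
      missing <- setdiff(classes, names(x))
      x[missing] <- dflt[missing]
      x <- x[classes]
    } else {
      x <- x[classes]
      names(x) <- classes
      if (anyNA(x)) {
        x[is.na(x)] <- dflt[classes[is.na(x)]]
      }
    }
    if (anyNA(unlist(x, use.names = FALSE)))
      stop("no default available for some classes in ", what,
           "; supply values for all classes")
    x
  }
  params <- list(
    seed = as.integer(seed),
    n_reads = as.integer(n_reads),
    class_weights = class_weights,
    precursor_length_range = fill(precursor_length_range,
                                  d$precursor_length_range,
                                  "precursor_length_range"),
    fragment_length_mode = fill(fragment_length_mode, d$fragment_length_mode,
                                "fragment_length_mode"),
    fragment_length_sd = as.numeric(fragment_length_sd),
    full_length_prob = fill(full_length_prob, d$full_length_prob,
                            "full_length_prob"),
    end_bias = fill(end_bias, d$end_bias, "end_bias"),
    gc_target = fill(gc_target, d$gc_target, "gc_target"),
    internal_rate = as.numeric(internal_rate),
    adaptor = toupper(adaptor),
    n_precursors_per_class = as.integer(n_precursors_per_class),
    group_effects = group_effects
  )
  validate_sim_params(params)
  class(params) <- "ncrf_sim_params"
  params
}

#' @noRd
validate_sim_params <- function(p) {
  w <- p$class_weights
  if (abs(sum(w) - 1) > 1e-9)
    stop("class_weights must sum to 1 (got ", format(sum(w)), ")")
  if (any(w < 0)) stop("class_weights must be non-negative")
  probs <- c(p$full_length_prob, p$end_bias, p$gc_target, p$internal_rate)
  if (any(probs < 0 | probs > 1))
    stop("full_length_prob, end_bias, gc_target and internal_rate must lie in [0, 1]")
  for (cl in names(w)) {
    rng <- p$precursor_length_range[[cl]]
    if (length(rng) != 2L || any(is.na(rng)) || rng[2] < rng[1])
      stop("empty precursor length range for class ", cl)
    if (rng[1] < 29L)
      stop("precursor length minimum for class ", cl,
           " must be >= 29 nt (full-length insert length)")
  }
  modes <- p$fragment_length_mode
  if (any(modes < 15 | modes > 27))
    stop("fragment_length_mode must lie within the 15-27 nt fragment support")
  if (p$fragment_length_sd <= 0) stop("fragment_length_sd must be positive")
  if (p$n_precursors_per_class < 1L)
    stop("n_precursors_per_class must be >= 1")
  if (nchar(p$adaptor) < 5L || grepl("[^ACGT]", p$adaptor))
    stop("adaptor must be an ACGT sequence of at least 5 nt")
  invisible(TRUE)
}

#' Read simulation parameters from a YAML configuration file
#'
#' Scalar fields override the defaults of [simulation_params()]; map fields
#' (e.g. `class_weights`, `end_bias`) are converted to named numeric vectors,
#' and `precursor_length_range` to a named list of length-2 vectors.
#'
#' @param path Path to a YAML file.
#' @return An `ncrf_sim_params` object.
#' @export
simulation_params_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  vec_fields <- c("class_weights", "fragment_length_mode", "full_length_prob",
                  "end_bias", "gc_target")
  for (f in vec_fields) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  }
  if (!is.null(cfg$precursor_length_range)) {
    cfg$precursor_length_range <- lapply(cfg$precursor_length_range,
                                         function(x) as.integer(unlist(x)))
  }
  allowed <- names(formals(simulation_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown simulation parameter(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(simulation_params, cfg)
}

# Run `code` under a seed derived from `seed` without disturbing the caller's
# RNG stream.
#' @noRd
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  force(code)
}
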