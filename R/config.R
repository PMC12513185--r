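#' Alignment scoring scheme
#'
#' Scoring used for the local sequence alignments that transfer active-site
#' positions from the seed to each candidate. Defaults are +2 for identical
#' characters, -1 for mismatches, -0.5 for opening a gap and -0.1 for each
#' gap extension; a gap of length L therefore scores
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param match score for an identical aligned pair (must be > 0)
#' @param mismatch score for a mismatched aligned pair (< match)
#' @param gap_open score charged to the first character of a gap run (<= 0)
#' @param gap_extend score charged to each further gap character (<= 0,
#'   `|gap_extend| <= |gap_open|`)
#' @return an object of class `align_scoring`
#' @export
#' @examples
#' align_scoring()
align_scoring <- function(match = 2, mismatch = -1,
                          gap_open = -0.5, gap_extend = -0.1) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  if (match <= 0) stop("match score must be positive")
  if (mismatch >= match) stop("mismatch score must be below the match score")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap scores must be <= 0")
  if (abs(gap_extend) > abs(gap_open))
    stop("|gap_extend| must not exceed |gap_open|")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Pipeline configuration
#'
#' Collects every threshold of the filtering pipeline. Defaults are the
#' standard operating point: redundancy clustering at 99\% identity, a
#' TM-score band of \\[0.5, 1.0\\], seed coverage of at least 70\%, a 95\%
#' identity floor for proxy structures, a 5 Angstrom substrate-contact shell
#' and a 3.5 Angstrom polar-contact cutoff.
#'
#' @param redundancy_identity identity fraction at/above which two sequences
#'   are considered redundant (0 < x <= 1)
#' @param length_min,length_max inclusive sequence-length window (aa);
#'   `NULL` disables the corresponding bound
#' @param tm_min,tm_max inclusive TM-score band for the structural filter
#' @param coverage_min minimum seed coverage (fraction of seed residues in
#'   the structural correspondence)
#' @param proxy_identity_min minimum identity for a proxy structure to stand
#'   in for a candidate lacking its own model
#' @param contact_cutoff heavy-atom distance (Angstrom) defining
#'   substrate-contact residues
#' @param polar_cutoff N/O--N/O distance (Angstrom) flagging polar backbone
#'   contacts (annotation only, never a filter)
#' @param align_scoring an [align_scoring()] object
#' @param identity_denominator denominator convention for
#'   [pairwise_identity()]: `"shorter"` (CD-HIT-style, default) or
#'   `"alignment"` (alignment length including gap columns)
#' @param coverage_denominator denominator for seed coverage: `"seed"`
#'   (default; seed length) or `"alignment"` (structural alignment length)
#' @return an object of class `pipeline_config`
#' @export
#' @examples
#' cfg <- pipeline_config(length_min = 800, length_max = 1500)
#' cfg$tm_min
pipeline_config <- function(redundancy_identity = 0.99,
                            length_min = NULL, length_max = NULL,
                            tm_min = 0.5, tm_max = 1.0,
                            coverage_min = 0.70,
                            proxy_identity_min = 0.95,
                            contact_cutoff = 5.0,
                            polar_cutoff = 3.5,
                            align_scoring = structfilter::align_scoring(),
                            identity_denominator = c("shorter", "alignment"),
                            coverage_denominator = c("seed", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  coverage_denominator <- match.arg(coverage_denominator)
  if (!(redundancy_identity > 0 && redundancy_identity <= 1))
    stop("redundancy_identity must be in (0, 1]")
  if (!(tm_min >= 0 && tm_min <= tm_max && tm_max <= 1))
    stop("need 0 <= tm_min <= tm_max <= 1")
  if (!(coverage_min > 0 && coverage_min <= 1))
    stop("coverage_min must be in (0, 1]")
  if (!(proxy_identity_min > 0 && proxy_identity_min <= 1))
    stop("proxy_identity_min must be in (0, 1]")
  if (contact_cutoff <= 0 || polar_cutoff <= 0)
    stop("distance cutoffs must be positive")
  if (!is.null(length_min) && !is.null(length_max) && length_min > length_max)
    stop("length_min must not exceed length_max")
  if (!inherits(align_scoring, "align_scoring"))
    stop("align_scoring must be built with align_scoring()")
  structure(list(redundancy_identity = redundancy_identity,
                 length_min = length_min, length_max = length_max,
                 tm_min = tm_min, tm_max = tm_max,
                 coverage_min = coverage_min,
                 proxy_identity_min = proxy_identity_min,
                 contact_cutoff = contact_cutoff,
                 polar_cutoff = polar_cutoff,
                 align_scoring = align_scoring,
                 identity_denominator = identity_denominator,
                 coverage_denominator = coverage_denominator),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the [pipeline_config()] argument names; the nested
#' `align_scoring` block mirrors [align_scoring()]. Unknown keys are an
#' error so typos never silently fall back to defaults.
#'
#' @param path path to a YAML file
#' @return a [pipeline_config()] object
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$align_scoring))
    raw$align_scoring <- do.call(align_scoring, raw$align_scoring)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  redundancy identity : >= %.2f\n", x$redundancy_identity))
  cat(sprintf("  length window (aa)  : [%s, %s]\n",
              if (is.null(x$length_min)) "-Inf" else x$length_min,
              if (is.null(x$length_max)) "Inf" else x$length_max))
  cat(sprintf("  TM-score band       : [%.2f, %.2f]\n", x$tm_min, x$tm_max))
  cat(sprintf("  seed coverage       : >= %.2f\n", x$coverage_min))
  cat(sprintf("  proxy identity      : >= %.2f\n", x$proxy_identity_min))
  cat(sprintf("  contact cutoff      : %.1f A\n", x$contact_cutoff))
  cat(sprintf("  polar cutoff        : %.1f A\n", x$polar_cutoff))
  cat(sprintf("  scoring             : match %+g mismatch %+g gap %+g/%+g\n",
              x$align_scoring$match, x$align_scoring$mismatch,
              x$align_scoring$gap_open, x$align_scoring$gap_extend))
  invisible(x)
}
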