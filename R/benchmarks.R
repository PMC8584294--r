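pkg_extdata <- function(file) {
  system.file("extdata", file, package = "ebpabench", mustWork = TRUE)
}

#' Load benchmark trial specifications
#'
#' Reads the packaged `benchmarks.yaml` (or a user-supplied file with the
#' same structure): per benchmark the inclusion criteria (age, Risser and
#' Cobb ranges, optional menarche / apex / prior-treatment predicates),
#' the success definition, the protocol treatment intensity, and the
#' published arm summaries (n, success proportion, baseline means and
#' SDs, and — for the cohort subgroup — its intensity distribution).
#'
#' @param path Optional path to a YAML file overriding the packaged
#'   defaults.
#' @return Named list of `benchmark_spec` objects.
#' @examples
#' specs <- benchmark_specs()
#' names(specs)
#' specs$braist$cobb_range
#' @export
benchmark_specs <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("benchmarks.yaml")
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(spec) {
    for (f in c("age_range", "risser_range", "cobb_range")) {
      spec[[f]] <- as.numeric(spec[[f]])
      if (length(spec[[f]]) != 2 || spec[[f]][1] > spec[[f]][2]) {
        stop("benchmark field ", f, " must be a non-empty range",
             call. = FALSE)
      }
    }
    for (arm in names(spec$arms)) {
      a <- spec$arms[[arm]]
      if (is.null(a$n) || a$n <= 0) {
        stop("arm '", arm, "' must have n > 0", call. = FALSE)
      }
      if (!is.null(a$success_prop) &&
          (a$success_prop < 0 || a$success_prop > 1)) {
        stop("arm '", arm, "' success_prop outside [0, 1]", call. = FALSE)
      }
      if (!is.null(a$intensity_pct)) {
        v <- unlist(a$intensity_pct)
        spec$arms[[arm]]$intensity_pct <-
          stats::setNames(as.numeric(v[as.character(0:6)]),
                          as.character(0:6))
      }
    }
    structure(spec, class = "benchmark_spec")
  })
  out
}

#' Expected treatment-intensity ranges per Cobb band
#'
#' @param path Optional YAML override; defaults to the packaged
#'   `expected_intensity.yaml`.
#' @return Named list: band label to integer vector of expected
#'   intensities.
#' @export
expected_intensity_ranges <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("expected_intensity.yaml")
  ranges <- lapply(yaml::read_yaml(path), as.integer)
  if (!setequal(names(ranges), band_levels)) {
    stop("expected-intensity config must cover the four Cobb bands",
         call. = FALSE)
  }
  if (any(!unlist(ranges) %in% 0:6)) {
    stop("expected intensities must be in 0..6", call. = FALSE)
  }
  ranges
}

#' Tunable parameters of the aims rule engine
#'
#' @param path Optional YAML override; defaults to the packaged
#'   `aims.yaml`.
#' @return List with `change_delta` (degrees) and
#'   `under_treatment_any_progression` (logical).
#' @export
aims_rules <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("aims.yaml")
  cfg <- yaml::read_yaml(path)
  stopifnot(is.numeric(cfg$change_delta), cfg$change_delta >= 0,
            is.logical(cfg$under_treatment_any_progression))
  cfg
}
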