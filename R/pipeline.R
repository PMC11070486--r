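#' Assemble a pipeline run configuration
#'
#' @param cohort a [cohort_spec()].
#' @param protocol a [loading_protocol()].
#' @param acquisition an [acquisition_config()].
#' @param geometry an [indenter_geometry()].
#' @param mode analysis path: `"full"` (echo rendering and tracking) or
#'   `"fast"` (curve read off the trajectory).
#' @param h_convention kappa thickness convention, see [regional_moduli()].
#' @param drop_first_cycle preconditioning-cycle policy, see
#'   [cycle_policy()].
#' @param seed master seed; overrides `cohort$seed` when non-NULL.
#' @param out_dir output directory, or NULL to skip writing.
#' @param verbose print stage progress to stderr.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), protocol = loading_protocol(),
                       acquisition = acquisition_config(),
                       geometry = indenter_geometry(),
                       mode = c("full", "fast"),
                       h_convention = "instantaneous",
                       drop_first_cycle = TRUE,
                       seed = NULL, out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, protocol = protocol,
                 acquisition = acquisition, geometry = geometry,
                 mode = mode, h_convention = h_convention,
                 drop_first_cycle = drop_first_cycle,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [cohort_spec()], [loading_protocol()],
#' [acquisition_config()] or [indenter_geometry()] can be overridden from
#' the corresponding YAML section (`cohort:`, `protocol:`, `acquisition:`,
#' `geometry:`); top-level keys map to the remaining [run_config()]
#' arguments. Use `n_per_arm` for the cohort sizes (a bare `n` is a YAML
#' boolean).
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, section) {
    args <- y[[section]] %||% list()
    ## YAML 1.1 parses a bare `n:` key as a boolean; accept the alias
    ## `n_per_arm` and normalise the coerced key
    names(args)[names(args) %in% c("n_per_arm", "FALSE")] <- "n"
    if (section == "cohort" && !is.null(args$modulus_effect))
      args$modulus_effect <- matrix(unlist(args$modulus_effect), ncol = 3,
                                    byrow = TRUE)
    if (section == "cohort" && !is.null(args$modulus_effect_cv))
      args$modulus_effect_cv <- matrix(unlist(args$modulus_effect_cv),
                                       ncol = 3, byrow = TRUE)
    do.call(ctor, args)
  }
  top <- y[setdiff(names(y), c("cohort", "protocol", "acquisition",
                               "geometry"))]
  do.call(run_config, c(list(cohort = build(cohort_spec, "cohort"),
                             protocol = build(loading_protocol, "protocol"),
                             acquisition = build(acquisition_config,
                                                 "acquisition"),
                             geometry = build(indenter_geometry,
                                              "geometry")),
                        top))
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full generate-track-invert-report pipeline
#'
#' Generates the ground-truth cohort, simulates and analyses every subject
#' in both phases (pre/post treatment), assembles the per-subject results
#' table, builds the statistical report, and (when `out_dir` is set) writes
#' the report tables and a JSON run manifest. Deterministic under a fixed
#' seed: identical configuration and seed reproduce byte-identical report
#' tables.
#'
#' @param config a [run_config()].
#' @return list with `report` (a `cohort_report`), `records`, `cohort` and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  cohort <- tryCatch(make_cohort(config$cohort),
                     error = function(e) stop("[generate] ", conditionMessage(e),
                                              call. = FALSE))
  timings["generate"] <- tic() - t0
  stage_log(v, "generate", "%d subjects in %d arms", length(cohort),
            length(config$cohort$arms))

  t0 <- tic()
  records <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    one <- function(truth, phase) {
      cfg <- config$acquisition
      ## per-subject, per-phase noise stream
      cfg$seed <- child_seed(config$cohort$seed, 1000L + 2L * i + phase)
      res <- tryCatch(
        analyze_subject(truth, config$protocol, cfg, config$geometry,
                        mode = config$mode,
                        h_convention = config$h_convention,
                        cycles = NULL),
        error = function(e) stop("[analyze] subject ", s$subject_id, ": ",
                                 conditionMessage(e), call. = FALSE))
      c(thickness = res$h0_mm, E1 = res$triplet$E1, E2 = res$triplet$E2,
        E3 = res$triplet$E3)
    }
    pre <- one(s$pre, 0L); post <- one(s$post, 1L)
    data.frame(subject_id = s$subject_id, group = s$group,
               thickness_pre = pre[["thickness"]],
               thickness_post = post[["thickness"]],
               E1_pre = pre[["E1"]], E1_post = post[["E1"]],
               E2_pre = pre[["E2"]], E2_post = post[["E2"]],
               E3_pre = pre[["E3"]], E3_post = post[["E3"]])
  }))
  timings["analyze"] <- tic() - t0
  stage_log(v, "analyze", "%d subject-phases (%s mode)", 2 * nrow(records),
            config$mode)

  t0 <- tic()
  report <- tryCatch(build_report(records),
                     error = function(e) stop("[report] ", conditionMessage(e),
                                              call. = FALSE))
  timings["report"] <- tic() - t0

  manifest <- list(
    package_version = as.character(utils::packageVersion("scarindent")),
    seed = config$cohort$seed,
    mode = config$mode,
    config_hash = config_hash(config),
    n_subjects = nrow(records),
    stage_seconds = as.list(round(timings, 3)))

  if (!is.null(config$out_dir)) {
    paths <- write_report(report, config$out_dir)
    manifest$outputs <- basename(paths)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stage_log(v, "write", "%d tables -> %s", length(paths), config$out_dir)
  }

  list(report = report, records = records, cohort = cohort,
       manifest = manifest)
}

## md5 of the canonical JSON serialization of the configuration (timings and
## output paths excluded), so identical scientific settings hash identically
config_hash <- function(config) {
  cfg <- config[c("cohort", "protocol", "acquisition", "geometry", "mode",
                  "h_convention", "drop_first_cycle")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
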