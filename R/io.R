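#' Write a synthetic study to disk
#'
#' One CSV per trace (`fish<ID>_airsat.csv`: time_s, airsat;
#' `fish<ID>_flow.csv`: time_s, flow_ml_min; `fish<ID>_calibration.csv`:
#' true, recorded), a `metadata.csv` with one row per fish, a `truth.json`
#' with the per-fish ground-truth records, and a `design.yaml` snapshot of
#' the scalar design parameters.
#'
#' @param study A `respicard_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "respicard_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(study$fish))) {
    tr <- study$traces[[i]]
    utils::write.csv(tr$airsat, file.path(dir, sprintf("fish%02d_airsat.csv", i)),
                     row.names = FALSE)
    utils::write.csv(tr$flow, file.path(dir, sprintf("fish%02d_flow.csv", i)),
                     row.names = FALSE)
    utils::write.csv(tr$calibration,
                     file.path(dir, sprintf("fish%02d_calibration.csv", i)),
                     row.names = FALSE)
  }
  utils::write.csv(study$fish, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       digits = NA)
  d <- study$design
  scal <- d[vapply(d, function(x) is.numeric(x) || is.character(x),
                   logical(1))]
  scal$flush_s <- d$schedule$flush_s
  scal$measure_s <- d$schedule$measure_s
  yaml::write_yaml(scal, file.path(dir, "design.yaml"))
  invisible(dir)
}

#' Read a study design from a YAML file
#'
#' Reads the scalar fields written by [write_study()] (or hand-written) and
#' rebuilds a [study_design()]; unknown keys are ignored, missing keys take
#' the design defaults.
#'
#' @param path YAML file.
#' @return A `study_design`.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$flush_s) || !is.null(y$measure_s)) {
    y$schedule <- cycle_schedule(y$flush_s %||% 240, y$measure_s %||% 360)
    y$flush_s <- NULL; y$measure_s <- NULL
  }
  known <- names(formals(study_design))
  do.call(study_design, y[intersect(names(y), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a study report
#'
#' Per-group mean +/- s.e.m. tables for the metabolic and cardiac variables,
#' two-way ANOVA effect tables, EPOC summaries restricted to recovered fish
#' (with the non-recovered count footnoted per group), and the post-exercise
#' time-course grid. Returned as a list that serialises losslessly to JSON.
#'
#' @param phenotypes Phenotype tibble from [analyze_study()].
#' @param cardiac Cardiac summary tibble from [analyze_study()] (optional).
#' @param transforms Named list variable -> transformation for the ANOVA
#'   (see [two_way_anova()]); variables not listed are untransformed. The
#'   default mirrors the package's variance-stabilising registry: log for
#'   resting CO and SV scope, square root for maximum fH, square for
#'   maximum SV.
#' @return A `respicard_report` list: `groups`, `effects`, `epoc`,
#'   `n_not_recovered`.
#' @export
build_report <- function(phenotypes, cardiac = NULL,
                         transforms = list(co_rest = "log", sv_scope = "log",
                                           fh_max = "sqrt", sv_max = "square")) {
  if (!is.null(cardiac)) {
    orphans <- union(setdiff(phenotypes$fish_id, cardiac$fish_id),
                     setdiff(cardiac$fish_id, phenotypes$fish_id))
    if (length(orphans) > 0) {
      stop("fish ids not present in both tables: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
  }
  met_vars <- c("smr", "mmr", "aerobic_scope")
  card_vars <- c("co_rest", "co_max", "co_scope", "fh_rest", "fh_max",
                 "fh_scope", "sv_rest", "sv_max", "sv_scope")
  pick_transform <- function(v, x) {
    tr <- transforms[[v]] %||% "none"
    # log/sqrt require strictly positive data; fall back rather than drop fish
    if (tr %in% c("log", "sqrt") && any(x <= 0, na.rm = TRUE)) tr <- "none"
    tr
  }
  groups <- group_summary(phenotypes, met_vars)
  effects <- list()
  for (v in met_vars) {
    effects[[v]] <- two_way_anova(phenotypes, v, "salinity_group",
                                  "surgery_group",
                                  transform = pick_transform(v, phenotypes[[v]]))
  }
  if (!is.null(cardiac)) {
    groups <- rbind(groups, group_summary(cardiac, card_vars))
    for (v in card_vars) {
      effects[[v]] <- two_way_anova(cardiac, v, "salinity_group",
                                    "surgery_group",
                                    transform = pick_transform(v, cardiac[[v]]))
    }
  }
  rec <- phenotypes[phenotypes$recovered %in% TRUE, ]
  epoc_tab <- group_summary(rec, c("epoc", "epoc_duration", "epoc_rate"))
  nr <- stats::aggregate(list(n_not_recovered = !phenotypes$recovered),
                         by = list(salinity_group = phenotypes$salinity_group,
                                   surgery_group = phenotypes$surgery_group),
                         FUN = sum)
  out <- list(groups = groups,
              effects = lapply(effects, function(e)
                tibble::tibble(term = e$term, df = e$df,
                               df_resid = e$df_resid, F = e$F, p = e$p)),
              epoc = epoc_tab, n_not_recovered = tibble::as_tibble(nr))
  class(out) <- "respicard_report"
  out
}

#' Serialise a report to JSON and back
#'
#' @param report A `respicard_report`.
#' @param path JSON file path.
#' @return `read_report()` returns the reloaded report (tibbles restored).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(groups = tibble::as_tibble(raw$groups),
              effects = lapply(raw$effects, tibble::as_tibble),
              epoc = tibble::as_tibble(raw$epoc),
              n_not_recovered = tibble::as_tibble(raw$n_not_recovered))
  class(out) <- "respicard_report"
  out
}
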