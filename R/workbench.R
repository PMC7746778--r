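#' Load and validate a benchmark run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, and fills defaults
#' from [metaboThresholds()]. A configuration names either on-disk inputs
#' (`reference`, `functions`, `metabolome`, `metadata` paths) or a
#' `synthetic` block of [simulatePairedCohort()] parameters; the pipelines
#' to run (`mangosteen`, `cmp`, `ml`); an optional `contrast` (case and
#' control labels); optional `markers` for single-copy normalization ahead
#' of CMP scoring; a `seed`; and an optional `outdir` for reports.
#'
#' @param path YAML file path.
#' @return A validated config list (class `RunConfig`).
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname loadRunConfig
#' @param cfg a config list built in code.
#' @export
validateRunConfig <- function(cfg) {
  known <- c("pipelines", "seed", "outdir", "thresholds", "contrast",
             "reference", "functions", "metabolome", "metadata", "markers",
             "synthetic")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg$pipelines <- if (is.null(cfg$pipelines)) c("mangosteen", "cmp", "ml")
                   else unlist(cfg$pipelines)
  badp <- setdiff(cfg$pipelines, c("mangosteen", "cmp", "ml"))
  if (length(badp)) stop("unknown pipeline(s): ", paste(badp, collapse = ", "))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$thresholds <- do.call(metaboThresholds,
                            if (is.null(cfg$thresholds)) list()
                            else cfg$thresholds)
  if (!is.null(cfg$contrast) &&
      !all(c("case", "control") %in% names(cfg$contrast)))
    stop("contrast needs 'case' and 'control' labels")
  has_paths <- !is.null(cfg$functions) && !is.null(cfg$metabolome)
  if (!has_paths && is.null(cfg$synthetic))
    stop("config needs either input paths (functions, metabolome) or a ",
         "'synthetic' block")
  if (has_paths) {
    for (k in c("reference", "functions", "metabolome", "metadata")) {
      if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
        stop("config path does not exist: ", k, " = ", cfg[[k]])
    }
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    ref_args <- args$reference
    args$reference <- NULL
    if (is.null(args$seed)) args$seed <- stageSeed(cfg$seed, "synthetic")
    ref <- do.call(makeReference,
                   c(ref_args, list(seed = stageSeed(cfg$seed, "reference"))))
    sim <- do.call(simulatePairedCohort, c(list(ref = ref), args))
    list(ref = ref, funcs = sim$funcs, metab = sim$metab, truth = sim$truth)
  } else {
    ref <- if (!is.null(cfg$reference)) readReferenceMap(cfg$reference) else NULL
    funcs <- readAbundanceTable(cfg$functions, metadata = cfg$metadata)
    metab <- readAbundanceTable(cfg$metabolome, metadata = cfg$metadata)
    list(ref = ref, funcs = funcs, metab = metab, truth = NULL)
  }
}

.stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage, paste(..., collapse = " "),
                  as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end prediction benchmark
#'
#' Executes the selected prediction pipelines on paired function/metabolome
#' tables and scores each against the measured metabolome, reproducing the
#' full comparison design: occurrence evaluation (prevalence-filtered
#' presence sets, precision/recall/F1), differential evaluation
#' (differential-function detection feeding the relationship-table
#' prediction; abundance differential tests for CMP and regression
#' predictions), Procrustes comparison for the abundance pipelines, the
#' random-draw coverage null, and the label-shuffling differential null.
#' Every random stage consumes a child seed derived from the config seed
#' and the stage name, so runs are reproducible end to end.
#'
#' @param config a `RunConfig` from [loadRunConfig()] /
#'   [validateRunConfig()], or a plain list passed through the validator.
#' @return An `EvalReport` list: per pipeline, the occurrence and
#'   differential `EvalMetrics`, null distributions with empirical p, and
#'   (abundance pipelines) a `ProcrustesResult`; plus the thresholds and
#'   seed for provenance. Written as JSON and TSV when `outdir` is set.
#' @export
runBenchmark <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validateRunConfig(config)
  th <- config$thresholds
  t0 <- as.numeric(Sys.time())
  inputs <- .load_inputs(config)
  ref <- inputs$ref; funcs <- inputs$funcs; metab <- inputs$metab
  .stage_log("load", t0, sprintf("functions %dx%d, metabolome %dx%d",
                                 nrow(funcs), ncol(funcs),
                                 nrow(metab), ncol(metab)))

  ## contrast restriction
  g <- sampleGroups(funcs)
  if (!is.null(config$contrast)) {
    keep <- names(g)[g %in% unlist(config$contrast)]
    funcs <- funcs[, intersect(sampleIDs(funcs), keep)]
    metab <- metab[, intersect(sampleIDs(metab), keep)]
    g <- sampleGroups(funcs)
  }
  caseLabel <- if (!is.null(config$contrast)) config$contrast$case
               else sort(unique(unname(g)))[1]
  if (is.null(g)) stop("sample group labels are required (metadata 'group')")

  ## measured truth sets
  measured_occ <- occurrenceFromAbundance(metab, th$prevalence_metabolites)
  metab_f <- prevalenceFilter(metab, th$prevalence_metabolites)
  measured_dt <- diffMetabolitesTtest(metab_f, caseLabel = caseLabel,
                                      alpha = th$alpha_fdr)
  measured_diff <- differentialFeatures(measured_dt)
  .stage_log("measured", t0, sprintf("%d occurring, %d differential",
                                     length(measured_occ), length(measured_diff)))
  dict <- if (!is.null(ref)) chemicalDictionary(ref) else
    sort(unique(featureIDs(metab)))

  report <- list(seed = config$seed, thresholds = th,
                 contrast = list(case = caseLabel),
                 measured = list(n_occurring = length(measured_occ),
                                 n_differential = length(measured_diff)),
                 pipelines = list())

  eval_pipeline <- function(occ_set, diff_set, pred_table = NULL,
                            null_diff, name) {
    occ <- setMetrics(occ_set, measured_occ)
    diffm <- setMetrics(diff_set, measured_diff)
    nc <- if (length(occ_set))
      nullCoverage(dict, length(occ_set), measured_occ, occ,
                   nNull = th$n_null, seed = stageSeed(config$seed,
                                                       paste0("cov:", name)))
    else NULL
    pr <- if (!is.null(pred_table))
      procrustesCompare(pred_table, metab_f, nPerm = th$n_procrustes_perm,
                        seed = stageSeed(config$seed, paste0("proc:", name)))
    else NULL
    list(occurrence = occ, differential = diffm, null_coverage = nc,
         null_differential = null_diff, procrustes = pr,
         n_predicted_occurrence = length(occ_set),
         n_predicted_differential = length(diff_set))
  }

  if ("mangosteen" %in% config$pipelines) {
    if (is.null(ref)) stop("[mangosteen] a reference map is required")
    occ_set <- mangosteenOccurrence(funcs, ref)
    funcs_f <- prevalenceFilter(funcs, th$prevalence_functions)
    dt <- nbWaldDiffFunctions(funcs_f, caseLabel = caseLabel,
                              alpha = th$alpha_fdr)
    diff_set <- mangosteenDifferential(differentialFeatures(dt), ref)
    obs <- setMetrics(diff_set, measured_diff)
    nd <- nullDifferential("shuffle-genes", funcs = funcs, ref = ref,
                           measuredDiff = measured_diff, observed = obs,
                           caseLabel = caseLabel, alpha = th$alpha_fdr,
                           prevalence = th$prevalence_functions,
                           nNull = th$n_null,
                           seed = stageSeed(config$seed, "nd:mangosteen"))
    report$pipelines$mangosteen <-
      eval_pipeline(occ_set, diff_set, NULL, nd, "mangosteen")
    .stage_log("mangosteen", t0, sprintf("occ F1 %.3f, diff F1 %.3f",
               report$pipelines$mangosteen$occurrence$f1,
               report$pipelines$mangosteen$differential$f1))
  }

  if ("cmp" %in% config$pipelines) {
    if (is.null(ref)) stop("[cmp] a reference map is required")
    base <- if (!is.null(config$markers))
      singleCopyNormalize(funcs, unlist(config$markers)) else funcs
    cmp <- suppressWarnings(computeCMP(base, ref))
    occ_set <- occurrenceFromAbundance(cmp, th$prevalence_metabolites)
    cmp_f <- prevalenceFilter(cmp, th$prevalence_metabolites)
    dt <- diffMetabolitesRanksum(cmp_f, caseLabel = caseLabel,
                                 alpha = th$alpha_fdr)
    diff_set <- differentialFeatures(dt)
    obs <- setMetrics(diff_set, measured_diff)
    nd <- nullDifferential("shuffle-metabolites", pred = cmp_f,
                           test = "ranksum", measuredDiff = measured_diff,
                           observed = obs, caseLabel = caseLabel,
                           alpha = th$alpha_fdr, nNull = th$n_null,
                           seed = stageSeed(config$seed, "nd:cmp"))
    report$pipelines$cmp <- eval_pipeline(occ_set, diff_set, cmp_f, nd, "cmp")
    .stage_log("cmp", t0, sprintf("occ F1 %.3f, diff F1 %.3f",
               report$pipelines$cmp$occurrence$f1,
               report$pipelines$cmp$differential$f1))
  }

  if ("ml" %in% config$pipelines) {
    loso <- losoPredict(metab, funcs, seed = stageSeed(config$seed, "ml"),
                        thresholds = th)
    pred <- loso$predicted
    occ_set <- occurrenceFromAbundance(pred, th$prevalence_metabolites)
    pred_f <- prevalenceFilter(pred, th$prevalence_metabolites)
    dt <- suppressWarnings(diffMetabolitesTtest(pred_f, caseLabel = caseLabel,
                                                alpha = th$alpha_fdr))
    diff_set <- differentialFeatures(dt)
    obs <- setMetrics(diff_set, measured_diff)
    nd <- if (nrow(pred_f) >= 2)
      nullDifferential("shuffle-metabolites", pred = pred_f, test = "ttest",
                       measuredDiff = measured_diff, observed = obs,
                       caseLabel = caseLabel, alpha = th$alpha_fdr,
                       nNull = th$n_null,
                       seed = stageSeed(config$seed, "nd:ml"))
    else NULL
    pr_tab <- if (nrow(pred_f) >= 2) pred_f else NULL
    report$pipelines$ml <- eval_pipeline(occ_set, diff_set, pr_tab, nd, "ml")
    .stage_log("ml", t0, sprintf("occ F1 %.3f, diff F1 %.3f",
               report$pipelines$ml$occurrence$f1,
               report$pipelines$ml$differential$f1))
  }

  if (!is.null(config$outdir)) writeEvalReport(report, config$outdir)
  report
}

#' Write an EvalReport to disk
#'
#' Emits `report.json` (full report, null replicate values included for
#' audit) and `metrics.tsv` (one row per pipeline and evaluation with
#' precision/recall/F1) under `outdir`.
#'
#' @param report an `EvalReport` list from [runBenchmark()].
#' @param outdir output directory (created if missing).
#' @export
writeEvalReport <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.report_for_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  rows <- list()
  for (p in names(report$pipelines)) {
    for (sec in c("occurrence", "differential")) {
      m <- report$pipelines[[p]][[sec]]
      rows[[paste(p, sec)]] <- data.frame(
        pipeline = p, evaluation = sec, tp = m$tp, fp = m$fp, fn = m$fn,
        precision = m$precision, recall = m$recall, f1 = m$f1)
    }
  }
  write.table(do.call(rbind, rows), file.path(outdir, "metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

.report_for_json <- function(x) {
  if (is.list(x)) return(lapply(x, .report_for_json))
  x
}

#' Collect a metric table across datasets
#'
#' Reshapes a list of per-dataset `EvalReport`s into the pipelines-by-
#' datasets matrix consumed by [comparePipelinesSignedRank()].
#'
#' @param reports named list of `EvalReport`s (names are dataset IDs).
#' @param section `"occurrence"` or `"differential"`.
#' @param metric `"precision"`, `"recall"` or `"f1"`.
#' @return Numeric matrix, pipelines by datasets.
#' @export
collectMetricTable <- function(reports, section = c("occurrence", "differential"),
                               metric = "f1") {
  section <- match.arg(section)
  pipes <- unique(unlist(lapply(reports, function(r) names(r$pipelines))))
  out <- matrix(NA_real_, length(pipes), length(reports),
                dimnames = list(pipes, names(reports)))
  for (d in names(reports)) for (p in pipes) {
    m <- reports[[d]]$pipelines[[p]][[section]]
    if (!is.null(m)) out[p, d] <- m[[metric]]
  }
  out
}
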