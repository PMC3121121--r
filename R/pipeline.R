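#' Assemble a pipeline run configuration
#'
#' Holds the paths and the method constants: 1.4 A probe, 10.0 A^2 exposure
#' threshold, 2.75 A contact padding (a water diameter), 2.0 kcal/mol
#' hot-spot cutoff.
#'
#' @param pdb path to the complex PDB file.
#' @param side_a,side_b chain partition.
#' @param mutations optional path to a mutation CSV with columns `chain`,
#'   `resno`, optional `insert`, optional `wt_aa`, and `ddg` (kcal/mol).
#' @param out_dir output directory.
#' @param probe,sasa_threshold,pad,ddg_threshold method constants.
#' @param mode `"DBAC"` or `"AC"` feature set.
#' @param protocol `"loocv"` or `"leave_n_out"`; `n_out` group size.
#' @param include_waters keep buried waters as contact-graph nodes.
#' @param n_points Shrake-Rupley points per atom.
#' @param seed top-level seed for the SVM protocol.
#' @return a `dbac_config` list.
#' @export
dbac_config <- function(pdb, side_a, side_b, mutations = NULL,
                        out_dir = ".", probe = 1.4, sasa_threshold = 10.0,
                        pad = 2.75, ddg_threshold = 2.0,
                        mode = c("DBAC", "AC"),
                        protocol = c("loocv", "leave_n_out"), n_out = 5,
                        include_waters = TRUE, n_points = 960, seed = 0) {
  stopifnot(probe > 0, sasa_threshold >= 0, pad > 0, ddg_threshold > 0)
  structure(list(pdb = pdb, side_a = side_a, side_b = side_b,
                 mutations = mutations, out_dir = out_dir, probe = probe,
                 sasa_threshold = sasa_threshold, pad = pad,
                 ddg_threshold = ddg_threshold, mode = match.arg(mode),
                 protocol = match.arg(protocol), n_out = n_out,
                 include_waters = include_waters, n_points = n_points,
                 seed = seed),
            class = "dbac_config")
}

#' Load a configuration from a YAML or JSON file
#'
#' @param file path; `.yaml`/`.yml` parsed with \pkg{yaml}, otherwise JSON.
#' @return a `dbac_config`.
#' @export
read_config <- function(file) {
  raw <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs", call. = FALSE)
    yaml::read_yaml(file)
  } else jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(dbac_config, raw)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full hot-spot pipeline
#'
#' structure -> SASA -> water pruning -> contact graph -> burial levels ->
#' feature table, and, when a mutation table is supplied, nested
#' cross-validated SVM classification with evaluation metrics and the
#' Mann-Whitney ddG analysis.  Artifacts (`features.csv`, `report.json`,
#' `manifest.json`) are written to `config$out_dir`; two runs with the same
#' configuration produce byte-identical files.
#'
#' @param config a `dbac_config` (or path accepted by [read_config()]).
#' @return invisibly, a list with `features` (data.frame), `report` (list
#'   or NULL), and the intermediate objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "dbac_config"))
  x <- pipeline_stage("read_structure",
    read_structure(config$pdb, config$side_a, config$side_b))
  message("parsed ", nrow(x$atoms), " atoms (",
          sum(x$atoms$is_water), " waters)")
  sasa <- pipeline_stage("sasa",
    compute_sasa(x, config$probe, config$n_points))
  exposed <- label_exposure(sasa, config$sasa_threshold)
  xp <- prune_exposed_waters(x, exposed)
  keep <- !(x$atoms$is_water & exposed)
  message("pruned ", sum(!keep), " exposed waters; ",
          sum(xp$atoms$is_water), " buried waters retained")
  graph <- pipeline_stage("contact_graph",
    build_contact_graph(xp, exposed[keep], pad = config$pad,
                        include_waters = config$include_waters))
  message("contact graph: ", nrow(graph$edges), " edges")
  burial <- pipeline_stage("burial_levels", atom_burial_levels(graph))
  residues <- NULL
  ddg <- NULL
  if (!is.null(config$mutations)) {
    mut <- pipeline_stage("mutations",
      utils::read.csv(config$mutations, stringsAsFactors = FALSE))
    if (is.null(mut$insert)) mut$insert <- ""
    residues <- mut[, c("chain", "resno", "insert")]
    ddg <- mut$ddg
  }
  feats <- pipeline_stage("features",
    if (is.null(residues))
      feature_table(graph$structure, graph, burial, mode = config$mode)
    else
      feature_table(graph$structure, graph, burial, residues, config$mode))
  report <- NULL
  if (!is.null(ddg)) {
    feats$ddg <- ddg
    feats$label <- label_hotspots(ddg, config$ddg_threshold)
    fx <- as.matrix(feats[, intersect(colnames(feats), AC_COLUMNS)])
    if (length(unique(feats$label)) == 2 && nrow(fx) >= 3) {
      cv <- pipeline_stage("train_eval",
        dbac_cv(fx, feats$label, protocol = config$protocol,
                n_out = config$n_out, seed = config$seed))
      ev <- evaluate(cv$predicted, feats$label)
      mw <- if (any(cv$predicted) && !all(cv$predicted))
        mann_whitney(ddg[cv$predicted], ddg[!cv$predicted]) else NA_real_
      report <- list(
        n = length(ddg), n_hotspot = sum(feats$label),
        confusion = list(tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn),
        metrics = list(sensitivity = ev$sensitivity,
                       precision = ev$precision,
                       specificity = ev$specificity,
                       accuracy = ev$accuracy, f1 = ev$f1),
        mann_whitney_p = mw,
        params = cv$params)
    } else {
      warning("mutation table has a single class or too few rows; ",
              "skipping SVM evaluation", call. = FALSE)
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(report))
      jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(package = "dbac",
                     version = as.character(utils::packageVersion("dbac")),
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(features = feats, report = report, structure = xp,
                 graph = graph, burial = burial, sasa = sasa,
                 exposed = exposed))
}
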