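#' Read a feature x sample matrix from TSV or CSV
#'
#' The first column holds feature identifiers and the header row holds
#' sample identifiers; the delimiter (tab or comma) is auto-detected from
#' the header line. Duplicate feature identifiers and missing cells are
#' rejected with messages naming the offending feature/sample.
#'
#' @param path File path.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_omic_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs a feature column and at least ",
                         "one sample column: ", path, call. = FALSE)
  feats <- as.character(df[[1L]])
  if (anyDuplicated(feats)) {
    dup <- feats[duplicated(feats)][1L]
    stop(sprintf("duplicate feature identifier '%s' in %s", dup, path),
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric values in matrix file: ", path, call. = FALSE)
  rownames(mat) <- feats
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("missing value at feature '%s', sample '%s' in %s; ",
                        "missing values must be removed or imputed before ",
                        "the analysis"),
                 feats[idx[1L]], colnames(mat)[idx[2L]], path), call. = FALSE)
  }
  mat
}

#' Write a feature x sample matrix as TSV
#'
#' @param mat Numeric matrix with feature row names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_omic_matrix <- function(mat, path) {
  utils::write.table(data.frame(feature = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample group labels
#'
#' Two-column TSV/CSV: sample identifier, group label.
#'
#' @param path File path.
#' @return Named character vector (names = sample identifiers).
#' @export
read_group_labels <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("group file needs two columns (sample, group)",
                         call. = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read and validate a study configuration
#'
#' YAML or JSON with an `omics` list (each entry: `name`, `path`,
#' `groups_path` or shared top-level `groups_path`, `data_type`, `p1`,
#' optional `cost`) and an optional `constraints` block (`min_power`,
#' `avg_power`, `fdr`, `d0`, `k`, `equal_size`, `n_max`). Validation (file
#' existence, data types, numeric ranges) happens before any matrix is
#' read.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return List with validated `omics` entries and a `constraints` list.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$omics) || length(cfg$omics) == 0L)
    stop("config must list at least one omic under `omics`", call. = FALSE)
  omics <- cfg$omics
  if (is.data.frame(omics)) omics <- split(omics, seq_len(nrow(omics)))
  for (i in seq_along(omics)) {
    o <- as.list(omics[[i]])
    for (field in c("name", "path", "data_type", "p1"))
      if (is.null(o[[field]]))
        stop(sprintf("omic entry %d lacks `%s`", i, field), call. = FALSE)
    if (!o$data_type %in% c("normal", "count", "binary"))
      stop(sprintf("omic '%s': unknown data_type '%s'", o$name, o$data_type),
           call. = FALSE)
    if (o$p1 <= 0 || o$p1 >= 1)
      stop(sprintf("omic '%s': p1 must be in (0, 1)", o$name), call. = FALSE)
    if (!file.exists(o$path))
      stop(sprintf("omic '%s': file not found: %s", o$name, o$path),
           call. = FALSE)
    gp <- o$groups_path %||% cfg$groups_path
    if (is.null(gp) || !file.exists(gp))
      stop(sprintf("omic '%s': group-label file missing", o$name),
           call. = FALSE)
    o$groups_path <- gp
    o$cost <- o$cost %||% 1
    omics[[i]] <- o
  }
  cons <- as.list(cfg$constraints %||% list())
  list(omics = omics,
       constraints = design_constraints(
         min_power = cons$min_power %||% 0.6,
         avg_power = cons$avg_power %||% 0.8,
         equal_size = cons$equal_size %||% TRUE,
         n_max = cons$n_max %||% 200),
       fdr = cons$fdr %||% 0.05,
       d0 = cons$d0 %||% 0.8,
       k = cons$k %||% 75,
       seed = cfg$seed %||% 1L,
       out_dir = cfg$out_dir %||% ".")
}

#' Load the pilots described by a study configuration
#'
#' @param config Output of [read_study_config()].
#' @return List of [omic_pilot()] objects.
#' @export
load_pilots <- function(config) {
  lapply(config$omics, function(o) {
    mat <- read_omic_matrix(o$path)
    g <- read_group_labels(o$groups_path)
    missing <- setdiff(colnames(mat), names(g))
    if (length(missing))
      stop(sprintf("omic '%s': no group label for sample(s) %s", o$name,
                   paste(missing, collapse = ", ")), call. = FALSE)
    omic_pilot(o$name, mat, g[colnames(mat)], data_type = o$data_type,
               p1 = o$p1, cost = o$cost)
  })
}

#' Provenance record for a run
#'
#' Machine-readable record of input hashes, seed and resolved parameters,
#' written next to every CLI output.
#'
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed.
#' @param params Named list of resolved parameters.
#' @param path Output JSON path.
#' @return Invisibly, the record list.
#' @export
write_provenance <- function(inputs, seed, params, path) {
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              seed = seed, parameters = params,
              package_version = as.character(utils::packageVersion(
                "multipower")))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
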