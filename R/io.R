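#' Read a square numeric matrix from delimited text
#'
#' Whitespace- or tab-delimited, one row per line, no header (the format
#' used for SC, PL and FC matrices). Non-square content and non-finite or
#' non-numeric cells are rejected with the offending location.
#'
#' @param path File path.
#' @param expected_n Optional required dimension.
#' @return Numeric N x N matrix.
#' @export
load_square_matrix <- function(path, expected_n = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  rows <- strsplit(trimws(readLines(path)), "[ \t]+")
  rows <- rows[vapply(rows, function(r) length(r) > 0 && any(nzchar(r)),
                      logical(1))]
  n <- length(rows)
  lens <- vapply(rows, length, integer(1))
  if (any(lens != n))
    stop(sprintf("non-square matrix in %s: %d rows but row %d has %d columns",
                 path, n, which(lens != n)[1], lens[lens != n][1]))
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric or non-finite cell at row %d, column %d of %s",
                   i, bad[1], path))
    m[i, ] <- v
  }
  if (!is.null(expected_n) && n != expected_n)
    stop(sprintf("expected a %d x %d matrix, got %d x %d",
                 expected_n, expected_n, n, n))
  m
}

#' Write a square matrix as tab-delimited text
#'
#' 17 significant digits so that write/read round trips are exact.
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @export
write_square_matrix <- function(x, path) {
  x <- as.matrix(x)
  lines <- apply(x, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(lines, path)
}

#' Write BOLD time series as delimited text
#'
#' T x N tab-delimited with a one-line header of region labels.
#'
#' @param bold T x N matrix.
#' @param path File path.
#' @param region_ids Region labels (defaults to `R1..RN`).
#' @export
write_bold <- function(bold, path, region_ids = NULL) {
  bold <- as.matrix(bold)
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(ncol(bold)))
  lines <- c(paste(region_ids, collapse = "\t"),
             apply(bold, 1, function(r)
               paste(sprintf("%.17g", r), collapse = "\t")))
  writeLines(lines, path)
}

#' Read BOLD time series written by [write_bold()]
#'
#' @param path File path.
#' @return List with `bold` (T x N matrix) and `region_ids`.
#' @export
load_bold <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t")[[1]]
  rows <- strsplit(lines[-1], "\t")
  m <- t(vapply(rows, function(r) as.numeric(r), numeric(length(ids))))
  if (any(!is.finite(m))) stop(sprintf("non-finite BOLD value in %s", path))
  list(bold = m, region_ids = ids)
}

#' Write a run manifest
#'
#' JSON record of what produced a set of outputs: command, configuration
#' snapshot, master seed and the child-seed table, package version, input
#' file digests and a timestamp. In fixed-noise mode the manifest is
#' sufficient to replay a run bit-exactly.
#'
#' @param path Output path.
#' @param command Command or function name.
#' @param config Named list snapshot of the configuration.
#' @param master_seed Integer master seed.
#' @param child_seeds Named list/vector of derived seeds.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), master_seed = NA,
                           child_seeds = list(), inputs = character()) {
  digests <- lapply(inputs, function(f)
    if (file.exists(f)) list(path = f, bytes = file.size(f),
                             md5 = unname(tools::md5sum(f))) else
      list(path = f, bytes = NA, md5 = NA))
  man <- list(command = command, config = config,
              master_seed = master_seed, child_seeds = child_seeds,
              package_version = as.character(utils::packageVersion("kurafit")),
              inputs = digests,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}

#' Serialize a grid result to JSON plus a node table
#'
#' Writes `<stem>.json` (axes, best point, top five, evaluation count, seed
#' policy) and `<stem>_nodes.tsv` (one row per node: parameters and fit).
#'
#' @param gres A [run_grid_search()] result.
#' @param stem Output path stem.
#' @return Paths of the written files, invisibly.
#' @export
write_grid_result <- function(gres, stem) {
  json_path <- paste0(stem, ".json")
  tsv_path <- paste0(stem, "_nodes.tsv")
  jsonlite::write_json(list(
    dim = gres$grid$dim, c_axis = gres$grid$c_axis,
    tau_axis = gres$grid$tau_axis, sigma_axis = gres$grid$sigma_axis,
    best_point = gres$best_point, best_fit = gres$best_fit,
    top_points = gres$top_points, top_fits = gres$top_fits,
    n_evaluations = gres$n_evaluations, seed_info = gres$seed_info),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tab <- cbind(as.data.frame(gres$nodes), fit = gres$fits)
  write.table(format(tab, digits = 17, trim = TRUE), tsv_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
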