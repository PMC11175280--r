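#' Open or create a planning-record store
#'
#' A lightweight single-file JSON record store for planning results: volume
#' metadata, the configuration snapshot, the ranked recommendation, the Pareto
#' screening summary and any interactive evaluations. Records are immutable
#' once saved, ids are assigned monotonically, writes are atomic (temp file +
#' rename) and every floating-point value is serialized with 17 significant
#' digits so reloading reproduces it bit-exactly.
#'
#' @param path store file; created (with its parent directory) if missing.
#' @return An object of class `plan_store`.
#' @export
plan_store <- function(path) {
  if (!dir.exists(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  if (!file.exists(path)) {
    ok <- tryCatch({ .store_write(path, list(next_id = 1L, records = list())); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      npl_stop(sprintf("cannot create store at '%s'", path), "npl_io_error")
  }
  structure(list(path = path), class = "plan_store")
}

.store_read <- function(store) {
  jsonlite::fromJSON(store$path, simplifyVector = FALSE)
}

.store_write <- function(path, data) {
  tmp <- paste0(path, ".tmp")
  # always_decimal keeps whole-number doubles typed as doubles on re-parse
  json <- jsonlite::toJSON(data, digits = I(17), auto_unbox = TRUE,
                           null = "null", always_decimal = TRUE)
  ok <- tryCatch({ writeLines(json, tmp); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    npl_stop(sprintf("cannot write store file '%s'", path), "npl_io_error")
  }
  invisible(path)
}

#' Assemble a planning record
#'
#' @param volume the planned [label_volume()] (per-role voxel counts and
#'   volumes in mL are summarized into the record).
#' @param config the [planning_config()] used.
#' @param ranked a [rank_paths()] result, or `NULL` when no path was feasible.
#' @param pareto a [global_pareto()] result, or `NULL`.
#' @param fs the `feasible_set` (for the rejection histogram), or `NULL`.
#' @param interactive list of evaluated user paths (rows from
#'   [evaluate_user_path()]), or `NULL`.
#' @param meta free-text metadata (e.g. patient/study identifiers).
#' @return An object of class `planning_record` (not yet saved; no id).
#' @export
planning_record <- function(volume, config, ranked = NULL, pareto = NULL,
                            fs = NULL, interactive = NULL, meta = list()) {
  g <- volume$grid
  voxel_ml <- prod(g$spacing) / 1000
  counts <- vapply(names(volume$role_map), function(r) sum(role_mask(volume, r)), 0)
  rec <- list(
    volume = list(shape = g$shape, spacing = g$spacing, origin = g$origin,
                  role_voxels = as.list(counts),
                  role_volumes_ml = as.list(counts * voxel_ml)),
    config = unclass(config),
    target = if (!is.null(ranked)) ranked$target else if (!is.null(fs)) fs$target else NULL,
    n_feasible = if (!is.null(fs)) n_feasible(fs) else NULL,
    rejections = if (!is.null(fs)) fs$rejections else NULL,
    top_paths = if (!is.null(ranked)) .df_records(ranked$top) else list(),
    pareto = if (!is.null(pareto)) list(
      pair_fronts = lapply(pareto$pair_fronts, as.integer),
      global = as.integer(pareto$global),
      fallback = pareto$fallback) else NULL,
    interactive = if (!is.null(interactive)) lapply(interactive, .df_records) else list(),
    meta = meta)
  structure(rec, class = "planning_record")
}

.df_records <- function(df) {
  if (is.null(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Save a planning record
#'
#' @param store a [plan_store()].
#' @param record a [planning_record()].
#' @return The assigned record id (integer).
#' @export
save_record <- function(store, record) {
  data <- .store_read(store)
  id <- as.integer(data$next_id)
  record$id <- id
  record$saved_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  data$records[[length(data$records) + 1L]] <- unclass(record)
  data$next_id <- id + 1L
  .store_write(store$path, data)
  id
}

#' Load a planning record by id
#'
#' @param store a [plan_store()].
#' @param id record id as returned by [save_record()].
#' @return The record, with numeric fields restored (including infinities).
#' @export
load_record <- function(store, id) {
  data <- .store_read(store)
  for (rec in data$records)
    if (identical(as.integer(rec$id), as.integer(id)))
      return(structure(.restore_numbers(rec), class = "planning_record"))
  npl_stop(sprintf("no record with id %s in '%s'", id, store$path), "npl_not_found")
}

# jsonlite writes Inf/-Inf/NaN as strings; turn them back into numerics
.restore_numbers <- function(x) {
  if (is.list(x)) return(lapply(x, .restore_numbers))
  if (is.character(x) && length(x) == 1L && x %in% c("Inf", "-Inf", "NaN"))
    return(as.numeric(x))
  x
}

#' List saved record ids
#' @param store a [plan_store()].
#' @return Integer vector of ids.
#' @export
list_records <- function(store) {
  data <- .store_read(store)
  vapply(data$records, function(r) as.integer(r$id), 0L)
}

#' Export a stored planning record as a human-readable report
#'
#' JSON exports the whole record; CSV exports the recommended paths, one row
#' per path, with entry and target coordinates, absolute soft values `S1`-`S3`,
#' normalized scores and `Pscore`.
#'
#' @param store a [plan_store()].
#' @param id record id.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(store, id, path, format = c("json", "csv")) {
  if (!is.character(format) || !all(format %in% c("json", "csv")))
    npl_stop(sprintf("unknown report format '%s'", paste(format, collapse = ",")),
             "npl_usage_error")
  format <- match.arg(format)
  rec <- load_record(store, id)
  if (format == "json") {
    jsonlite::write_json(unclass(rec), path, digits = I(17), auto_unbox = TRUE,
                         null = "null", always_decimal = TRUE)
  } else {
    rows <- lapply(rec$top_paths, function(p) as.data.frame(p[!vapply(p, is.null, TRUE)]))
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame()
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
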