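AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

LABEL_LEVELS <- c("tumor_reactive", "non_tumor_reactive", "unknown")
AVIDITY_LEVELS <- c("high", "low", "unknown")

#' Clonotype-level table
#'
#' One row per (patient, clone). Beyond identity and CDR3 sequences the table
#' carries the experimental tumor-reactivity label, model outputs
#' (`trt_score`, `trt_call`), the structural-avidity call, and the clone's
#' in-repertoire frequency.
#'
#' @param df data.frame with at least `clone_id` and `patient`. Optional
#'   columns: `cdr3a`, `cdr3b` (amino-acid strings over the 20-letter
#'   alphabet; NA allowed), `n_cells` (positive integer), `label`
#'   (`tumor_reactive` / `non_tumor_reactive` / `unknown`), `trt_score`,
#'   `trt_call` (logical), `avidity_call` (`high` / `low` / `unknown`),
#'   `frequency` (within-patient, sums to at most 1).
#' @return a data.frame of class `CloneTable`.
#' @export
CloneTable <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("clone_id", "patient")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("clone_id", "patient")]))
    stop("(clone_id, patient) pairs must be unique")
  defaults <- list(cdr3a = NA_character_, cdr3b = NA_character_,
                   n_cells = NA_integer_, label = "unknown",
                   trt_score = NA_real_, trt_call = NA,
                   avidity_call = "unknown", frequency = NA_real_)
  for (col in names(defaults))
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  df$label[is.na(df$label) | df$label == ""] <- "unknown"
  df$avidity_call[is.na(df$avidity_call) | df$avidity_call == ""] <- "unknown"
  if (!all(df$label %in% LABEL_LEVELS))
    stop("label must be one of: ", paste(LABEL_LEVELS, collapse = ", "))
  if (!all(df$avidity_call %in% AVIDITY_LEVELS))
    stop("avidity_call must be one of: ", paste(AVIDITY_LEVELS, collapse = ", "))
  for (col in c("cdr3a", "cdr3b")) {
    seqs <- df[[col]]
    ok <- is.na(seqs) | seqs == "" |
      !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
    if (!all(ok))
      stop(sprintf("non-amino-acid character in %s at row(s): %s",
                   col, paste(which(!ok), collapse = ", ")))
    df[[col]][!is.na(seqs) & seqs == ""] <- NA_character_
  }
  if (any(!is.na(df$n_cells) & df$n_cells < 1))
    stop("n_cells must be positive")
  freq_sums <- tapply(df$frequency, df$patient, function(f) sum(f, na.rm = TRUE))
  if (any(freq_sums > 1 + 1e-9))
    stop("within-patient frequencies sum to more than 1")
  df$trt_call <- as.logical(df$trt_call)
  rownames(df) <- NULL
  class(df) <- c("CloneTable", "data.frame")
  df
}

#' @export
print.CloneTable <- function(x, ...) {
  cat(sprintf("CloneTable: %d clones, %d patients (%d labeled tumor-reactive)\n",
              nrow(x), length(unique(x$patient)),
              sum(x$label == "tumor_reactive")))
  NextMethod()
}

CLONE_TABLE_COLUMNS <- c("clone_id", "patient", "cdr3a", "cdr3b", "n_cells",
                         "label", "trt_score", "trt_call", "avidity_call",
                         "frequency")

#' Read / write clonotype tables
#'
#' CSV round-trip is lossless for all fields: comma-separated, UTF-8, header
#' required, empty string for absent values, `unknown` serialized explicitly.
#'
#' @param ct a [CloneTable()].
#' @param path CSV file path.
#' @return `read_clone_table` returns a [CloneTable()];
#'   `write_clone_table` returns the path invisibly.
#' @export
write_clone_table <- function(ct, path) {
  stopifnot(inherits(ct, "CloneTable"))
  out <- as.data.frame(ct)[, CLONE_TABLE_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("clone_id", "patient"), names(df))
  for (col in intersect(c("clone_id", "patient"), names(df)))
    df[[col]] <- as.character(df[[col]])
  if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  for (col in c("cdr3a", "cdr3b"))
    if (col %in% names(df)) df[[col]] <- {
      v <- as.character(df[[col]]); v[!is.na(v) & v == ""] <- NA_character_; v
    }
  for (col in c("trt_score", "frequency"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("n_cells" %in% names(df)) df$n_cells <- as.integer(df$n_cells)
  if ("trt_call" %in% names(df)) df$trt_call <- as.logical(df$trt_call)
  CloneTable(df)
}

#' Derive a clone table from cell annotations
#'
#' Collapses the (patient, clone_id) pairs present in a [CellMatrix()] into a
#' [CloneTable()], counting cells per clone. Cells without a clone id are
#' skipped.
#'
#' @param cm a [CellMatrix()].
#' @param extra optional data.frame keyed by `clone_id` with further columns
#'   (cdr3a, cdr3b, label, ...) to merge in.
#' @return a [CloneTable()].
#' @export
clone_table_from_cells <- function(cm, extra = NULL) {
  stopifnot(inherits(cm, "CellMatrix"))
  meta <- cm$cell_meta[!is.na(cm$cell_meta$clone_id), ]
  agg <- stats::aggregate(list(n_cells = meta$barcode),
                          by = list(clone_id = meta$clone_id,
                                    patient = meta$patient),
                          FUN = length)
  if (!is.null(extra)) agg <- merge(agg, extra, by = "clone_id", sort = FALSE)
  agg <- agg[order(agg$patient, agg$clone_id), ]
  CloneTable(agg)
}
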