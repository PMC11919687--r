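#' Tumor-reactivity gene signature
#'
#' Ordered up- and down-regulated gene lists together with the differential
#' expression statistics that produced them and the derivation settings
#' (criterion, length, side, DE method).
#'
#' @param up character vector of upregulated genes (ordered by the selection
#'   criterion, best first).
#' @param down character vector of downregulated genes (may be empty).
#' @param stats data.frame with per-gene `gene`, `logFC`, `p`, `adj_p`.
#' @param meta list with `criterion`, `length`, `side`, `de_method`.
#' @return an object of class `Signature`.
#' @export
Signature <- function(up, down = character(), stats = NULL, meta = list()) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down)))
    stop("up and down gene sets must be disjoint")
  if (anyDuplicated(up) || anyDuplicated(down))
    stop("duplicate genes within a signature side")
  structure(list(up = up, down = down, stats = stats, meta = meta),
            class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature: %d up / %d down genes (%s, criterion=%s, side=%s)\n",
              length(x$up), length(x$down),
              x$meta$de_method %||% "?", x$meta$criterion %||% "?",
              x$meta$side %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write signature TSVs
#'
#' Columns: `gene`, `direction` (up/down), `logFC`, `adj_p`, `rank` (1-based
#' within direction).
#'
#' @param sig a [Signature()].
#' @param path TSV path.
#' @return `read_signature` returns a [Signature()].
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "Signature"))
  row_of <- function(genes, dir) {
    if (!length(genes)) return(NULL)
    st <- sig$stats
    idx <- if (!is.null(st)) match(genes, st$gene) else rep(NA_integer_, length(genes))
    data.frame(gene = genes, direction = dir,
               logFC = if (!is.null(st)) st$logFC[idx] else NA_real_,
               adj_p = if (!is.null(st)) st$adj_p[idx] else NA_real_,
               rank = seq_along(genes))
  }
  out <- rbind(row_of(sig$up, "up"), row_of(sig$down, "down"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "direction"), names(df))
  if (length(miss)) stop("missing signature columns: ", paste(miss, collapse = ", "))
  up <- df$gene[df$direction == "up"][order(df$rank[df$direction == "up"])]
  down <- df$gene[df$direction == "down"][order(df$rank[df$direction == "down"])]
  stats <- data.frame(gene = df$gene, logFC = df$logFC,
                      p = NA_real_, adj_p = df$adj_p)
  Signature(up, down, stats = stats,
            meta = list(length = nrow(df), side = if (length(down)) "both" else "up"))
}
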