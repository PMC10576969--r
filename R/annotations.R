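#' Construct a VmeImageSet from a count matrix and image metadata
#'
#' @param counts numeric matrix, taxa in rows, images in columns; column
#'   names are image ids.
#' @param meta data.frame of per-image metadata with an \code{image_id}
#'   column matching the count columns; optional fields are filled with
#'   \code{NA} (region, depth, substrate, camera, label) or \code{FALSE}
#'   (evidence flags).
#' @return a \linkS4class{VmeImageSet}.
#' @export
VmeImageSet <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (!"image_id" %in% names(meta)) stop("meta must contain image_id")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- meta$image_id
  ord <- match(colnames(counts), meta$image_id)
  if (anyNA(ord)) stop("count columns and meta image_id do not match")
  meta <- meta[ord, , drop = FALSE]
  meta <- .complete_meta(meta)
  cd <- S4Vectors::DataFrame(meta[setdiff(.META_COLS, "image_id")],
                             row.names = meta$image_id)
  storage.mode(counts) <- "double"
  new("VmeImageSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd))
}

.complete_meta <- function(meta) {
  n <- nrow(meta)
  fill <- list(laboratory = NA_character_, site = NA_character_,
               region = NA_character_, depth_m = NA_real_,
               area_m2 = NA_real_, pct_hard_substrate = NA_real_,
               camera = NA_character_, label = NA_character_)
  for (f in names(fill)) {
    if (is.null(meta[[f]])) meta[[f]] <- rep(fill[[f]], n)
    else if (is.character(fill[[f]])) {
      meta[[f]] <- as.character(meta[[f]])
      meta[[f]][!is.na(meta[[f]]) & !nzchar(meta[[f]])] <- NA_character_
    }
  }
  for (f in .FLAG_COLS) {
    if (is.null(meta[[f]])) meta[[f]] <- rep(FALSE, n)
    meta[[f]] <- as.logical(meta[[f]])
    meta[[f]][is.na(meta[[f]])] <- FALSE
  }
  num <- c("depth_m", "area_m2", "pct_hard_substrate")
  for (f in num) meta[[f]] <- as.numeric(meta[[f]])
  meta$label <- normalizeLabels(meta$label)
  meta
}

#' Normalize expert Yes/Maybe/No label tokens
#'
#' Accepts \code{y/yes}, \code{m/maybe}, \code{n/no} in any case; empty
#' strings and \code{NA} stay \code{NA}; anything else is an error.
#'
#' @param x character vector of raw label tokens.
#' @return character vector over \code{Yes}, \code{Maybe}, \code{No}, \code{NA}.
#' @export
normalizeLabels <- function(x) {
  x <- as.character(x)
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[key %in% c("y", "yes")] <- "Yes"
  out[key %in% c("m", "maybe")] <- "Maybe"
  out[key %in% c("n", "no")] <- "No"
  bad <- is.na(out) & !is.na(x) & nzchar(key)
  if (any(bad))
    stop("unknown label token(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a schema-mapping config
#'
#' A YAML file with two optional blocks: \code{columns}, a mapping from file
#' column names to canonical field names (see the package vignette for the
#' canonical set), and \code{taxa}, an explicit list of taxon count columns.
#' When \code{taxa} is omitted, every column not mapped to a metadata field
#' is treated as a taxon.
#'
#' @param path YAML file.
#' @return list with elements \code{columns} (named character) and
#'   \code{taxa} (character or NULL).
#' @export
readSchemaConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cols <- if (!is.null(cfg$columns)) unlist(cfg$columns) else character()
  bad <- setdiff(unname(cols), .META_COLS)
  if (length(bad))
    stop("schema maps to unknown field(s): ", paste(bad, collapse = ", "))
  list(columns = cols, taxa = if (!is.null(cfg$taxa)) unlist(cfg$taxa))
}

#' Read a per-image annotation table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header)
#' into a \linkS4class{VmeImageSet}. Metadata columns are identified by name
#' or remapped through \code{schema}; all remaining columns are taxon
#' counts. Rows violating the dataset invariants (non-positive area,
#' negative or fractional counts, out-of-range substrate, unknown label
#' token, duplicate image id) produce an error naming the offending row and
#' column.
#'
#' @param path delimited text file with a header row.
#' @param schema optional schema config (a path to a YAML file or the list
#'   returned by [readSchemaConfig()]).
#' @param delim \code{","} or \code{"\t"}; \code{NULL} auto-detects.
#' @return a \linkS4class{VmeImageSet}.
#' @export
readAnnotations <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim))
    delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
                 lengths(regmatches(header, gregexpr(",", header)))) "\t"
             else ","
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (is.character(schema)) schema <- readSchemaConfig(schema)
  taxa_cols <- NULL
  if (!is.null(schema)) {
    hit <- names(df) %in% names(schema$columns)
    names(df)[hit] <- unname(schema$columns[names(df)[hit]])
    taxa_cols <- schema$taxa
  }
  if (!"image_id" %in% names(df))
    stop("annotation table needs an image_id column (or a schema mapping one)")
  if (is.null(taxa_cols)) taxa_cols <- setdiff(names(df), .META_COLS)
  miss <- setdiff(taxa_cols, names(df))
  if (length(miss))
    stop("taxon column(s) absent from file: ", paste(miss, collapse = ", "))
  viol <- validateAnnotationTable(df, taxa_cols)
  if (nrow(viol))
    stop("invalid annotation table:\n  ",
         paste(utils::head(sprintf("image '%s', field '%s': %s",
                                   viol$image_id, viol$field, viol$rule), 10),
               collapse = "\n  "))
  counts <- t(as.matrix(df[taxa_cols]))
  colnames(counts) <- df$image_id
  VmeImageSet(counts, df[intersect(.META_COLS, names(df))])
}

#' Validate a raw annotation table
#'
#' Checks the dataset invariants on a plain data.frame before it is turned
#' into a \linkS4class{VmeImageSet}; [readAnnotations()] calls this and
#' refuses invalid files. On a valid table the result has zero rows.
#'
#' @param df data.frame with one row per image.
#' @param taxa character vector naming the count columns.
#' @return data.frame of violations with columns \code{image_id},
#'   \code{field}, \code{rule}.
#' @export
validateAnnotationTable <- function(df, taxa) {
  v <- list()
  add <- function(ids, field, rule)
    v[[length(v) + 1]] <<- data.frame(image_id = as.character(ids),
                                      field = field, rule = rule,
                                      stringsAsFactors = FALSE)
  ids <- as.character(df$image_id)
  dup <- duplicated(ids)
  if (any(dup)) add(unique(ids[dup]), "image_id", "duplicate image_id")
  a <- suppressWarnings(as.numeric(df$area_m2))
  bad <- is.na(a) | a <= 0
  if (any(bad)) add(ids[bad], "area_m2", "area must be a number > 0")
  if (!is.null(df$pct_hard_substrate)) {
    p <- suppressWarnings(as.numeric(df$pct_hard_substrate))
    bad <- !is.na(df$pct_hard_substrate) & (is.na(p) | p < 0 | p > 100)
    if (any(bad))
      add(ids[bad], "pct_hard_substrate", "must lie in [0, 100]")
  }
  if (!is.null(df$depth_m)) {
    d <- suppressWarnings(as.numeric(df$depth_m))
    bad <- !is.na(df$depth_m) & !is.na(as.character(df$depth_m)) &
      nzchar(as.character(df$depth_m)) & (is.na(d) | d < 0)
    if (any(bad)) add(ids[bad], "depth_m", "must be a non-negative number")
  }
  for (tc in taxa) {
    n <- suppressWarnings(as.numeric(df[[tc]]))
    bad <- is.na(n) | n < 0 | n != floor(n)
    if (any(bad))
      add(ids[bad], tc, "counts must be non-negative integers")
  }
  if (!is.null(df$label)) {
    lab <- tolower(trimws(as.character(df$label)))
    bad <- !is.na(df$label) & nzchar(lab) &
      !lab %in% c("y", "yes", "m", "maybe", "n", "no")
    if (any(bad)) add(ids[bad], "label", "label must be Yes/Maybe/No")
  }
  if (!length(v))
    return(data.frame(image_id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' @describeIn validateAnnotationTable validate an existing
#'   \linkS4class{VmeImageSet} (returns an empty violation table for any
#'   object that passed construction).
#' @param x a \code{VmeImageSet}
#' @export
validateAnnotations <- function(x) {
  stopifnot(is(x, "VmeImageSet"))
  validateAnnotationTable(as.data.frame(.annotation_frame(x)),
                          rownames(x))
}

# Flatten a VmeImageSet to the canonical on-disk layout: metadata columns in
# fixed order, then taxa alphabetically.
.annotation_frame <- function(x) {
  cd <- as.data.frame(colData(x))
  df <- cbind(data.frame(image_id = colnames(x), stringsAsFactors = FALSE),
              cd[setdiff(.META_COLS, "image_id")])
  cts <- t(assay(x, "counts"))
  cts <- cts[, order(colnames(cts)), drop = FALSE]
  cbind(df, as.data.frame(cts))
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else if (v == floor(v) && abs(v) < 1e15)
      sprintf("%d", as.integer(v)) else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a per-image annotation table
#'
#' Deterministic CSV writer: metadata columns in canonical order, taxon
#' columns alphabetically, numbers formatted losslessly so that
#' \code{readAnnotations(writeAnnotations(x))} reproduces \code{x} exactly
#' and repeated writes are byte-identical.
#'
#' @param x a \linkS4class{VmeImageSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(x, path) {
  df <- .annotation_frame(x)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- .fmt_num(df[[nm]])
    else if (is.logical(df[[nm]])) df[[nm]] <- ifelse(df[[nm]], "TRUE", "FALSE")
    else { df[[nm]] <- as.character(df[[nm]]); df[[nm]][is.na(df[[nm]])] <- "" }
  }
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste,
               c(unname(as.list(df)), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @export
setMethod("show", "VmeImageSet", function(object) {
  cat("VmeImageSet:", nrow(object), "taxa x", ncol(object), "images\n")
  if (ncol(object)) {
    lab <- colData(object)$label
    cat("  labels:",
        paste(sprintf("%s=%d", .LABELS,
                      vapply(.LABELS, function(l) sum(lab == l, na.rm = TRUE),
                             integer(1))), collapse = " "),
        sprintf("unlabelled=%d\n", sum(is.na(lab))))
    cat(sprintf("  area: %.3g-%.3g m2; sites: %d\n",
                min(colData(object)$area_m2), max(colData(object)$area_m2),
                length(unique(colData(object)$site))))
  }
})
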