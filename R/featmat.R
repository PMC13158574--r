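#' Feature matrix container
#'
#' Recordings-by-features numeric matrix with row identifiers and optional
#' binary group labels. Missing values (features undefined for a recording,
#' e.g. voiced-only measures on silent audio) are `NA` and are median-imputed
#' later, at modeling time.
#'
#' @param values Numeric matrix (rows = recordings).
#' @param row_ids Character vector of recording/subject identifiers.
#' @param feature_names Unique feature names (one per column).
#' @param labels Optional vector of labels (`"positive"`/`"control"` or 0/1).
#' @return Object of class `adspeech_fm`.
#' @export
feature_matrix <- function(values, row_ids, feature_names, labels = NULL) {
  values <- as.matrix(values)
  if (anyDuplicated(feature_names))
    stop("duplicate feature names")
  if (nrow(values) != length(row_ids) || ncol(values) != length(feature_names))
    stop("feature matrix dimensions do not match ids/names")
  if (!is.null(labels) && length(labels) != length(row_ids))
    stop("labels length mismatch")
  bad <- is.infinite(values)
  if (any(bad)) values[bad] <- NA_real_
  dimnames(values) <- list(row_ids, feature_names)
  structure(list(values = values, row_ids = as.character(row_ids),
                 feature_names = as.character(feature_names),
                 labels = labels),
            class = "adspeech_fm")
}

#' @export
print.adspeech_fm <- function(x, ...) {
  cat(sprintf("<adspeech_fm> %d recordings x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' UTF-8 CSV with an `id` column first, an optional `label` column second,
#' then one column per feature. Values are serialized with 15 significant
#' digits, so the round-trip is lossless well past 12 significant digits;
#' missing cells are empty.
#'
#' @param m An `adspeech_fm`.
#' @param path Output / input CSV path.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(id = m$row_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(m$labels)) df$label <- as.character(m$labels)
  vals <- as.data.frame(m$values, check.names = FALSE)
  vals[] <- lapply(vals, function(col) {
    out <- sprintf("%.15g", col)
    out[is.na(col)] <- ""
    out
  })
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix()`: an `adspeech_fm`.
#' @export
read_feature_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- gsub("^\"|\"$", "", header)
  if (anyDuplicated(header))
    stop("duplicate feature names in CSV: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!identical(names(df)[1], "id")) stop("first CSV column must be 'id'")
  labels <- NULL
  first_feat <- 2L
  if (length(names(df)) >= 2 && identical(names(df)[2], "label")) {
    labels <- df$label
    first_feat <- 3L
  }
  feats <- names(df)[seq(first_feat, length.out = ncol(df) - first_feat + 1L)]
  vals <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(vals) <- "double"
  feature_matrix(vals, df$id, feats, labels)
}

# labels as 0/1 with "positive"/"impaired"/"1" as the positive class
binary_labels <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(tolower(as.character(labels)) %in%
               c("positive", "impaired", "ad", "1", "true"))
}
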