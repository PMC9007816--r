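#' Read a tabular expression dataset from CSV or ARFF
#'
#' CSV files are expected comma-separated with a header row and the class
#' as the last column (conventionally named `class`). ARFF files must
#' declare one nominal class attribute (the attribute named `class`, or
#' failing that the last nominal attribute). Feature cells must be
#' numeric; rows containing missing values are rejected with their row
#' numbers named in the error.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"arff"`, or `"auto"` (from the file
#'   extension).
#' @return A list with `x` (numeric matrix, feature names preserved),
#'   `y` (0-based integer labels), and `classes` (original label levels).
#' @export
read_dataset <- function(path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2) stop("need at least one feature column plus a class column")
    class_col <- if ("class" %in% names(df)) "class" else names(df)[ncol(df)]
  } else {
    df <- foreign::read.arff(path)
    nominal <- names(df)[vapply(df, is.factor, TRUE)]
    class_col <- if ("class" %in% names(df)) "class"
                 else if (length(nominal)) nominal[length(nominal)]
                 else stop("ARFF file declares no nominal class attribute")
  }
  y <- as.factor(df[[class_col]])
  feat <- df[names(df) != class_col]
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop(sprintf("%d row(s) with missing values rejected (rows %s)",
                 length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  non_num <- names(feat)[!vapply(feat, is.numeric, TRUE)]
  if (length(non_num))
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  list(x = as.matrix(feat), y = as.integer(y) - 1L, classes = levels(y))
}

#' Write a dataset to CSV or ARFF
#'
#' The inverse of [read_dataset()]: features first, class as the last
#' column named `class` (nominal in ARFF). Round-trips losslessly up to
#' numeric print precision.
#'
#' @param data A `"synth_dataset"`, or any list with `x` (matrix) and `y`
#'   (labels).
#' @param path Output path.
#' @param format `"csv"`, `"arff"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  df <- as.data.frame(data$x)
  df$class <- factor(data$y)
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
  else foreign::write.arff(df, path)
  invisible(path)
}
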