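# Dataset and model I/O.
#
# Dataset CSV schema: name,smiles,state,minus_dcH with minus_dcH the
# positive magnitude of the standard combustion enthalpy in kJ/mol.
# Feature-table CSV schema:
# name,smiles,estrada,wiener,gutman,degree,betweenness,closeness,eigenvector

.DATASET_COLUMNS <- c("name", "smiles", "state", "minus_dcH")
.STATES <- c("solid", "liquid", "gas", "unknown")

#' Read a compound dataset CSV
#'
#' Validates each row: the SMILES must parse, the state must be one of
#' solid/liquid/gas/unknown (missing treated as unknown), and
#' \code{minus_dcH}, when present, must be positive.  In lenient mode
#' invalid rows are dropped and reported via warnings with their line
#' numbers; \code{strict = TRUE} aborts on the first invalid row.
#'
#' @param path CSV file with header columns
#'   \code{name,smiles,state,minus_dcH}
#' @param strict abort on the first invalid row instead of skipping
#' @return data.frame of validated records; rejected row numbers are kept
#'   in attribute \code{rejected}.
#' @export
read_dataset <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("name", "smiles"), names(df))
  if (length(missing) > 0L)
    stop(sprintf("dataset schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!"state" %in% names(df)) df$state <- "unknown"
  if (!"minus_dcH" %in% names(df)) df$minus_dcH <- NA_real_
  df$state[is.na(df$state) | !nzchar(df$state)] <- "unknown"
  keep <- logical(nrow(df))
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    row_err <- NULL
    if (!df$state[i] %in% .STATES)
      row_err <- sprintf("row %d: invalid state '%s'", i, df$state[i])
    else if (!is.na(df$minus_dcH[i]) && df$minus_dcH[i] <= 0)
      row_err <- sprintf("row %d: minus_dcH must be positive (got %g)",
                         i, df$minus_dcH[i])
    else {
      ok <- tryCatch({ parse_smiles(df$smiles[i]); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) row_err <- sprintf("row %d: %s", i, ok)
    }
    if (is.null(row_err)) keep[i] <- TRUE
    else {
      if (strict) stop(row_err, call. = FALSE)
      problems <- c(problems, row_err)
    }
  }
  if (length(problems) > 0L)
    warning(sprintf("rejected %d row(s):\n%s", length(problems),
                    paste(problems, collapse = "\n")), call. = FALSE)
  out <- df[keep, .DATASET_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(!keep)
  out
}

#' Write / read a feature-table CSV
#'
#' @param df a descriptor table from [descriptor_table()]
#' @param path CSV path
#' @return \code{write_feature_table()} returns \code{path} invisibly;
#'   \code{read_feature_table()} returns the data.frame.
#' @export
write_feature_table <- function(df, path) {
  cols <- c("name", "smiles", .FEATURE_ORDER)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), cols)
  utils::write.csv(df[, c(cols, extra), drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("name", "smiles", .FEATURE_ORDER), names(df))
  if (length(missing) > 0L)
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

.serialize_node <- function(node) {
  if (isTRUE(node$leaf))
    list(leaf = TRUE, value = node$value, n = node$n)
  else
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         n = node$n, decrease = node$decrease,
         left = .serialize_node(node$left),
         right = .serialize_node(node$right))
}

.deserialize_node <- function(rec) {
  if (isTRUE(rec$leaf))
    list(leaf = TRUE, value = rec$value, n = rec$n)
  else
    list(leaf = FALSE, feature = rec$feature, threshold = rec$threshold,
         n = rec$n, decrease = rec$decrease,
         left = .deserialize_node(rec$left),
         right = .deserialize_node(rec$right))
}

#' Serialize a fitted model to JSON
#'
#' Linear models store named coefficients and the intercept; trees and
#' forests store nested node records, so fits are inspectable and
#' portable.
#'
#' @param model a \code{qspr_linear}, \code{qspr_tree} or
#'   \code{qspr_forest}
#' @param path optional file to write; if NULL the JSON string is
#'   returned
#' @return JSON string (invisibly when \code{path} is given).
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- if (inherits(model, "qspr_linear")) {
    list(type = "linear", kind = model$kind,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept)
  } else if (inherits(model, "qspr_tree")) {
    list(type = "tree", features = model$features,
         y_range = model$y_range, root = .serialize_node(model$root))
  } else if (inherits(model, "qspr_forest")) {
    list(type = "forest", kind = model$kind, features = model$features,
         config = model$config, y_range = model$y_range,
         trees = lapply(model$trees, .serialize_node))
  } else stop("unsupported model class", call. = FALSE)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()]
#' @export
model_from_json <- function(json) {
  src <- if (file.exists(json)) paste(readLines(json, warn = FALSE),
                                      collapse = "") else json
  obj <- jsonlite::fromJSON(src, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  switch(obj$type,
    linear = new_qspr_linear(unlist(obj$coefficients), obj$intercept,
                             obj$kind),
    tree = structure(list(root = .deserialize_node(obj$root),
                          features = unlist(obj$features),
                          y_range = unlist(obj$y_range)),
                     class = "qspr_tree"),
    forest = structure(list(trees = lapply(obj$trees, .deserialize_node),
                            features = unlist(obj$features),
                            kind = obj$kind, config = obj$config,
                            oob = NULL, y_range = unlist(obj$y_range)),
                       class = "qspr_forest"),
    stop("unknown model type in JSON", call. = FALSE))
}
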