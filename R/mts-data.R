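#' Construct a multivariate time series item
#'
#' An MTS item is an `m x n` real matrix: `m` time points (rows) observed on
#' `n` simultaneous channels (columns), e.g. one EEG recording across
#' electrodes, plus an identifier and an optional class label.
#'
#' @param values Numeric matrix with `m >= 2` rows and `n >= 1` columns; no
#'   missing values.
#' @param id Character scalar identifier.
#' @param label Optional class label (character scalar) for classification.
#' @return An object of class `mts_item` with elements `id`, `values`, `label`.
#' @examples
#' x <- mts_item(matrix(rnorm(30), 10, 3), id = "a", label = "healthy")
#' dim(x$values)
#' @export
mts_item <- function(values, id, label = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("'id' must be a non-empty character scalar")
  if (nrow(values) < 2L)
    stop(sprintf("item '%s': needs at least 2 time points, got %d", id, nrow(values)))
  if (ncol(values) < 1L)
    stop(sprintf("item '%s': needs at least 1 variable", id))
  if (anyNA(values) || any(!is.finite(values)))
    stop(sprintf("item '%s': missing or non-finite values are not allowed", id))
  if (!is.null(label)) label <- as.character(label)
  structure(list(id = id, values = values, label = label), class = "mts_item")
}

#' @export
print.mts_item <- function(x, ...) {
  cat(sprintf("<mts_item '%s'> %d time points x %d variables%s\n",
              x$id, nrow(x$values), ncol(x$values),
              if (is.null(x$label)) "" else paste0(", label '", x$label, "'")))
  invisible(x)
}

#' Construct a labelled MTS collection
#'
#' @param items List of [mts_item()] objects sharing the same number of
#'   variables `n`; ids must be unique. Item lengths `m` may differ.
#' @return An object of class `mts_dataset`: list with `items` (named by id),
#'   `n`, and `class_labels` (sorted unique labels present).
#' @examples
#' d <- mts_dataset(list(
#'   mts_item(matrix(rnorm(20), 10, 2), "a", "x"),
#'   mts_item(matrix(rnorm(20), 10, 2), "b", "y")))
#' d$class_labels
#' @export
mts_dataset <- function(items) {
  if (!length(items)) stop("a dataset needs at least one item")
  if (!all(vapply(items, inherits, logical(1), "mts_item")))
    stop("all elements of 'items' must be mts_item objects")
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate item ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- vapply(items, function(x) ncol(x$values), integer(1))
  if (length(unique(n)) != 1L)
    stop("all items must share the same number of variables; found n = ",
         paste(sort(unique(n)), collapse = ", "))
  names(items) <- ids
  labs <- unlist(lapply(items, `[[`, "label"))
  structure(list(items = items, n = n[[1L]],
                 class_labels = sort(unique(labs))),
            class = "mts_dataset")
}

#' @export
print.mts_dataset <- function(x, ...) {
  cat(sprintf("<mts_dataset> %d items, n = %d variables, %d class labels\n",
              length(x$items), x$n, length(x$class_labels)))
  invisible(x)
}

#' @export
length.mts_dataset <- function(x) length(x$items)

#' Item labels of a dataset
#' @param dataset An `mts_dataset`.
#' @return Named character vector (NA for unlabelled items).
#' @export
item_labels <- function(dataset) {
  vapply(dataset$items, function(it) {
    if (is.null(it$label)) NA_character_ else it$label
  }, character(1))
}

#' Construct a long multivariate series for subsequence matching
#'
#' @param values Numeric `M x n` matrix, `M` typically much larger than the
#'   query length.
#' @param id Character scalar identifier.
#' @return An object of class `long_series`.
#' @export
long_series <- function(values, id = "long") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop(sprintf("series '%s': missing or non-finite values are not allowed", id))
  if (nrow(values) < 2L) stop("a long series needs at least 2 time points")
  structure(list(id = id, values = values), class = "long_series")
}

#' @export
print.long_series <- function(x, ...) {
  cat(sprintf("<long_series '%s'> %d time points x %d variables\n",
              x$id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a labelled MTS dataset from CSV files
#'
#' Two on-disk layouts are supported. `per-item`: a directory holding one CSV
#' per item (`<id>.csv`, header row, columns = variables, rows = time points)
#' plus a `labels.csv` manifest with columns `id,label`. `long`: a single CSV
#' in long format with columns `item`, `t`, then one column per variable; rows
#' are sorted by `t` within item on read, and labels come from an optional
#' sibling `labels.csv` or a `label` column.
#'
#' @param path Directory (layout `per-item`) or CSV file (layout `long`).
#' @param layout One of `"per-item"`, `"long"`.
#' @return An [mts_dataset()].
#' @export
read_mts_dataset <- function(path, layout = c("per-item", "long")) {
  layout <- match.arg(layout)
  if (layout == "per-item") {
    if (!dir.exists(path)) stop("directory not found: ", path)
    manifest <- file.path(path, "labels.csv")
    labs <- NULL
    if (file.exists(manifest)) {
      labs <- utils::read.csv(manifest, colClasses = "character")
      if (!all(c("id", "label") %in% names(labs)))
        stop("labels.csv must have columns 'id' and 'label'")
    }
    files <- sort(setdiff(list.files(path, pattern = "\\.csv$"), "labels.csv"))
    if (!length(files)) stop("no item CSV files found under ", path)
    items <- lapply(files, function(f) {
      id <- sub("\\.csv$", "", f)
      df <- utils::read.csv(file.path(path, f))
      vals <- as.matrix(df)
      if (anyNA(vals))
        stop(sprintf("item '%s': missing value at row %d", id,
                     which(rowSums(is.na(vals)) > 0)[1L]))
      label <- if (!is.null(labs) && id %in% labs$id) labs$label[match(id, labs$id)]
      mts_item(vals, id = id, label = label)
    })
    return(mts_dataset(items))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("item", "t") %in% names(df)))
    stop("long-format table must have columns 'item' and 't'")
  has_label <- "label" %in% names(df)
  vcols <- setdiff(names(df), c("item", "t", "label"))
  if (!length(vcols)) stop("long-format table has no variable columns")
  items <- lapply(split(df, df$item), function(g) {
    g <- g[order(g$t), , drop = FALSE]
    vals <- as.matrix(g[, vcols, drop = FALSE])
    id <- as.character(g$item[[1L]])
    if (anyNA(vals))
      stop(sprintf("item '%s': missing value in long-format table", id))
    label <- if (has_label) as.character(g$label[[1L]])
    mts_item(vals, id = id, label = label)
  })
  mts_dataset(items[order(names(items))])
}

#' Write a labelled MTS dataset to CSV files
#'
#' Inverse of [read_mts_dataset()]: values survive a write/read round trip
#' bit-exactly for finite decimal inputs (`.` decimal separator, full
#' precision, header row).
#'
#' @param dataset An [mts_dataset()].
#' @param path Target directory (`per-item`) or CSV file (`long`).
#' @param layout One of `"per-item"`, `"long"`.
#' @return Invisibly, `path`.
#' @export
write_mts_dataset <- function(dataset, path, layout = c("per-item", "long")) {
  layout <- match.arg(layout)
  if (!inherits(dataset, "mts_dataset")) stop("'dataset' must be an mts_dataset")
  vnames <- function(n) paste0("v", seq_len(n))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  fmt <- function(v) as.data.frame(lapply(as.data.frame(v), sprintf,
                                          fmt = "%.17g"))
  if (layout == "per-item") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (it in dataset$items) {
      df <- fmt(it$values)
      names(df) <- vnames(ncol(it$values))
      utils::write.csv(df, file.path(path, paste0(it$id, ".csv")), row.names = FALSE)
    }
    labs <- item_labels(dataset)
    if (!all(is.na(labs)))
      utils::write.csv(data.frame(id = names(labs), label = unname(labs)),
                       file.path(path, "labels.csv"), row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(dataset$items, function(it) {
    df <- fmt(it$values)
    names(df) <- vnames(ncol(it$values))
    out <- cbind(data.frame(item = it$id, t = seq_len(nrow(it$values))), df)
    if (!is.null(it$label)) out$label <- it$label
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Validate an MTS dataset, reporting issues instead of raising
#'
#' Checks the container invariants: every item has `m >= 2` rows, at least one
#' variable, no missing/non-finite values, consistent arity across items, and
#' unique ids. Pure: never raises, never modifies.
#'
#' @param dataset An `mts_dataset`, or a bare list of `mts_item`-like lists
#'   (so that invalid collections can be inspected).
#' @return Character vector of human-readable issues; empty when valid.
#' @export
validate_dataset <- function(dataset) {
  items <- if (inherits(dataset, "mts_dataset")) dataset$items else dataset
  issues <- character(0)
  if (!length(items)) return("dataset contains no items")
  ids <- vapply(items, function(it) {
    if (is.character(it$id) && length(it$id) == 1L) it$id else "<missing id>"
  }, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    issues <- c(issues, paste0("duplicate id: ", dup))
  ns <- integer(0)
  for (k in seq_along(items)) {
    it <- items[[k]]
    v <- it$values
    if (!is.matrix(v)) {
      issues <- c(issues, sprintf("item '%s': values are not a matrix", ids[[k]]))
      next
    }
    if (nrow(v) < 2L)
      issues <- c(issues, sprintf("item '%s': too short (m = %d < 2)", ids[[k]], nrow(v)))
    if (ncol(v) < 1L)
      issues <- c(issues, sprintf("item '%s': no variables", ids[[k]]))
    if (anyNA(v) || any(!is.finite(v)))
      issues <- c(issues, sprintf("item '%s': missing or non-finite values", ids[[k]]))
    ns <- c(ns, ncol(v))
  }
  if (length(unique(ns)) > 1L)
    issues <- c(issues, paste0("arity mismatch: items have n in {",
                               paste(sort(unique(ns)), collapse = ", "), "}"))
  issues
}
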