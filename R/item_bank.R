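#' Construct an item bank
#'
#' An item bank is the set of calibrated polytomous item difficulties a
#' partial credit model needs: for each item an overall difficulty
#' (logits) and an ordered set of step thresholds (centered deviations,
#' logits). The effective category threshold for step k of item i is
#' `overall_difficulty[i] + step_k`. A dichotomous item carries a single
#' step.
#'
#' @param items data frame with columns `item_id`, `text`,
#'   `overall_difficulty`, and `step1`..`step4` (NA for absent steps).
#' @param name short label for the bank.
#' @param metadata named list of free-form provenance fields.
#' @param validate run structural validation (default TRUE).
#' @return an object of class `item_bank`.
#' @export
item_bank <- function(items, name = "item_bank", metadata = list(),
                      validate = TRUE) {
  stopifnot(is.data.frame(items))
  required <- c("item_id", "text", "overall_difficulty")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("item bank is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  step_cols <- grep("^step[0-9]+$", names(items), value = TRUE)
  if (length(step_cols) == 0L) {
    stop("item bank needs at least one step column (step1..step4)",
         call. = FALSE)
  }
  items <- items[order(items$item_id), , drop = FALSE]
  rownames(items) <- NULL
  bank <- structure(
    list(items = items, name = name, metadata = metadata),
    class = "item_bank"
  )
  if (validate) validate_item_bank(bank)
  bank
}

#' Validate an item bank
#'
#' Checks the structural invariants: unique contiguous item ids, at
#' least one step per item, no gaps in the step sequence, and finite
#' difficulties. Step centering (polytomous steps summing to zero) is
#' checked softly: the published calibration contains items whose
#' printed steps do not sum exactly to zero, so departures raise a
#' warning, not an error.
#'
#' @param bank an `item_bank`.
#' @param centering_tol tolerance (logits) for the step-centering check.
#' @return the bank, invisibly.
#' @export
validate_item_bank <- function(bank, centering_tol = 0.05) {
  items <- bank$items
  ids <- items$item_id
  if (anyDuplicated(ids)) {
    stop("duplicate item_id in bank: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(ids), seq_len(nrow(items)))) {
    stop("item_ids must be contiguous 1..N", call. = FALSE)
  }
  off_center <- integer(0)
  for (i in seq_len(nrow(items))) {
    steps <- item_steps(bank, i)
    if (length(steps) == 0L) {
      stop("item ", ids[i], " has no step thresholds", call. = FALSE)
    }
    if (anyNA(steps) || !all(is.finite(steps)) ||
        !is.finite(items$overall_difficulty[i])) {
      stop("item ", ids[i], " has non-finite difficulties", call. = FALSE)
    }
    if (length(steps) >= 2L && abs(sum(steps)) > centering_tol) {
      off_center <- c(off_center, ids[i])
    }
  }
  if (length(off_center) > 0L) {
    warning("step thresholds not centered (|sum| > ", centering_tol,
            " logits) for item(s): ", paste(off_center, collapse = ", "),
            call. = FALSE)
  }
  invisible(bank)
}

#' @export
print.item_bank <- function(x, ...) {
  k <- vapply(seq_len(n_items(x)), function(i) length(item_steps(x, i)),
              integer(1))
  cat("Item bank '", x$name, "': ", n_items(x), " items (",
      sum(k == 1L), " dichotomous, ", sum(k > 1L), " polytomous)\n",
      sep = "")
  cat("Overall difficulty range: [",
      sprintf("%.2f", min(x$items$overall_difficulty)), ", ",
      sprintf("%.2f", max(x$items$overall_difficulty)), "] logits\n",
      sep = "")
  invisible(x)
}

#' Number of items in a bank
#' @param bank an `item_bank`.
#' @return integer count.
#' @export
n_items <- function(bank) nrow(bank$items)

#' Step thresholds of one item
#'
#' @param bank an `item_bank`.
#' @param item_id integer item id.
#' @return numeric vector of the item's step thresholds (logits),
#'   absent steps dropped.
#' @export
item_steps <- function(bank, item_id) {
  row <- bank$items[bank$items$item_id == item_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("no item with id ", item_id, call. = FALSE)
  step_cols <- grep("^step[0-9]+$", names(bank$items), value = TRUE)
  steps <- as.numeric(row[1, step_cols])
  steps <- steps[!is.na(steps)]
  steps
}

#' One item's parameter set
#'
#' @param bank an `item_bank`.
#' @param item_id integer item id.
#' @return list with `item_id`, `text`, `overall_difficulty`, `steps`
#'   (centered deviations), `thresholds` (effective category thresholds
#'   `overall + step`), and `n_categories` (= steps + 1; categories are
#'   scored `0..K`).
#' @export
item_params <- function(bank, item_id) {
  row <- bank$items[bank$items$item_id == item_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("no item with id ", item_id, call. = FALSE)
  steps <- item_steps(bank, item_id)
  list(
    item_id = row$item_id[1],
    text = row$text[1],
    overall_difficulty = row$overall_difficulty[1],
    steps = steps,
    thresholds = row$overall_difficulty[1] + steps,
    n_categories = length(steps) + 1L
  )
}

#' Load an item bank from disk
#'
#' @param path file path.
#' @param format `"csv"` (header row, NA for absent steps) or `"json"`
#'   (array of item objects). Inferred from the file extension when
#'   omitted.
#' @param name,metadata passed to [item_bank()].
#' @return an `item_bank`.
#' @export
load_item_bank <- function(path, format = c("auto", "csv", "json"),
                           name = NULL, metadata = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (is.null(name)) name <- sub("\\.(csv|json)$", "", basename(path))
  if (format == "csv") {
    items <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    items <- do.call(rbind, lapply(recs, function(r) {
      steps <- as.numeric(unlist(r$steps))
      steps <- c(steps, rep(NA_real_, 4L - length(steps)))
      data.frame(item_id = as.integer(r$item_id), text = r$text,
                 overall_difficulty = as.numeric(r$overall_difficulty),
                 step1 = steps[1], step2 = steps[2], step3 = steps[3],
                 step4 = steps[4], stringsAsFactors = FALSE)
    }))
  }
  required <- c("item_id", "text", "overall_difficulty")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  item_bank(items, name = name, metadata = metadata)
}

#' Write an item bank to disk
#'
#' The CSV dialect is UTF-8 with a header row and `NA` marking absent
#' steps; the JSON dialect is an array of objects with `steps` as a
#' variable-length array. Both round-trip through [load_item_bank()]
#' to an equal bank.
#'
#' @param bank an `item_bank`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; inferred from extension when omitted.
#' @return the path, invisibly.
#' @export
write_item_bank <- function(bank, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(bank$items, path, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  } else {
    recs <- lapply(seq_len(n_items(bank)), function(i) {
      p <- item_params(bank, bank$items$item_id[i])
      list(item_id = p$item_id, text = p$text,
           overall_difficulty = p$overall_difficulty, steps = p$steps)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' The packaged 30-item skin-cancer risk bank
#'
#' Loads the calibrated 30-item difficulty bank shipped with the
#' package: overall difficulties and up to four step thresholds per
#' item, in logits, for the unidimensional skin-cancer risk scale
#' (pigmentation traits, sun exposure, sunburn history, sunscreen
#' habits, personal cancer history). Items 1, 12 and 25-28 are
#' dichotomous; the rest have 3-5 ordered categories.
#'
#' @return an `item_bank` with 30 items.
#' @export
skin_item_bank <- function() {
  path <- system.file("extdata", "skin_item_bank.csv", package = "sccat",
                      mustWork = TRUE)
  suppressWarnings(
    load_item_bank(path, format = "csv", name = "skin_item_bank",
                   metadata = list(units = "logits",
                                   scale = "skin-cancer risk"))
  )
}
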