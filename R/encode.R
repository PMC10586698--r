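#' Encode a mixed-type pre-transplant table
#'
#' Numeric and binary attributes pass through unchanged; every categorical
#' attribute with k levels is replaced by k-1 binary indicator columns
#' (standard dummy coding), the designated baseline level mapping to the
#' all-zero indicator row.  For example a 6-level "cancer type" attribute
#' with baseline "Other" contributes 5 indicator columns, and a patient of
#' the "Other" class scores 0 on every one of them.
#'
#' @param raw A data.frame, one row per patient, with numeric, logical/0-1
#'   and character/factor columns; patient ids in `rownames(raw)` or in an
#'   `patient_id` column.
#' @param levels_map Named list: for each categorical column, a character
#'   vector of its known levels, the first being the baseline.  Categorical
#'   columns absent from the map get levels from the data (sorted, first =
#'   baseline).
#' @return An object of class `pretransplant_table` with fields
#'   `patient_ids`, `raw_attributes`, `encoded` (a `d x N_p` numeric matrix,
#'   variables in rows), `attribute_names` and the `levels_map` used (so a
#'   prospective patient can be encoded identically).
#' @export
encode_pretransplant <- function(raw, levels_map = list()) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if ("patient_id" %in% names(raw)) {
    ids <- as.character(raw$patient_id)
    raw <- raw[, setdiff(names(raw), "patient_id"), drop = FALSE]
  } else {
    ids <- rownames(raw)
    if (is.null(ids)) ids <- paste0("P", seq_len(nrow(raw)))
  }
  cols <- list()
  used_map <- list()
  for (nm in names(raw)) {
    x <- raw[[nm]]
    if (is.factor(x)) x <- as.character(x)
    if (is.numeric(x) || is.logical(x)) {
      v <- as.numeric(x)
      if (any(is.na(v))) stop("missing values in attribute '", nm, "'")
      cols[[nm]] <- v
    } else if (is.character(x)) {
      lv <- levels_map[[nm]]
      if (is.null(lv)) lv <- sort(unique(x))
      unseen <- setdiff(unique(x), lv)
      if (length(unseen) > 0)
        stop("unseen level(s) ", paste(sQuote(unseen), collapse = ", "),
             " in attribute '", nm, "'; known levels: ",
             paste(lv, collapse = ", "))
      used_map[[nm]] <- lv
      for (lev in lv[-1L]) {
        cols[[paste0(nm, ":", lev)]] <- as.numeric(x == lev)
      }
    } else {
      stop("unsupported attribute type in column '", nm, "'")
    }
  }
  enc <- do.call(rbind, cols)   # d x N_p, variables in rows
  colnames(enc) <- ids
  if (any(!is.finite(enc))) stop("encoded table contains missing entries")
  structure(list(patient_ids = ids, raw_attributes = raw, encoded = enc,
                 attribute_names = rownames(enc), levels_map = used_map),
            class = "pretransplant_table")
}

#' @export
print.pretransplant_table <- function(x, ...) {
  cat("<pretransplant_table> ", length(x$patient_ids), " patients, ",
      nrow(x$encoded), " encoded attributes\n", sep = "")
  invisible(x)
}

#' Encode a prospective patient with a fitted encoder
#'
#' Applies the same dummy coding (including level maps) that produced a
#' training [encode_pretransplant()] table to a single new patient.  An
#' unseen categorical level is a hard error listing the known levels.
#'
#' @param table A `pretransplant_table` fitted on the training cohort.
#' @param raw_row One-row data.frame with the same raw attribute columns.
#' @return Numeric vector of length `d`, named as `table$attribute_names`.
#' @export
encode_new_patient <- function(table, raw_row) {
  raw_row <- as.data.frame(raw_row, stringsAsFactors = FALSE)
  raw_row <- raw_row[, setdiff(names(raw_row), "patient_id"), drop = FALSE]
  if (!identical(sort(names(raw_row)), sort(names(table$raw_attributes))))
    stop("prospective patient attributes do not match the training table")
  tmp <- encode_pretransplant(
    rbind(table$raw_attributes[1, , drop = FALSE], raw_row),
    levels_map = table$levels_map)
  y <- tmp$encoded[, 2L]
  if (!identical(rownames(tmp$encoded), table$attribute_names))
    stop("encoding of prospective patient produced mismatched attributes")
  names(y) <- table$attribute_names
  y
}

#' Read / write a pre-transplant table as delimited text
#'
#' The raw (un-encoded) table is stored as CSV with a `patient_id` column;
#' finite doubles round-trip exactly via 17 significant digits.
#'
#' @param raw Data.frame as accepted by [encode_pretransplant()].
#' @param path File path.
#' @export
write_pretransplant <- function(raw, path) {
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_pretransplant
#' @export
read_pretransplant <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
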