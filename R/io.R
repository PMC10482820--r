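# CSV interchange ------------------------------------------------------------
#
# Single data interchange format: UTF-8 CSV with '.' decimal and a header.
# Dataset schema: participant_id, x_ss, t_ss, x_ll, t_ll, choice, time_unit,
# subset (subset may be empty). choice: 1 = larger-later chosen.

#' Read / write a choice dataset CSV
#'
#' `read_choice_dataset()` validates the schema and every row against the
#' item invariants and the 0/1 choice coding, reporting offending data rows
#' by number. `write_choice_dataset()` writes a CSV that reads back
#' identically; when the dataset carries a generating-truth attribute it can
#' also emit the truth sidecar.
#'
#' @param path CSV file path.
#' @return An `itc_dataset`.
#' @export
read_choice_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "x_ss", "t_ss", "x_ll", "t_ll", "choice",
                "time_unit")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input("dataset schema mismatch: missing column(s) ",
               paste(missing, collapse = ", "))
  }
  if (is.null(df$subset)) df$subset <- NA_character_
  df$subset[!is.na(df$subset) & df$subset == ""] <- NA_character_
  if (!all(df$choice %in% c(0L, 1L))) {
    bad <- which(!df$choice %in% c(0L, 1L))
    stop_input("invalid choice code at data row(s) ",
               paste(head(bad, 5L), collapse = ", "),
               " (must be 0 or 1, 1 = larger-later chosen)")
  }
  report <- validate_items(df)
  if (!all(report$pass)) {
    bad <- report[!report$pass, , drop = FALSE]
    stop_input("invalid item at data row(s) ",
               paste(head(unique(bad$row), 5L), collapse = ", "), ": ",
               paste(unique(bad$check), collapse = "; "))
  }
  units <- unique(df$time_unit)
  if (!all(units %in% c("days", "months"))) {
    stop_input("time_unit must be 'days' or 'months'")
  }
  df$participant_id <- as.character(df$participant_id)
  df$choice <- as.integer(df$choice)
  df <- df[, c(required, "subset")]
  class(df) <- c("itc_dataset", "data.frame")
  df
}

#' @rdname read_choice_dataset
#' @param dataset An `itc_dataset`.
#' @param truth_path Optional path for the generating-truth sidecar CSV
#'   (written only when the dataset has a `truth` attribute).
#' @export
write_choice_dataset <- function(dataset, path, truth_path = NULL) {
  cols <- c("participant_id", "x_ss", "t_ss", "x_ll", "t_ll", "choice",
            "time_unit", "subset")
  write.csv(as.data.frame(dataset)[, cols], path, row.names = FALSE,
            quote = FALSE, na = "")
  truth <- attr(dataset, "truth")
  if (!is.null(truth_path)) {
    if (is.null(truth)) stop_input("dataset carries no truth attribute")
    write_truth(truth, truth_path)
  }
  invisible(path)
}

#' Read / write a generating-truth sidecar CSV
#'
#' Long format keyed by participant and parameter name, with natural-scale
#' values and the model id in every row.
#'
#' @param truth An `itc_truth` table.
#' @param path CSV file path.
#' @export
write_truth <- function(truth, path) {
  model_id <- attr(truth, "model_id")
  pn <- model_spec(model_id)$params
  long <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    data.frame(participant_id = truth$participant_id[i], model_id = model_id,
               parameter = pn, value = as.numeric(truth[i, pn]),
               row.names = NULL)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  model_id <- unique(long$model_id)
  if (length(model_id) != 1L) stop_input("truth sidecar must hold one model")
  pn <- model_spec(model_id)$params
  pids <- unique(long$participant_id)
  wide <- do.call(rbind, lapply(pids, function(pid) {
    sub <- long[long$participant_id == pid, ]
    setNames(sub$value[match(pn, sub$parameter)], pn)
  }))
  out <- data.frame(participant_id = pids, wide, stringsAsFactors = FALSE)
  attr(out, "model_id") <- model_id
  class(out) <- c("itc_truth", "data.frame")
  out
}
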