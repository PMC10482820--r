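#' Construct a choice dataset
#'
#' Long-format container for binary inter-temporal choices: one row per
#' participant x item, holding the item attributes, the response
#' (`choice` = 1 if the larger-later option was chosen, 0 otherwise), the
#' design's native time unit, and an optional subset label.
#'
#' @param participant_id Participant identifier(s), recycled across items.
#' @param items An [choice_items()] data frame (its `subset` column and time
#'   unit are carried over).
#' @param choice Integer vector of 0/1 responses, one per row of `items`.
#' @return A `data.frame` of class `"itc_dataset"` with columns
#'   `participant_id`, `x_ss`, `t_ss`, `x_ll`, `t_ll`, `choice`, `time_unit`,
#'   `subset`.
#' @export
choice_dataset <- function(participant_id, items, choice) {
  n <- nrow(items)
  choice <- as.integer(choice)
  if (length(choice) != n) {
    stop_input("`choice` must have one response per item row")
  }
  if (!all(choice %in% c(0L, 1L))) {
    stop_input("choice codes must be 0 or 1 (1 = larger-later chosen)")
  }
  out <- data.frame(
    participant_id = rep_len(as.character(participant_id), n),
    x_ss = items$x_ss, t_ss = items$t_ss,
    x_ll = items$x_ll, t_ll = items$t_ll,
    choice = choice,
    time_unit = item_time_unit(items),
    subset = if (!is.null(items$subset)) as.character(items$subset)
             else NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("itc_dataset", "data.frame")
  out
}

# Bind per-participant datasets, keeping the class.
bind_datasets <- function(dsets) {
  out <- do.call(rbind, lapply(dsets, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("itc_dataset", "data.frame")
  out
}

dataset_items <- function(dataset) {
  items <- data.frame(
    x_ss = dataset$x_ss, t_ss = dataset$t_ss,
    x_ll = dataset$x_ll, t_ll = dataset$t_ll,
    subset = if (!is.null(dataset$subset)) dataset$subset else NA_character_,
    stringsAsFactors = FALSE
  )
  attr(items, "time_unit") <- unique(dataset$time_unit)[1L]
  class(items) <- c("itc_items", "data.frame")
  items
}

#' @export
print.itc_dataset <- function(x, ...) {
  cat(sprintf("<itc_dataset> %d rows, %d participant(s), delays in %s\n",
              nrow(x), length(unique(x$participant_id)),
              paste(unique(x$time_unit), collapse = "/")))
  print(as.data.frame(head(x, 6L)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
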