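# Trial-table I/O.
#
# The canonical dialect is tab-delimited with a mandatory header:
# subject_id, experiment_id, trial_index, condition, target_deg,
# nontarget1_deg[, nontarget2_deg], response_deg. External deposits with
# different column names are read through a configurable mapping, never a
# hard-coded schema.

trial_cols <- function(set_size) {
  c("subject_id", "experiment_id", "trial_index", "condition", "target_deg",
    paste0("nontarget", seq_len(set_size - 1), "_deg"), "response_deg")
}

#' Write a trial table
#'
#' @param trials Trial table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  nt <- grep("^nontarget[0-9]+_deg$", names(trials), value = TRUE)
  cols <- trial_cols(length(nt) + 1)
  utils::write.table(trials[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a trial table, optionally through a column mapping
#'
#' @param path Input file path (delimited text with header).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(target_deg = "orientation", response_deg = "report")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param sep Field separator (default tab; `","` for CSV deposits).
#' @return A trial table in the canonical dialect.
#' @export
read_trials <- function(path, col_map = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' (for '", canon, "') not in file")
      }
      raw[[canon]] <- raw[[src]]
      if (src != canon) raw[[src]] <- NULL
    }
  }
  nt <- grep("^nontarget[0-9]+_deg$", names(raw), value = TRUE)
  need <- trial_cols(length(nt) + 1)
  missing <- setdiff(need, names(raw))
  if (length(nt) == 0 || length(missing) > 0) {
    stop("trial table lacks required columns: ",
         paste(c(missing, if (length(nt) == 0) "nontarget1_deg"), collapse = ", "),
         " (use col_map to rename)")
  }
  raw[, need]
}
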