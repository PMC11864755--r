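#' Read and write trial tables
#'
#' Trial tables are plain CSV with one row per trial and the columns
#' produced by [generateDesign()] / [generateBehavior()]: `phase`,
#' `block`, `trial`, `cue_bin` (0-based; empty on no-memory trials),
#' `cue_angle` (degrees), `no_memory`, `distractor_present`,
#' `distractor_bin` (empty when absent), `target_bin`, `rt` (ms),
#' `correct`, `recall_deviation` (degrees), and optionally `dist_repeat`
#' and `subject`. The design configuration is not serialized; pass it to
#' downstream functions explicitly (or re-attach it).
#'
#' @param trials a TrialTable data.frame.
#' @param path file path (`.csv`).
#' @return `readTrialTable` returns the data.frame with column types
#'   restored; `writeTrialTable` returns `path` invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("cue_bin", "distractor_bin", "target_bin", "block",
                "trial", "subject"))
    if (col %in% names(tt)) tt[[col]] <- as.integer(tt[[col]])
  for (col in c("no_memory", "distractor_present", "correct",
                "dist_repeat"))
    if (col %in% names(tt)) tt[[col]] <- as.logical(tt[[col]])
  tt
}
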