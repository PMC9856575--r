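#' Read and write epoched trials in delimited long format
#'
#' The on-disk format is a plain tab-separated table with header columns
#' `subject`, `channel`, `class`, `trial`, followed by `s1 ... sN` sample
#' columns (microvolts); the sampling rate is stored in a `# fs=<Hz>`
#' comment on the first line. One file can hold many
#' (subject, channel, class) cells.
#'
#' @param x a [trial_ensemble()] or a named nested list of them (as
#'   produced by [generate_dataset()]).
#' @param file path of the TSV file.
#' @return `write_trials()` returns `file` invisibly; `read_trials()`
#'   returns a nested list `dataset[[subject]][[channel]][[class]]` of
#'   [trial_ensemble()]s (a single ensemble when the file holds one cell
#'   and `simplify = TRUE`).
#' @param simplify collapse a single-cell file to one ensemble.
#' @export
write_trials <- function(x, file) {
  rows <- list()
  add <- function(e) {
    lab <- e$labels
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = as.character(lab$subject), channel = as.character(lab$channel),
      class = as.character(lab$class), trial = seq_len(nrow(e$trials)),
      e$trials, check.names = FALSE)
  }
  fs <- NULL
  walk <- function(node) {
    if (inherits(node, "trial_ensemble")) {
      fs <<- node$fs
      add(node)
    } else if (is.list(node)) {
      lapply(node, walk)
    } else stop("expected trial_ensemble objects")
  }
  walk(x)
  tab <- do.call(rbind, rows)
  names(tab) <- c("subject", "channel", "class", "trial",
                  paste0("s", seq_len(ncol(tab) - 4L)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", fs), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file, simplify = TRUE) {
  header <- readLines(file, n = 1L)
  if (!grepl("^# fs=", header)) stop("missing '# fs=' header line")
  fs <- as.numeric(sub("^# fs=", "", header))
  tab <- utils::read.table(file, header = TRUE, sep = "\t", skip = 1L,
                           check.names = FALSE)
  sample_cols <- grep("^s[0-9]+$", names(tab))
  out <- list()
  for (subj in unique(tab$subject)) {
    ts <- tab[tab$subject == subj, ]
    out[[as.character(subj)]] <- list()
    for (ch in unique(ts$channel)) {
      tc <- ts[ts$channel == ch, ]
      cell <- list()
      for (cl in unique(tc$class)) {
        tt <- tc[tc$class == cl, ]
        tt <- tt[order(tt$trial), ]
        cell[[as.character(cl)]] <- trial_ensemble(
          as.matrix(tt[, sample_cols]), fs, subject = subj, channel = ch,
          class = cl)
      }
      out[[as.character(subj)]][[as.character(ch)]] <- cell
    }
  }
  if (simplify && length(out) == 1L && length(out[[1L]]) == 1L &&
      length(out[[1L]][[1L]]) == 1L) {
    return(out[[1L]][[1L]][[1L]])
  }
  out
}

#' Export a scalogram with band metadata
#'
#' Writes a `J x N` scalogram as a TSV whose first column is the band
#' center frequency (Hz); a companion export writes the COI table
#' (frequency, footprint, valid interval, in-COI count per band).
#'
#' @param G a `"scalogram"` matrix (or `"cwt_result"`).
#' @param coi a [coi_boundary()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_scalogram <- function(G, file) {
  if (inherits(G, "cwt_result")) G <- G$G
  freqs <- attr(G, "frequencies") %||% rep(NA_real_, nrow(G))
  tab <- data.frame(frequency_hz = freqs, unclass(G), check.names = FALSE)
  names(tab) <- c("frequency_hz", paste0("n", seq_len(ncol(G)) - 1L))
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname export_scalogram
#' @export
export_coi <- function(coi, file) {
  utils::write.table(as.data.frame(coi), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a feature matrix with its layout sidecar
#'
#' Writes one row per m-ERP (TSV, with an `approach` tag column) plus a
#' sidecar table mapping each feature column to its scalogram
#' `(band, time)` position.
#'
#' @param x `n x p` feature matrix.
#' @param layout integer layout matrix (columns `band`, `time`), e.g. from
#'   a [s_vector()]-family `"feature_vector"`.
#' @param approach approach tag (`"S"`, `"Z"`, `"V"`, `"Vbar"`).
#' @param file output path; the sidecar is written to `<file>.layout`.
#' @return `file`, invisibly.
#' @export
export_features <- function(x, layout, approach, file) {
  tab <- data.frame(approach = approach, x, check.names = FALSE)
  names(tab) <- c("approach", paste0("f", seq_len(ncol(x))))
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(layout), paste0(file, ".layout"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
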