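#' Construct a log-evidence matrix
#'
#' Wraps an N x K numeric matrix of per-subject, per-model log model
#' evidences (nats) in a validated [LogEvidenceMatrix-class]. Row and column
#' names of `values` are used as subject and model labels when `subjectIds`
#' or `modelNames` are not supplied.
#'
#' @param values numeric N x K matrix; all entries must be finite.
#' @param subjectIds optional character vector of N subject labels.
#' @param modelNames optional character vector of K model labels.
#' @return A [LogEvidenceMatrix-class].
#' @examples
#' lev <- LogEvidenceMatrix(rbind(c(3, 0), c(2.5, 0)),
#'                          modelNames = c("validity", "null"))
#' evidence(lev)
#' @export
LogEvidenceMatrix <- function(values, subjectIds = NULL, modelNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subjectIds)) {
    subjectIds <- rownames(values)
    if (is.null(subjectIds)) {
      subjectIds <- sprintf("subject%02d", seq_len(nrow(values)))
    }
  }
  if (is.null(modelNames)) {
    modelNames <- colnames(values)
    if (is.null(modelNames)) {
      modelNames <- sprintf("model%d", seq_len(ncol(values)))
    }
  }
  dimnames(values) <- NULL
  new("LogEvidenceMatrix", values = values,
      subjectIds = as.character(subjectIds),
      modelNames = as.character(modelNames))
}

#' Read or write a log-evidence matrix as delimited text
#'
#' The on-disk format is tab-separated text with a header row of model names
#' and one row per subject; the first column, `subject`, carries the subject
#' labels.
#'
#' @param path file path.
#' @param x a [LogEvidenceMatrix-class].
#' @return `readLogEvidence` returns a [LogEvidenceMatrix-class];
#'   `writeLogEvidence` returns `path` invisibly.
#' @export
readLogEvidence <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"subject" %in% names(df)) {
    stop("expected a 'subject' column in ", path, call. = FALSE)
  }
  ids <- as.character(df[["subject"]])
  df[["subject"]] <- NULL
  LogEvidenceMatrix(as.matrix(df), subjectIds = ids,
                    modelNames = names(df))
}

#' @rdname readLogEvidence
#' @export
writeLogEvidence <- function(x, path) {
  x <- asLogEvidence(x)
  df <- data.frame(subject = x@subjectIds, x@values, check.names = FALSE)
  names(df) <- c("subject", x@modelNames)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
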