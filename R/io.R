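# Dataset readers/writers and training-set hygiene.

.SEQ_ALIASES <- c("sequence", "modified_sequence", "Modified.sequence",
                  "Modified sequence", "Modified_sequence", "seq", "peptide")
.CHARGE_ALIASES <- c("charge", "Charge", "z", "charge_state")
.CCS_ALIASES <- c("ccs", "CCS", "ccs_value", "CCS_value", "ccs_a2")

.resolve_column <- function(cols, aliases) {
  hit <- which(tolower(cols) %in% tolower(aliases))
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L]
}

#' Read a peptide CCS data set from CSV
#'
#' Reads the canonical comma-separated dialect (header row with `sequence`,
#' `charge` and optionally `ccs`), accepting common column aliases used by
#' published CCS dumps. Rows with unsupported charge states or unparsable
#' sequences are dropped, with a logged count.
#'
#' @param path CSV file path.
#' @return Data frame with columns `sequence` (canonical dialect), `charge`
#'   and `ccs` (`NA` when absent), in file order, with the parsed peptide
#'   objects in the `peptides` attribute.
#' @export
read_ccs_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  si <- .resolve_column(names(raw), .SEQ_ALIASES)
  zi <- .resolve_column(names(raw), .CHARGE_ALIASES)
  if (is.na(si) || is.na(zi))
    stop("format error: could not resolve sequence/charge columns in ", path)
  ci <- .resolve_column(names(raw), .CCS_ALIASES)
  n0 <- nrow(raw)
  peps <- vector("list", n0)
  keep <- logical(n0)
  for (i in seq_len(n0)) {
    p <- tryCatch(parse_peptide(raw[[si]][i], raw[[zi]][i]),
                  error = function(e) NULL)
    if (!is.null(p)) { peps[[i]] <- p; keep[i] <- TRUE }
  }
  if (any(!keep))
    message(sum(!keep), " of ", n0,
            " records dropped (invalid sequence or charge state)")
  peps <- peps[keep]
  ccs <- if (is.na(ci)) rep(NA_real_, sum(keep)) else as.numeric(raw[[ci]][keep])
  if (any(!is.na(ccs) & ccs <= 0))
    stop("format error: non-positive CCS values in ", path)
  out <- data.frame(
    sequence = vapply(peps, format, character(1)),
    charge = vapply(peps, function(p) p$charge, integer(1)),
    ccs = ccs, stringsAsFactors = FALSE)
  attr(out, "peptides") <- peps
  out
}

#' Write a peptide CCS data set to CSV
#'
#' Writes the canonical dialect (`sequence`, `charge`, `ccs` columns) so
#' synthetic and real data are interchangeable downstream.
#'
#' @param peptides List of `peptide` objects, or a data frame as returned by
#'   [read_ccs_csv()].
#' @param path Output path.
#' @param ccs CCS values (ignored when `peptides` is a data frame).
#' @export
write_ccs_csv <- function(peptides, path, ccs = NULL) {
  if (is.data.frame(peptides)) {
    df <- peptides[, c("sequence", "charge", "ccs")]
  } else {
    df <- data.frame(
      sequence = vapply(peptides, format, character(1)),
      charge = vapply(peptides, function(p) p$charge, integer(1)),
      ccs = if (is.null(ccs)) NA_real_ else ccs,
      stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove holdout peptides from a training set
#'
#' Drops training records whose modified sequence + charge combination occurs
#' in the holdout set, logging the removal count. Identity is the canonical
#' modified-sequence string plus charge because CCS is charge-state-specific.
#'
#' @param train,holdout Data frames with `sequence` and `charge` columns.
#' @return The filtered training data frame.
#' @export
deduplicate_against <- function(train, holdout) {
  key <- function(d) paste0(d$sequence, "/", d$charge)
  drop <- key(train) %in% key(holdout)
  message(sum(drop), " training records removed (present in holdout)")
  out <- train[!drop, , drop = FALSE]
  pl <- attr(train, "peptides")
  if (!is.null(pl)) attr(out, "peptides") <- pl[!drop]
  out
}
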